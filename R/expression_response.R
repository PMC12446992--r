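#' Call DEG direction from a differential-expression result table
#'
#' Applies the study thresholds to a raw DE result table: a gene is "up"
#' when log2 fold change > 0, adjusted p < \code{alpha} and
#' |log2 fold change| >= \code{lfc_min}; "down" symmetrically; otherwise
#' "ns". The fold-change threshold is interpreted on the log2 scale
#' (|log2FC| >= 1 by default, i.e. a two-fold change).
#'
#' @param tab data.frame with columns \code{gene_id}, \code{log2fc},
#'   \code{p}, \code{p_adj}.
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @param lfc_min Minimum |log2 fold change| (default 1).
#' @return The table with a \code{direction} factor column
#'   ("up"/"down"/"ns") added.
#' @export
call_degs <- function(tab, alpha = 0.05, lfc_min = 1) {
  req <- c("gene_id", "log2fc", "p_adj")
  if (!all(req %in% names(tab))) {
    stop("DEG table needs columns: ", paste(req, collapse = ", "))
  }
  sig <- !is.na(tab$p_adj) & tab$p_adj < alpha &
    !is.na(tab$log2fc) & abs(tab$log2fc) >= lfc_min
  tab$direction <- ifelse(sig & tab$log2fc > 0, "up",
                          ifelse(sig & tab$log2fc < 0, "down", "ns"))
  tab
}

#' Merge DEG calls from two independent methods
#'
#' Intersects the up- and down-regulated gene sets called by two DE methods
#' to obtain the "common" DEGs — the conservative consensus used when two
#' count-model tools are run on the same contrast. Genes called in opposite
#' directions by the two methods are excluded and reported as conflicts.
#'
#' @param a,b DEG tables with a \code{direction} column (see [call_degs()];
#'   tables without one are passed through \code{call_degs} with defaults).
#' @return A list: \code{common_up}, \code{common_down} (character vectors,
#'   sorted), \code{conflicts} (character), \code{n_up}, \code{n_down}.
#' @examples
#' a <- data.frame(gene_id = c("g1", "g2"), log2fc = c(2, -2),
#'                 p = 0.001, p_adj = 0.001)
#' b <- data.frame(gene_id = c("g1", "g2"), log2fc = c(1.5, 2),
#'                 p = 0.001, p_adj = 0.001)
#' merge_degs(a, b)$common_up   # "g1"; g2 conflicts
#' @export
merge_degs <- function(a, b) {
  if (!"direction" %in% names(a)) a <- call_degs(a)
  if (!"direction" %in% names(b)) b <- call_degs(b)
  if (length(intersect(a$gene_id, b$gene_id)) == 0L) {
    stop("DEG tables share no genes")
  }
  dir_of <- function(tab) {
    stats::setNames(tab$direction, tab$gene_id)
  }
  da <- dir_of(a); db <- dir_of(b)
  shared <- intersect(names(da), names(db))
  conflicts <- shared[(da[shared] == "up" & db[shared] == "down") |
                      (da[shared] == "down" & db[shared] == "up")]
  common_up <- sort(shared[da[shared] == "up" & db[shared] == "up"])
  common_down <- sort(shared[da[shared] == "down" & db[shared] == "down"])
  list(common_up = common_up, common_down = common_down,
       conflicts = sort(conflicts),
       n_up = length(common_up), n_down = length(common_down))
}

#' Enumerate and select short-series model expression profiles
#'
#' Generates all candidate integer expression profiles of length \code{T}
#' that start at 0 and change by at most \code{c} units between successive
#' conditions — \eqn{(2c+1)^{T-1}} candidates — and greedily selects
#' \code{m} maximally distinct representatives, in the manner of
#' short time-series expression mining. Distance between profiles is
#' \eqn{d = 1 - r} (Pearson); correlation with the flat (all-zero) profile
#' is treated as 0, so every non-flat candidate is at distance 1 from flat.
#' Selection starts from the candidate farthest from the flat profile and
#' repeatedly adds the candidate maximizing its minimum distance to those
#' already selected; all ties break lexicographically by pattern, so the
#' selected set is fully deterministic. The flat profile itself is never a
#' selectable target (it represents "no change").
#'
#' @param T Number of ordered conditions (>= 3).
#' @param c Maximum unit change between successive conditions (>= 1).
#' @param m Number of model profiles to select.
#' @return A list with class \code{profile_models}: \code{patterns} (m x T
#'   integer matrix, row order = selection order, rownames = profile ids
#'   "P1".."Pm"), \code{candidates} (full candidate matrix), \code{T},
#'   \code{c}, \code{m}.
#' @examples
#' nrow(stem_profiles(4, 1, 5)$candidates)  # 27
#' @export
stem_profiles <- function(T, c, m) {
  stopifnot(T >= 3L, c >= 1L)
  steps <- seq.int(-c, c)
  grids <- rep(list(steps), T - 1L)
  inc <- as.matrix(rev(expand.grid(rev(grids))))
  cand <- cbind(0L, t(apply(inc, 1L, cumsum)))
  storage.mode(cand) <- "integer"
  colnames(cand) <- paste0("t", seq_len(T))
  # lexicographic candidate order for deterministic tie-breaking
  ord <- do.call(order, as.data.frame(cand))
  cand <- cand[ord, , drop = FALSE]
  rownames(cand) <- NULL
  flat <- rowSums(cand != 0L) == 0L
  pool <- which(!flat)
  if (m > length(pool)) {
    stop("m exceeds the number of non-flat candidate profiles (",
         length(pool), ")")
  }
  d <- function(p, q) {
    if (stats::sd(p) == 0 || stats::sd(q) == 0) return(1)
    1 - stats::cor(p, q)
  }
  # distance of every pool candidate to flat is 1: first pick is the
  # lexicographically smallest non-flat candidate
  sel <- pool[1L]
  remaining <- setdiff(pool, sel)
  mind <- vapply(remaining,
                 function(i) d(cand[i, ], cand[sel, ]), numeric(1))
  while (length(sel) < m) {
    best <- which(mind == max(mind))[1L]  # remaining is in lex order
    pick <- remaining[best]
    sel <- c(sel, pick)
    remaining <- remaining[-best]
    mind <- mind[-best]
    if (length(remaining) > 0L) {
      newd <- vapply(remaining,
                     function(i) d(cand[i, ], cand[pick, ]), numeric(1))
      mind <- pmin(mind, newd)
    }
  }
  patterns <- cand[sel, , drop = FALSE]
  rownames(patterns) <- paste0("P", seq_len(m))
  structure(list(patterns = patterns, candidates = cand,
                 T = T, c = c, m = m),
            class = "profile_models")
}

#' Find a pattern among selected model profiles
#'
#' @param profiles A \code{profile_models} object.
#' @param pattern Integer vector of length \code{profiles$T}.
#' @return The profile id ("P<k>") or \code{NA} if the pattern was not
#'   selected.
#' @export
find_profile <- function(profiles, pattern) {
  hit <- which(apply(profiles$patterns, 1L,
                     function(p) all(p == pattern)))
  if (length(hit) == 0L) NA_character_ else rownames(profiles$patterns)[hit[1L]]
}

#' Summarize a count matrix per group on the log2 CPM scale
#'
#' Normalizes counts to counts-per-million per sample, transforms to
#' log2(CPM + 1), and averages replicates within each group, in the stated
#' group order.
#'
#' @param counts Integer matrix, genes x samples.
#' @param groups Character/factor of length ncol(counts) giving each
#'   sample's group.
#' @param group_order Ordered unique group labels (default: order of first
#'   appearance).
#' @return Numeric matrix genes x groups of mean log2(CPM + 1).
#' @export
group_log_means <- function(counts, groups,
                            group_order = unique(as.character(groups))) {
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts),
            all(groups %in% group_order))
  libsize <- colSums(counts)
  if (any(libsize == 0)) stop("sample(s) with zero total counts")
  cpm <- sweep(counts, 2L, libsize / 1e6, "/")
  lg <- log2(cpm + 1)
  out <- vapply(group_order, function(g) {
    rowMeans(lg[, groups == g, drop = FALSE])
  }, numeric(nrow(counts)))
  if (is.null(dim(out))) {
    out <- matrix(out, nrow = 1L,
                  dimnames = list(rownames(counts), group_order))
  }
  colnames(out) <- group_order
  out
}

#' Assign genes to model profiles and test profile sizes exactly
#'
#' Summarizes expression per ordered group (mean log2(CPM+1)), expresses
#' each gene as its change vector against the baseline group
#' \eqn{v_t = s_t - s_{baseline}}, and assigns each gene to the selected
#' model profile with the highest Pearson correlation to its pattern
#' (zero-variance genes stay unassigned; ties go to the lower profile id).
#'
#' Significance of each profile's assigned count uses an exact permutation
#' null: for every gene, all \eqn{T!} permutations of its change vector are
#' assigned by the same rule, giving the gene's null probability of landing
#' on each profile; the expected profile size is the sum of these
#' probabilities over genes. Each profile's p-value is the upper-tail
#' binomial probability of observing at least its assigned count given the
#' permutation-expected proportion, Bonferroni-corrected by the number of
#' profiles.
#'
#' @param counts Integer count matrix, genes x samples.
#' @param groups Sample group labels (length ncol(counts)).
#' @param profiles A \code{profile_models} from [stem_profiles()].
#' @param group_order Ordered condition labels; the first is used for
#'   candidate ordering of columns. Must contain \code{baseline}.
#' @param baseline Baseline group id (default: first of
#'   \code{group_order}).
#' @param alpha Significance level on the Bonferroni-adjusted p (default
#'   0.05).
#' @return A list with class \code{profile_fit}:
#'   \describe{
#'     \item{table}{data.frame per profile: \code{profile_id},
#'       \code{pattern} (collapsed "0,0,1,0" form), \code{n_assigned},
#'       \code{expected}, \code{p}, \code{p_adj}, \code{significant}.}
#'     \item{assignments}{named character: gene -> profile id (\code{NA} =
#'       unassigned).}
#'     \item{baseline, group_order}{echoed inputs.}
#'   }
#' @export
assign_and_test_profiles <- function(counts, groups, profiles,
                                     group_order = unique(as.character(groups)),
                                     baseline = group_order[1L],
                                     alpha = 0.05) {
  if (!baseline %in% group_order) {
    stop("baseline group '", baseline, "' not among groups")
  }
  s <- group_log_means(counts, groups, group_order)
  v <- s - s[, baseline]
  pat <- profiles$patterns
  stopifnot(ncol(v) == ncol(pat))
  m <- nrow(pat)
  genes <- rownames(counts)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(counts)))

  assigned <- assign_matrix(v, pat)

  perms <- permutations_of(ncol(v))
  nperm <- nrow(perms)
  # exact permutation null: assign every permuted change vector, accumulate
  # per-profile expected counts
  expected <- numeric(m)
  for (k in seq_len(nperm)) {
    a <- assign_matrix(v[, perms[k, ], drop = FALSE], pat)
    hits <- tabulate(a[a > 0L], nbins = m)
    expected <- expected + hits / nperm
  }
  n_genes <- nrow(v)
  prop <- expected / n_genes
  n_assigned <- tabulate(assigned[assigned > 0L], nbins = m)
  p <- vapply(seq_len(m), function(j) {
    stats::pbinom(n_assigned[j] - 1L, size = n_genes, prob = prop[j],
                  lower.tail = FALSE)
  }, numeric(1))
  p_adj <- pmin(p * m, 1)
  tab <- data.frame(
    profile_id = rownames(pat),
    pattern = apply(pat, 1L, paste, collapse = ","),
    n_assigned = n_assigned,
    expected = expected,
    p = p,
    p_adj = p_adj,
    significant = p_adj < alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
  assignments <- ifelse(assigned > 0L, rownames(pat)[pmax(assigned, 1L)],
                        NA_character_)
  names(assignments) <- genes
  structure(list(table = tab, assignments = assignments,
                 baseline = baseline, group_order = group_order),
            class = "profile_fit")
}

# Assign every row of a change-vector matrix to the best-correlated profile
# row (Pearson r); 0 = unassigned (zero-variance vector). Ties break to the
# lower profile id (earlier pattern row).
assign_matrix <- function(v, patterns) {
  v <- v - rowMeans(v)
  vn <- sqrt(rowSums(v^2))
  p <- patterns - rowMeans(patterns)
  pn <- sqrt(rowSums(p^2))
  ok <- vn > 0
  out <- integer(nrow(v))
  if (any(ok)) {
    r <- (v[ok, , drop = FALSE] / vn[ok]) %*% t(p / pn)
    out[ok] <- max.col(r, ties.method = "first")
  }
  out
}

# Single-vector convenience wrapper around assign_matrix.
assign_one <- function(v, patterns) {
  assign_matrix(matrix(v, nrow = 1L), patterns)[1L]
}

# All permutations of 1..n as an n! x n matrix, deterministic order.
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Relative expression by the 2^-ddCt method
#'
#' Computes relative qPCR expression of a target gene normalized to a
#' reference (housekeeping) gene and to a control group:
#' \eqn{\Delta Ct = Ct_{target} - Ct_{ref}} per sample,
#' \eqn{\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{control}}, and
#' fold change \eqn{2^{-\Delta\Delta Ct}}. The control group's mean fold is
#' 1 by construction (geometric mean). Samples missing a reference Ct are
#' dropped with a warning.
#'
#' @param ct data.frame with columns \code{sample}, \code{group},
#'   \code{gene}, \code{ct}: one row per (sample, gene) Ct measurement.
#' @param target Target gene id.
#' @param reference Reference/housekeeping gene id (e.g. "GAPDH").
#' @param control_group Control group label.
#' @return data.frame per retained sample: \code{sample}, \code{group},
#'   \code{dct}, \code{ddct}, \code{fold}.
#' @examples
#' ct <- data.frame(
#'   sample = rep(c("c1", "c2", "t1"), each = 2),
#'   group = rep(c("Control", "Control", "Treat"), each = 2),
#'   gene = rep(c("tgt", "ref"), 3),
#'   ct = c(20, 17, 20, 17, 22, 17))
#' ddct_fold_change(ct, "tgt", "ref", "Control")$fold  # 1, 1, 0.25
#' @export
ddct_fold_change <- function(ct, target, reference, control_group) {
  req <- c("sample", "group", "gene", "ct")
  if (!all(req %in% names(ct))) {
    stop("Ct table needs columns: ", paste(req, collapse = ", "))
  }
  tgt <- ct[ct$gene == target, ]
  ref <- ct[ct$gene == reference, ]
  if (nrow(tgt) == 0L) stop("no Ct rows for target gene '", target, "'")
  ref_ct <- stats::setNames(ref$ct, ref$sample)
  missing_ref <- setdiff(tgt$sample, names(ref_ct))
  if (length(missing_ref) > 0L) {
    warning("dropping sample(s) without reference Ct: ",
            paste(missing_ref, collapse = ", "))
    tgt <- tgt[!tgt$sample %in% missing_ref, ]
  }
  if (nrow(tgt) == 0L) stop("no samples with both target and reference Ct")
  dct <- tgt$ct - ref_ct[tgt$sample]
  is_ctrl <- tgt$group == control_group
  if (!any(is_ctrl)) stop("control group '", control_group, "' absent")
  ddct <- dct - mean(dct[is_ctrl])
  data.frame(sample = tgt$sample, group = tgt$group,
             dct = unname(dct), ddct = unname(ddct),
             fold = 2^(-unname(ddct)),
             row.names = NULL, stringsAsFactors = FALSE)
}
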