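#' Build a genes x informative-codons RSCU matrix
#'
#' Computes per-gene RSCU for every gene in a codon count matrix, restricted
#' to the 59 informative codons (no stops, no Met/Trp), in a fixed codon
#' order shared by both organisms' matrices. Entries of unobserved families
#' stay \code{NA} (never silently zero-filled). Genes whose fraction of
#' undefined entries exceeds \code{max_undefined_fraction} are excluded and
#' reported.
#'
#' @param count_table A \code{codon_counts} matrix from [count_codons()].
#' @param code A \code{genetic_code}.
#' @param max_undefined_fraction Maximum tolerated fraction of \code{NA}
#'   RSCU entries per gene (default 0.5).
#' @return A list with class \code{rscu_matrix}: \code{values} (genes x 59
#'   numeric matrix), \code{codon_order} (character(59)), \code{excluded}
#'   (data.frame gene_id, n_undefined).
#' @export
build_rscu_matrix <- function(count_table, code = standard_genetic_code(),
                              max_undefined_fraction = 0.5) {
  if (!is.matrix(count_table) || nrow(count_table) == 0L) {
    stop("count table must be a nonempty codon count matrix")
  }
  codon_order <- code$codons[code$informative]
  vals <- t(apply(count_table, 1L, function(x) {
    rscu(x, code)[codon_order]
  }))
  colnames(vals) <- codon_order
  n_undef <- rowSums(is.na(vals))
  drop <- n_undef / length(codon_order) > max_undefined_fraction
  excluded <- data.frame(gene_id = rownames(vals)[drop],
                         n_undefined = n_undef[drop],
                         row.names = NULL, stringsAsFactors = FALSE)
  structure(list(values = vals[!drop, , drop = FALSE],
                 codon_order = codon_order,
                 excluded = excluded),
            class = "rscu_matrix")
}

#' Screen query genes for codon usage correlated with a partner organism
#'
#' For each query gene, computes the Pearson correlation between its RSCU
#' vector and the partner's codon-usage profile over codons defined in both
#' (pairwise deletion), with the two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. A gene
#' is selected when \eqn{r \ge r_{min}} and \eqn{p < p_{max}}; p-values are
#' deliberately NOT multiple-testing corrected by default (set
#' \code{fdr = "bh"} for Benjamini-Hochberg adjusted selection). Genes with
#' fewer than \code{min_codons_used} usable codons are flagged untestable
#' and never selected.
#'
#' Two interpretations of "partner profile" are supported:
#' \describe{
#'   \item{mode "profile" (default)}{each query gene vs the partner's
#'     organism-level RSCU vector — one test per query gene.}
#'   \item{mode "best-gene"}{each query gene vs its best-correlated
#'     individual partner gene (the partner id is reported); a far more
#'     permissive screen.}
#' }
#'
#' @param query An \code{rscu_matrix} for the query organism.
#' @param partner For mode "profile": a named organism-level RSCU vector
#'   (e.g. [organism_rscu()]); for mode "best-gene": the partner's
#'   \code{rscu_matrix}.
#' @param mode "profile" or "best-gene".
#' @param r_min Minimum correlation for selection (default 0.5).
#' @param p_max Maximum p-value for selection (default 0.05).
#' @param fdr "none" (default) or "bh": adjust p before applying
#'   \code{p_max}.
#' @param min_codons_used Minimum pairwise-complete codons (default 10).
#' @return data.frame sorted by descending r (ties by gene id): columns
#'   \code{gene_id}, \code{r}, \code{p}, \code{n_codons_used},
#'   \code{testable}, \code{selected}, and for mode "best-gene"
#'   \code{partner_id}. If \code{fdr = "bh"}, an extra \code{p_adj} column
#'   is used for selection.
#' @export
screen_genes <- function(query, partner, mode = c("profile", "best-gene"),
                         r_min = 0.5, p_max = 0.05,
                         fdr = c("none", "bh"), min_codons_used = 10L) {
  mode <- match.arg(mode)
  fdr <- match.arg(fdr)
  stopifnot(inherits(query, "rscu_matrix"))
  qv <- query$values
  if (mode == "profile") {
    if (is.list(partner) && inherits(partner, "rscu_matrix")) {
      stop('mode "profile" expects an organism-level RSCU vector')
    }
    prof <- partner[query$codon_order]
    res <- t(vapply(seq_len(nrow(qv)), function(i) {
      pearson_with_p(qv[i, ], prof)
    }, numeric(3)))
    out <- data.frame(gene_id = rownames(qv),
                      r = res[, 1L], p = res[, 2L],
                      n_codons_used = as.integer(res[, 3L]),
                      stringsAsFactors = FALSE)
  } else {
    stopifnot(inherits(partner, "rscu_matrix"))
    if (!identical(query$codon_order, partner$codon_order)) {
      stop("query and partner matrices must share codon_order")
    }
    pv <- partner$values
    rows <- lapply(seq_len(nrow(qv)), function(i) {
      best <- c(r = -Inf, p = NA_real_, n = 0)
      best_id <- NA_character_
      for (j in seq_len(nrow(pv))) {
        cur <- pearson_with_p(qv[i, ], pv[j, ])
        if (!is.na(cur[1L]) &&
            (cur[1L] > best[1L] ||
             (cur[1L] == best[1L] && is.na(best_id)))) {
          best <- cur
          best_id <- rownames(pv)[j]
        }
      }
      data.frame(gene_id = rownames(qv)[i],
                 r = if (is.finite(best[1L])) best[1L] else NA_real_,
                 p = best[2L], n_codons_used = as.integer(best[3L]),
                 partner_id = best_id, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  out$testable <- !is.na(out$r) & out$n_codons_used >= min_codons_used
  p_sel <- out$p
  if (fdr == "bh") {
    p_sel <- stats::p.adjust(out$p, method = "BH")
    out$p_adj <- p_sel
  }
  out$selected <- out$testable & !is.na(out$r) & out$r >= r_min &
    !is.na(p_sel) & p_sel < p_max
  ord <- order(-out$r, out$gene_id, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pearson r, two-sided t-test p and n over pairwise-complete entries.
# Returns c(r, p, n); r is NA when n < 3 or either side is constant.
pearson_with_p <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) return(c(NA_real_, NA_real_, n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(c(NA_real_, NA_real_, n))
  }
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1)
  p <- if (r2 >= 1) {
    0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  c(r, p, n)
}
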