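#' Construct a codon model for one synthetic organism
#'
#' A codon model holds, for every amino acid, a probability vector over its
#' synonymous codons. Base preferences come from a GC3 tilt — codons ending
#' in G/C get relative weight \code{gc3_bias}, codons ending in A/T get
#' \code{1 - gc3_bias} — multiplied by a per-family Dirichlet-distributed
#' preference draw of strength \code{preference_strength}, so two models
#' built with different seeds differ in which codon each family prefers,
#' not only in GC3. Per-gene Dirichlet jitter around the model is applied
#' at generation time (see [generate_cds_set()]).
#'
#' @param seed Integer seed for the preference draw.
#' @param gc3_bias Probability weight of G/C at synonymous third positions
#'   (default 0.5 = no tilt).
#' @param preference_strength Dirichlet concentration of the per-family
#'   preference draw; smaller = stronger idiosyncratic codon preferences
#'   (default 5).
#' @param code A \code{genetic_code}.
#' @return A list with class \code{codon_model}: \code{probs} (named list,
#'   amino acid -> named probability vector over its codons), \code{gc3_bias},
#'   \code{seed}.
#' @export
codon_model <- function(seed, gc3_bias = 0.5, preference_strength = 5,
                        code = standard_genetic_code()) {
  stopifnot(gc3_bias >= 0, gc3_bias <= 1, preference_strength > 0)
  set.seed(as.integer(seed))
  probs <- lapply(names(code$families), function(a) {
    fam <- code$families[[a]]
    third <- substring(fam, 3L, 3L)
    tilt <- ifelse(third %in% c("G", "C"), gc3_bias, 1 - gc3_bias)
    if (all(tilt == 0)) tilt <- rep(1, length(fam))
    pref <- stats::rgamma(length(fam), shape = preference_strength, rate = 1)
    p <- tilt * pref
    p <- p / sum(p)
    stats::setNames(p, fam)
  })
  names(probs) <- names(code$families)
  structure(list(probs = probs, gc3_bias = gc3_bias, seed = seed),
            class = "codon_model")
}

# Average amino-acid composition used as the background for synthetic
# proteins (typical proteome-wide frequencies, Met/Trp included).
AA_BACKGROUND <- c(
  A = 0.083, R = 0.055, N = 0.040, D = 0.054, C = 0.014, Q = 0.039,
  E = 0.067, G = 0.071, H = 0.022, I = 0.059, L = 0.096, K = 0.058,
  M = 0.024, F = 0.038, P = 0.047, S = 0.066, T = 0.053, W = 0.011,
  Y = 0.029, V = 0.068)

#' Generate a synthetic CDS collection with planted host-similar genes
#'
#' Draws \code{n_genes} coding sequences from a codon model. Each gene's
#' amino-acid sequence is sampled from a fixed background composition;
#' codons are then drawn per amino acid from a per-gene codon distribution:
#' the organism's own model for background genes, and the mixture
#' \eqn{(1-\lambda) \cdot own + \lambda \cdot partner} for the
#' \code{n_planted} planted genes, so \eqn{\lambda} tunes continuously how
#' strongly the planted genes' codon usage tracks the partner organism.
#' Per-gene Dirichlet jitter (concentration \code{concentration} times the
#' model probabilities) adds realistic gene-to-gene usage variation.
#'
#' Every sequence starts with ATG, ends with a TAA stop, contains no
#' internal stop (stop codons are never drawn internally) and no ambiguous
#' base, so the output passes strict CDS QC with zero removals. Gene
#' lengths (in codons, excluding start/stop) are log-normal with median
#' \code{exp(length_meanlog)} (default 300 codons), floored at
#' \code{min_codons}.
#'
#' @param model \code{codon_model} of the organism being generated.
#' @param n_genes Number of genes.
#' @param partner_model \code{codon_model} of the partner organism
#'   (required when \code{n_planted > 0}).
#' @param n_planted Number of planted partner-similar genes (the first
#'   \code{n_planted} generated ids).
#' @param lambda Mixing weight toward the partner model, in [0, 1].
#' @param length_meanlog,length_sdlog Log-normal length parameters
#'   (codons); defaults log(300) and 0.35.
#' @param min_codons Lower floor on gene length in codons (default 50).
#' @param concentration Dirichlet concentration of per-gene jitter
#'   (default 200; larger = genes closer to the model).
#' @param seed Integer seed; identical seeds give identical output.
#' @param id_prefix Gene id prefix (default "gene").
#' @return A list with class \code{synthetic_cds}:
#'   \describe{
#'     \item{sequences}{named \code{DNAStringSet}.}
#'     \item{truth}{list: \code{planted_similar_gene_ids}, \code{lambda},
#'       \code{seed}.}
#'   }
#' @export
generate_cds_set <- function(model, n_genes, partner_model = NULL,
                             n_planted = 0L, lambda = 0,
                             length_meanlog = log(300), length_sdlog = 0.35,
                             min_codons = 50L, concentration = 200,
                             seed = 1L, id_prefix = "gene") {
  stopifnot(inherits(model, "codon_model"), n_genes >= 1L,
            n_planted >= 0L, n_planted <= n_genes)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (n_planted > 0L && is.null(partner_model)) {
    stop("partner_model required when planting similar genes")
  }
  code <- standard_genetic_code()
  set.seed(as.integer(seed))
  aas <- names(AA_BACKGROUND)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n_genes))
  lens <- pmax(as.integer(round(stats::rlnorm(n_genes, length_meanlog,
                                              length_sdlog))),
               as.integer(min_codons))
  seqs <- character(n_genes)
  for (i in seq_len(n_genes)) {
    planted <- i <= n_planted
    base_probs <- lapply(aas, function(a) {
      p <- model$probs[[a]]
      if (planted && lambda > 0) {
        p <- (1 - lambda) * p + lambda * partner_model$probs[[a]]
      }
      p
    })
    names(base_probs) <- aas
    # per-gene Dirichlet jitter around the (possibly mixed) model
    gene_probs <- lapply(base_probs, function(p) {
      if (length(p) == 1L) return(p)
      g <- stats::rgamma(length(p), shape = concentration * p, rate = 1)
      if (sum(g) == 0) return(p)
      stats::setNames(g / sum(g), names(p))
    })
    aa_seq <- sample(aas, lens[i], replace = TRUE, prob = AA_BACKGROUND)
    codons <- character(lens[i])
    for (a in unique(aa_seq)) {
      idx <- which(aa_seq == a)
      p <- gene_probs[[a]]
      codons[idx] <- if (length(p) == 1L) names(p) else
        sample(names(p), length(idx), replace = TRUE, prob = p)
    }
    seqs[i] <- paste0("ATG", paste(codons, collapse = ""), "TAA")
  }
  sequences <- Biostrings::DNAStringSet(stats::setNames(seqs, ids))
  structure(
    list(sequences = sequences,
         truth = list(planted_similar_gene_ids = ids[seq_len(n_planted)],
                      lambda = lambda, seed = seed)),
    class = "synthetic_cds"
  )
}

#' Write a synthetic CDS collection to FASTA
#'
#' @param x A \code{synthetic_cds} or \code{DNAStringSet}.
#' @param path Output FASTA path.
#' @return \code{path}, invisibly.
#' @export
write_cds_fasta <- function(x, path) {
  seqs <- if (inherits(x, "synthetic_cds")) x$sequences else x
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' Simulate a count matrix with planted expression profiles
#'
#' Simulates negative-binomial RNA-seq counts for a multi-group design.
#' Gene baseline means are log-normal around \code{baseline_mean}; a gene
#' planted on profile pattern \eqn{(z_1..z_T)} with effect size e has group
#' mean \eqn{\mu_g \cdot 2^{e \cdot z_t}} in group t; counts are NB with
#' dispersion \eqn{\phi} (variance \eqn{\mu + \phi\mu^2}), scaled by
#' per-sample log-normal library-size factors.
#'
#' Two differential-expression tables per contrast (each treatment group vs
#' the first group) are fabricated by two deliberately simple, distinct
#' recipes, so that DEG merging has realistic partially-overlapping inputs:
#' \describe{
#'   \item{genewise_t}{pooled-variance t-test on log2(normalized count + 1),
#'     residual variance from all design groups.}
#'   \item{global_z}{log-ratio z-test with the per-gene variance replaced by
#'     the median residual variance across genes.}
#' }
#' Counts are normalized by median-of-ratios size factors (robust to the
#' composition shift planted DE genes induce); both recipes report log2 fold
#' change as the difference of group mean log values and BH-adjusted
#' p-values.
#'
#' @param n_genes Total genes.
#' @param groups Ordered group labels (default the four-condition design
#'   Control, Bacterium, Calcium, CalciumBacterium).
#' @param n_reps Replicates per group (default 3).
#' @param planted_profiles List of plantings, each a list with
#'   \code{pattern} (integer vector, length = number of groups, first entry
#'   0), \code{n} (genes) and \code{effect} (log2 units per pattern unit).
#'   Planted genes occupy the first ids, in list order.
#' @param dispersion NB dispersion phi > 0 (default 0.1).
#' @param baseline_mean Median baseline expression (default 100).
#' @param libsize_sdlog Log-normal sd of library-size factors (default 0.1).
#' @param seed Integer seed.
#' @return A list with class \code{synthetic_counts}:
#'   \describe{
#'     \item{counts}{integer matrix genes x samples.}
#'     \item{groups}{character vector of sample group labels.}
#'     \item{group_order}{ordered group labels.}
#'     \item{deg_tables}{nested list: contrast -> method ("genewise_t",
#'       "global_z") -> DEG data.frame (gene_id, log2fc, p, p_adj).}
#'     \item{truth}{list: \code{planted_profile_gene_ids} (named by
#'       collapsed pattern), \code{dispersion}, \code{seed}.}
#'   }
#' @export
simulate_counts <- function(n_genes,
                            groups = c("Control", "Bacterium", "Calcium",
                                       "CalciumBacterium"),
                            n_reps = 3L,
                            planted_profiles = list(),
                            dispersion = 0.1, baseline_mean = 100,
                            libsize_sdlog = 0.1, seed = 1L) {
  if (dispersion <= 0 || baseline_mean <= 0) {
    stop("dispersion and baseline_mean must be positive")
  }
  if (n_reps < 2L) stop("need >= 2 replicates per group for DE recipes")
  T <- length(groups)
  n_planted_tot <- sum(vapply(planted_profiles, function(p) p$n, numeric(1)))
  if (n_planted_tot > n_genes) stop("more planted genes than n_genes")
  set.seed(as.integer(seed))
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  sample_groups <- rep(groups, each = n_reps)
  sample_ids <- paste0(sample_groups, "_r", rep(seq_len(n_reps), times = T))

  log2_shift <- matrix(0, n_genes, T)   # per-gene, per-group log2 effect
  truth_ids <- list()
  at <- 1L
  for (pl in planted_profiles) {
    stopifnot(length(pl$pattern) == T, pl$pattern[1L] == 0)
    idx <- seq.int(at, at + pl$n - 1L)
    log2_shift[idx, ] <- matrix(rep(pl$effect * pl$pattern, each = pl$n),
                                nrow = pl$n)
    truth_ids[[paste(pl$pattern, collapse = ",")]] <- gene_ids[idx]
    at <- at + pl$n
  }

  mu0 <- stats::rlnorm(n_genes, meanlog = log(baseline_mean), sdlog = 1)
  sf <- stats::rlnorm(length(sample_ids), meanlog = 0, sdlog = libsize_sdlog)
  counts <- matrix(0L, n_genes, length(sample_ids),
                   dimnames = list(gene_ids, sample_ids))
  for (j in seq_along(sample_ids)) {
    g <- match(sample_groups[j], groups)
    mu <- mu0 * 2^log2_shift[, g] * sf[j]
    counts[, j] <- stats::rnbinom(n_genes, mu = mu, size = 1 / dispersion)
  }

  deg_tables <- list()
  sf_est <- size_factors_mor(counts)
  lg <- log2(sweep(counts, 2L, sf_est, "/") + 1)
  for (g in groups[-1L]) {
    contrast <- paste0(g, "_vs_", groups[1L])
    deg_tables[[contrast]] <- list(
      genewise_t = de_recipe(lg, sample_groups, groups[1L], g,
                             global_var = FALSE),
      global_z = de_recipe(lg, sample_groups, groups[1L], g,
                         global_var = TRUE)
    )
  }
  structure(
    list(counts = counts, groups = sample_groups, group_order = groups,
         deg_tables = deg_tables,
         truth = list(planted_profile_gene_ids = truth_ids,
                      dispersion = dispersion, seed = seed)),
    class = "synthetic_counts"
  )
}

# Median-of-ratios size factors (robust to composition shifts from planted
# DE genes, unlike total-count scaling).
size_factors_mor <- function(counts) {
  pos <- rowSums(counts == 0) == 0L
  if (sum(pos) < 10L) return(colSums(counts) / mean(colSums(counts)))
  ref <- exp(rowMeans(log(counts[pos, , drop = FALSE])))
  apply(counts[pos, , drop = FALSE], 2L, function(x) stats::median(x / ref))
}

# Two-group DE recipes on log2(size-factor-normalized count + 1); both use
# the within-group residual variance over every design group (residual df
# = n_samples - n_groups), but disagree on how it enters the test:
# genewise_t: ordinary pooled-variance t-test, each gene's own variance.
# global_z: normalized log-ratio z-test, the per-gene variance replaced by
#   the median residual variance across genes (gains power from borrowing
#   strength, loses it on genes noisier than typical) with a standard
#   normal reference.
# The two therefore produce partially-overlapping call sets, as two
# independent DE tools on the same data would.
de_recipe <- function(lg, groups, ref, alt, global_var = FALSE) {
  is_ref <- groups == ref
  is_alt <- groups == alt
  n1 <- sum(is_ref); n2 <- sum(is_alt)
  log2fc <- rowMeans(lg[, is_alt, drop = FALSE]) -
    rowMeans(lg[, is_ref, drop = FALSE])
  resid2 <- 0
  df <- 0L
  for (g in unique(groups)) {
    sel <- groups == g
    yg <- lg[, sel, drop = FALSE]
    resid2 <- resid2 + rowSums((yg - rowMeans(yg))^2)
    df <- df + sum(sel) - 1L
  }
  sp2 <- resid2 / df
  if (global_var) {
    se <- sqrt(stats::median(sp2) * (1 / n1 + 1 / n2))
    z <- if (se > 0) log2fc / se else rep(0, length(log2fc))
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  } else {
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tstat <- ifelse(se > 0, log2fc / se, 0)
    p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  }
  data.frame(gene_id = rownames(lg), log2fc = unname(log2fc),
             p = unname(p), p_adj = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fabricate a pair of DEG tables with planted overlap structure
#'
#' Builds two DEG tables over the same gene universe with exactly known
#' common-up, common-down, method-exclusive and direction-conflicting
#' calls, for validating DEG-set merging. Significant calls get
#' \code{p_adj} ~ U(0, alpha/2) and |log2fc| in [lfc_min + 0.5, lfc_min + 3];
#' non-significant genes get p_adj >= 0.5 and small fold changes.
#'
#' @param n_genes Gene universe size.
#' @param n_common_up,n_common_down Genes called up (down) by both methods.
#' @param n_only_a,n_only_b Genes called (up) by one method only.
#' @param n_conflict Genes called up by method A and down by method B.
#' @param alpha,lfc_min Thresholds the calls are planted against.
#' @param seed Integer seed.
#' @return A list: \code{a}, \code{b} (DEG data.frames), \code{truth}
#'   (planted id sets).
#' @export
simulate_deg_tables <- function(n_genes, n_common_up = 25L,
                                n_common_down = 10L, n_only_a = 15L,
                                n_only_b = 15L, n_conflict = 5L,
                                alpha = 0.05, lfc_min = 1, seed = 1L) {
  need <- n_common_up + n_common_down + n_only_a + n_only_b + n_conflict
  if (need > n_genes) stop("planted sets exceed n_genes")
  set.seed(as.integer(seed))
  ids <- sprintf("g%05d", seq_len(n_genes))
  grp <- rep("ns", n_genes)
  grp[seq_len(need)] <- rep(
    c("common_up", "common_down", "only_a", "only_b", "conflict"),
    times = c(n_common_up, n_common_down, n_only_a, n_only_b, n_conflict))
  sig_fc <- function(n, sign) sign * stats::runif(n, lfc_min + 0.5, lfc_min + 3)
  sig_p <- function(n) stats::runif(n, 0, alpha / 2)
  make <- function(which_method) {
    lfc <- stats::runif(n_genes, -lfc_min / 2, lfc_min / 2)
    padj <- stats::runif(n_genes, 0.5, 1)
    up <- grp == "common_up" |
      (grp == "only_a" & which_method == "a") |
      (grp == "only_b" & which_method == "b") |
      (grp == "conflict" & which_method == "a")
    down <- grp == "common_down" | (grp == "conflict" & which_method == "b")
    lfc[up] <- sig_fc(sum(up), 1)
    lfc[down] <- sig_fc(sum(down), -1)
    padj[up | down] <- sig_p(sum(up | down))
    data.frame(gene_id = ids, log2fc = lfc, p = padj, p_adj = padj,
               row.names = NULL, stringsAsFactors = FALSE)
  }
  list(a = make("a"), b = make("b"),
       truth = list(common_up = ids[grp == "common_up"],
                    common_down = ids[grp == "common_down"],
                    conflict = ids[grp == "conflict"],
                    seed = seed))
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Builds a Ct table (sample, group, gene, ct) for one target gene and one
#' reference gene where the target's true relative expression per group is
#' given by \code{fold_by_group} (control group fold = 1). Reference Ct
#' values are drawn around \code{ref_ct}; target Ct = reference +
#' \code{base_dct} - log2(fold) + noise.
#'
#' @param fold_by_group Named numeric of true fold changes per group; the
#'   first entry is the control group and must be 1.
#' @param n_reps Replicates per group (default 3).
#' @param target,reference Gene labels (defaults "target", "GAPDH").
#' @param ref_ct Mean reference Ct (default 17).
#' @param base_dct True control-group delta-Ct (default 3).
#' @param noise_sd Ct technical noise sd (default 0.05).
#' @param seed Integer seed.
#' @return A list: \code{ct} (data.frame), \code{truth} (fold_by_group,
#'   control group).
#' @export
simulate_ct_table <- function(fold_by_group, n_reps = 3L,
                              target = "target", reference = "GAPDH",
                              ref_ct = 17, base_dct = 3, noise_sd = 0.05,
                              seed = 1L) {
  stopifnot(!is.null(names(fold_by_group)), fold_by_group[1L] == 1,
            all(fold_by_group > 0))
  set.seed(as.integer(seed))
  rows <- list()
  for (g in names(fold_by_group)) {
    for (r in seq_len(n_reps)) {
      smp <- paste0(g, "_r", r)
      rc <- stats::rnorm(1, ref_ct, noise_sd)
      tc <- rc + base_dct - log2(fold_by_group[[g]]) +
        stats::rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, group = g, gene = c(target, reference),
        ct = c(tc, rc), stringsAsFactors = FALSE)
    }
  }
  list(ct = do.call(rbind, rows),
       truth = list(fold_by_group = fold_by_group,
                    control_group = names(fold_by_group)[1L], seed = seed))
}
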