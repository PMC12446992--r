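#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its observed count divided by the count expected if all
#' synonymous codons of its amino acid were used equally:
#' \deqn{RSCU_c = x_c / ( (1/k_a) \sum_{c' \in family(a)} x_{c'} )}
#' where \eqn{k_a} is the family size. RSCU = 1 means no bias. Families with
#' zero total count yield \code{NA} entries (flagged undefined, never zero).
#' Stop codons and the single-codon families (Met, Trp) are reported but
#' flagged non-informative.
#'
#' Genome-level RSCU is obtained by calling this on column sums of a codon
#' count matrix (pooled counts).
#'
#' @param counts Integer vector of length 64 (one gene's codon counts, named
#'   by codon) or a single-row \code{codon_counts} matrix.
#' @param code A \code{genetic_code}.
#' @return Named numeric(64) of RSCU values (\code{NA} where the family is
#'   unobserved or the codon is a stop), with attribute \code{informative}
#'   (logical mask of the 59 codons usable by downstream statistics).
#' @examples
#' x <- count_codons(c(g = "ATGGCAGCAGCTAAATAA"))[1, ]
#' rscu(x)[c("GCA", "GCT")]   # Ala counts 2,1 -> RSCU 8/3, 4/3
#' @export
rscu <- function(counts, code = standard_genetic_code()) {
  counts <- as_codon_vector(counts, code)
  out <- rep(NA_real_, 64)
  names(out) <- code$codons
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    tot <- sum(counts[fam])
    if (tot > 0) {
      out[fam] <- counts[fam] / (tot / length(fam))
    }
  }
  attr(out, "informative") <- code$informative
  out
}

#' Effective number of codons (ENC)
#'
#' Wright's ENC estimates how many codons a gene effectively uses: 20 means
#' one codon per amino acid (maximal bias), 61 means uniform synonymous
#' usage. Per amino-acid family with \eqn{n_a \ge 2} observed codons the
#' homozygosity is
#' \deqn{F_a = (n_a \sum_i p_i^2 - 1) / (n_a - 1),\quad p_i = x_i/n_a,}
#' averaged within each degeneracy class k to give \eqn{\bar F_k}, and
#' \deqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6.}
#' Nonpositive F values (possible at small n) are excluded from the class
#' mean; a missing \eqn{\bar F_3} (Ile absent) is imputed as
#' \eqn{(\bar F_2 + \bar F_4)/2}; values above 61 are capped at 61. The
#' sixfold families (Leu, Ser, Arg) are treated as single 6-fold classes.
#'
#' @inheritParams rscu
#' @return A list with class \code{enc_value}: \code{enc} (numeric, NA if
#'   undefined), \code{family_means} (named numeric, F-bar per class 2/3/4/6),
#'   \code{imputed_classes} (character).
#' @examples
#' x <- count_codons(c(g = "AAAAAAAAAAAG"))[1, ]  # Lys AAA=3, AAG=1
#' enc(x)$family_means[["2"]]                      # F = 0.5
#' @export
enc <- function(counts, code = standard_genetic_code()) {
  counts <- as_codon_vector(counts, code)
  f_by_class <- list(`2` = numeric(0), `3` = numeric(0),
                     `4` = numeric(0), `6` = numeric(0))
  for (a in names(code$families)) {
    k <- code$degeneracy[[a]]
    if (k < 2L) next
    x <- counts[code$families[[a]]]
    n <- sum(x)
    if (n < 2) next
    p <- x / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    if (is.finite(f) && f > 0) {
      cls <- as.character(k)
      f_by_class[[cls]] <- c(f_by_class[[cls]], f)
    }
  }
  fbar <- vapply(f_by_class, function(v) {
    if (length(v) == 0L) NA_real_ else mean(v)
  }, numeric(1))
  imputed <- character(0)
  if (is.na(fbar[["3"]]) && !is.na(fbar[["2"]]) && !is.na(fbar[["4"]])) {
    fbar[["3"]] <- (fbar[["2"]] + fbar[["4"]]) / 2
    imputed <- "3"
  }
  if (anyNA(fbar)) {
    return(structure(list(enc = NA_real_, family_means = fbar,
                          imputed_classes = imputed), class = "enc_value"))
  }
  nc <- 2 + 9 / fbar[["2"]] + 1 / fbar[["3"]] + 5 / fbar[["4"]] +
    3 / fbar[["6"]]
  nc <- min(nc, 61)
  structure(list(enc = nc, family_means = fbar, imputed_classes = imputed),
            class = "enc_value")
}

#' Expected ENC under mutation pressure alone
#'
#' The reference curve for the ENC-GC3 plot: the ENC a gene would have if
#' codon choice were determined purely by the G+C content at synonymous
#' third positions,
#' \deqn{ENC_{exp}(s) = 2 + s + 29/(s^2 + (1-s)^2).}
#' Genes far below this curve are biased beyond what mutation pressure
#' explains (selection); points near it are consistent with mutational bias.
#'
#' @param gc3 GC3 fraction(s) in [0, 1].
#' @return Expected ENC value(s).
#' @examples
#' enc_expected_curve(0.5)  # 60.5
#' @export
enc_expected_curve <- function(gc3) {
  if (any(!is.finite(gc3)) || any(gc3 < 0) || any(gc3 > 1)) {
    stop("gc3 must lie in [0, 1]")
  }
  2 + gc3 + 29 / (gc3^2 + (1 - gc3)^2)
}

#' Synonymous codon usage order (SCUO)
#'
#' Information-theoretic orderliness of synonymous codon choice. For each
#' amino acid a with family size \eqn{k_a \ge 2} and observed count
#' \eqn{n_a > 0}, the usage entropy is \eqn{H_a = -\sum_i p_i \log_2 p_i}
#' and the orderliness \eqn{O_a = (\log_2 k_a - H_a)/\log_2 k_a}. SCUO is
#' the codon-count-weighted average \eqn{\sum_a (n_a/N) O_a}: 0 = uniform
#' usage in every family, 1 = a single codon per family.
#'
#' @inheritParams rscu
#' @return A list with class \code{scuo_value}: \code{scuo} (numeric in
#'   [0, 1], NA if no multi-codon family observed), \code{per_aa_O} (named
#'   numeric of per-amino-acid orderliness).
#' @export
scuo <- function(counts, code = standard_genetic_code()) {
  counts <- as_codon_vector(counts, code)
  o <- numeric(0)
  n_aa <- numeric(0)
  for (a in names(code$families)) {
    k <- code$degeneracy[[a]]
    if (k < 2L) next
    x <- counts[code$families[[a]]]
    n <- sum(x)
    if (n == 0) next
    p <- x[x > 0] / n
    h <- -sum(p * log2(p))
    o[[a]] <- (log2(k) - h) / log2(k)
    n_aa[[a]] <- n
  }
  if (length(o) == 0L) {
    return(structure(list(scuo = NA_real_, per_aa_O = o),
                     class = "scuo_value"))
  }
  structure(list(scuo = sum(n_aa / sum(n_aa) * o), per_aa_O = o),
            class = "scuo_value")
}

#' PR2 (parity rule 2) plot coordinates
#'
#' Maps a gene onto the parity plane x = G3/(G3+C3), y = A3/(A3+T3) using
#' third-position base counts. Under no strand- or selection-asymmetry both
#' coordinates are 0.5. By default the counts are restricted to codons of
#' fourfold-degenerate families, where the third-position choice is fully
#' synonymous; set \code{fourfold_only = FALSE} to use all sense codons.
#'
#' @param comp A \code{base_composition} (from [base_composition()]).
#' @param fourfold_only Use fourfold-family-restricted third-position counts
#'   (default TRUE).
#' @return A list with class \code{pr2_point}: \code{x}, \code{y} (NA when a
#'   denominator is zero) and \code{quadrant}, one of \code{"top-left"},
#'   \code{"top-right"}, \code{"bottom-left"}, \code{"bottom-right"},
#'   \code{"boundary"} (a coordinate exactly 0.5) or \code{NA} (undefined).
#' @export
pr2_point <- function(comp, fourfold_only = TRUE) {
  if (fourfold_only) {
    a <- comp$a3_4f; t <- comp$t3_4f; g <- comp$g3_4f; c <- comp$c3_4f
  } else {
    a <- comp$a3; t <- comp$t3; g <- comp$g3; c <- comp$c3
  }
  x <- if ((g + c) > 0) g / (g + c) else NA_real_
  y <- if ((a + t) > 0) a / (a + t) else NA_real_
  quadrant <- if (is.na(x) || is.na(y)) {
    NA_character_
  } else if (x == 0.5 || y == 0.5) {
    "boundary"
  } else if (y > 0.5) {
    if (x > 0.5) "top-right" else "top-left"
  } else {
    if (x > 0.5) "bottom-right" else "bottom-left"
  }
  structure(list(x = x, y = y, quadrant = quadrant), class = "pr2_point")
}

#' Per-gene index table for a CDS collection
#'
#' Convenience wrapper computing, for every gene in a codon count matrix,
#' the full set of per-gene indices: GC/GC1/GC2/GC3, ENC, SCUO, PR2
#' coordinates and quadrant, plus CAI and RCDI when a host reference is
#' supplied.
#'
#' @param cds A \code{cds_set} (QC output); sequences are needed for
#'   positional composition.
#' @param host_counts Optional pooled (64-long) host codon counts enabling
#'   CAI and RCDI columns.
#' @param code A \code{genetic_code}.
#' @param fourfold_only Passed to [pr2_point()].
#' @return data.frame, one row per gene: \code{gene_id}, \code{n_codons},
#'   \code{gc}, \code{gc1}, \code{gc2}, \code{gc3}, \code{enc}, \code{scuo},
#'   \code{pr2_x}, \code{pr2_y}, \code{pr2_quadrant}, and (with a host)
#'   \code{cai}, \code{rcdi}. Undefined values are \code{NA}.
#' @export
gene_indices <- function(cds, host_counts = NULL,
                         code = standard_genetic_code(),
                         fourfold_only = TRUE) {
  counts <- count_codons(cds, code)
  seqs <- as.character(cds$sequences)
  stopifnot(nrow(counts) == length(seqs))
  weights <- if (!is.null(host_counts)) cai_weights(host_counts, code)
  hostf <- if (!is.null(host_counts)) host_codon_frequencies(host_counts, code)
  rows <- lapply(seq_along(seqs), function(i) {
    comp <- base_composition(seqs[[i]], code)
    p <- pr2_point(comp, fourfold_only = fourfold_only)
    x <- counts[i, ]
    row <- data.frame(
      gene_id = rownames(counts)[i],
      n_codons = comp$n_codons,
      gc = comp$gc, gc1 = comp$gc1, gc2 = comp$gc2, gc3 = comp$gc3,
      enc = enc(x, code)$enc,
      scuo = scuo(x, code)$scuo,
      pr2_x = p$x, pr2_y = p$y,
      pr2_quadrant = ifelse(is.na(p$quadrant), NA_character_, p$quadrant),
      stringsAsFactors = FALSE
    )
    if (!is.null(host_counts)) {
      row$cai <- cai(x, weights, code)
      row$rcdi <- rcdi(x, hostf, code)
    }
    row
  })
  do.call(rbind, rows)
}

#' Index distribution summaries and pairwise Pearson correlations
#'
#' Summarizes each numeric index column of a per-gene index table (min, max,
#' mean, median over defined values) and computes the pairwise Pearson
#' correlation matrix with two-sided p-values, using all genes with both
#' indices defined. Pairs with fewer than 3 complete observations are
#' flagged undefined (\code{NA}).
#'
#' @param records data.frame from [gene_indices()] (or any data.frame of
#'   per-gene index columns).
#' @param indices Character vector of column names to analyse; default all
#'   numeric columns except \code{n_codons}.
#' @return A list: \code{summary} (data.frame: index, n_defined, min, max,
#'   mean, median), \code{r} and \code{p} (square matrices), \code{n}
#'   (matrix of complete-pair counts).
#' @export
index_summary_and_correlations <- function(records, indices = NULL) {
  if (is.null(indices)) {
    num <- vapply(records, is.numeric, logical(1))
    indices <- setdiff(names(records)[num], c("n_codons"))
  }
  m <- as.matrix(records[, indices, drop = FALSE])
  summ <- data.frame(
    index = indices,
    n_defined = colSums(!is.na(m)),
    min = suppressWarnings(apply(m, 2, min, na.rm = TRUE)),
    max = suppressWarnings(apply(m, 2, max, na.rm = TRUE)),
    mean = colMeans(m, na.rm = TRUE),
    median = apply(m, 2, stats::median, na.rm = TRUE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  k <- length(indices)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(indices, indices))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- stats::complete.cases(m[, c(i, j)])
      n[i, j] <- sum(ok)
      if (n[i, j] >= 3) {
        if (i == j) {
          r[i, j] <- 1; p[i, j] <- 0
        } else if (stats::sd(m[ok, i]) > 0 && stats::sd(m[ok, j]) > 0) {
          ct <- stats::cor.test(m[ok, i], m[ok, j], method = "pearson")
          r[i, j] <- unname(ct$estimate)
          p[i, j] <- ct$p.value
        }
      }
    }
  }
  list(summary = summ, r = r, p = p, n = n)
}

# Coerce 1-row codon_counts matrices / named vectors to a named numeric(64)
# in canonical codon order.
as_codon_vector <- function(counts, code) {
  if (is.matrix(counts)) {
    if (nrow(counts) != 1L) {
      stop("expected counts for a single gene (vector or 1-row matrix)")
    }
    counts <- counts[1L, ]
  }
  if (is.null(names(counts)) || !all(code$codons %in% names(counts))) {
    stop("counts must be named by codon and cover all 64 codons")
  }
  counts <- as.numeric(counts[code$codons])
  names(counts) <- code$codons
  if (any(counts < 0)) stop("codon counts must be nonnegative")
  counts
}
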