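#' CAI relative-adaptiveness weights from a host reference
#'
#' Builds the codon weight table for the codon adaptation index from pooled
#' codon counts of a host/reference CDS collection: within each synonymous
#' family, \eqn{w_c = x_c / \max_{c'} x_{c'}}, so the host's preferred codon
#' has weight 1. Zero reference counts are replaced by a pseudocount of 0.5
#' beforehand, keeping every weight strictly positive. Met, Trp and stop
#' codons receive \code{NA} weights: they carry no synonymous choice and are
#' excluded from CAI.
#'
#' @param host_counts Pooled codon counts over the host CDS collection:
#'   named numeric(64) or a \code{codon_counts} matrix (columns are summed).
#' @param code A \code{genetic_code}.
#' @return Named numeric(64) of weights in (0, 1] (\code{NA} for
#'   non-informative codons), with class \code{cai_weights} and attribute
#'   \code{pseudocounted} (codons that received the 0.5 pseudocount).
#' @examples
#' h <- setNames(numeric(64), standard_genetic_code()$codons)
#' h["AAA"] <- 8; h["AAG"] <- 2
#' w <- cai_weights(h); w[c("AAA", "AAG")]  # 1.0, 0.25
#' @export
cai_weights <- function(host_counts, code = standard_genetic_code()) {
  x <- pooled_codon_vector(host_counts, code)
  if (sum(x) == 0) stop("host reference has no codon counts")
  pseudo <- character(0)
  w <- rep(NA_real_, 64)
  names(w) <- code$codons
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    if (length(fam) < 2L) next
    xf <- x[fam]
    zero <- xf == 0
    if (any(zero)) {
      xf[zero] <- 0.5
      pseudo <- c(pseudo, fam[zero])
    }
    w[fam] <- xf / max(xf)
  }
  structure(w, class = "cai_weights", pseudocounted = pseudo)
}

#' Codon adaptation index (CAI) of one gene
#'
#' Geometric mean of the host relative-adaptiveness weights over the gene's
#' informative codons (Met, Trp and stops excluded):
#' \deqn{CAI = \exp\left(\frac{1}{L}\sum_c x_c \ln w_c\right).}
#' CAI = 1 means the gene uses the host-preferred codon at every synonymous
#' position.
#'
#' @param gene_counts One gene's codon counts (named numeric(64) or 1-row
#'   \code{codon_counts} matrix).
#' @param weights A \code{cai_weights} object from [cai_weights()].
#' @param code A \code{genetic_code}.
#' @return CAI in (0, 1], or \code{NA} if the gene has no informative codon.
#' @export
cai <- function(gene_counts, weights, code = standard_genetic_code()) {
  x <- as_codon_vector(gene_counts, code)
  use <- code$informative & x > 0 & !is.na(weights)
  L <- sum(x[use])
  if (L == 0) return(NA_real_)
  exp(sum(x[use] * log(weights[use])) / L)
}

#' Host within-family codon frequencies (for RCDI)
#'
#' Converts pooled host codon counts into within-family relative frequencies
#' \eqn{CiF_h(c) = x_c / \sum_{c' \in family} x_{c'}}, with a 0.5 pseudocount
#' on zero counts so every frequency is strictly positive. Frequencies sum to
#' 1 within each family (including the single-codon families Met and Trp,
#' whose frequency is 1).
#'
#' @inheritParams cai_weights
#' @return Named numeric(64) (\code{NA} for stops) with class
#'   \code{host_codon_frequencies}.
#' @export
host_codon_frequencies <- function(host_counts, code = standard_genetic_code()) {
  x <- pooled_codon_vector(host_counts, code)
  if (sum(x) == 0) stop("host reference has no codon counts")
  f <- rep(NA_real_, 64)
  names(f) <- code$codons
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    xf <- x[fam]
    xf[xf == 0] <- 0.5
    f[fam] <- xf / sum(xf)
  }
  structure(f, class = "host_codon_frequencies")
}

#' Relative codon deoptimization index (RCDI) of one gene
#'
#' Average ratio of the gene's within-family codon frequencies to the
#' host's, weighted by the gene's codon counts:
#' \deqn{RCDI = \frac{1}{N}\sum_c \frac{CiF_a(c)}{CiF_h(c)}\, x_c,}
#' where \eqn{CiF_a(c)} is the codon's relative frequency within its family
#' in the gene, \eqn{CiF_h(c)} the host's, and N the gene's codon total over
#' the families considered. RCDI = 1 means the gene's synonymous usage
#' matches the host exactly; larger values mean deoptimized usage. Only
#' multi-codon families contribute (single-codon families have ratio 1 by
#' construction and are excluded along with stops).
#'
#' @param gene_counts One gene's codon counts.
#' @param host A \code{host_codon_frequencies} object.
#' @param code A \code{genetic_code}.
#' @return RCDI (positive), or \code{NA} for an empty gene.
#' @export
rcdi <- function(gene_counts, host, code = standard_genetic_code()) {
  x <- as_codon_vector(gene_counts, code)
  num <- 0
  N <- 0
  for (a in names(code$families)) {
    fam <- code$families[[a]]
    if (length(fam) < 2L) next
    xf <- x[fam]
    n <- sum(xf)
    if (n == 0) next
    cif_a <- xf / n
    num <- num + sum(cif_a / host[fam] * xf)
    N <- N + n
  }
  if (N == 0) return(NA_real_)
  num / N
}

#' Codon-usage similarity index (SiD) between two organisms
#'
#' One minus the cosine similarity of two organism-level codon-usage
#' vectors, halved:
#' \deqn{R(A,B) = \frac{\sum a_i b_i}{\sqrt{\sum a_i^2 \sum b_i^2}},\qquad
#'       SiD = (1 - R)/2.}
#' SiD = 0 means identical usage direction; 0.5 is the maximum for
#' nonnegative vectors (orthogonal usage). The conventional input is each
#' organism's genome-level RSCU over the 59 informative codons (see
#' [organism_rscu()]); raw pooled codon frequencies are also accepted.
#'
#' @param query_usage,host_usage Nonnegative numeric vectors over the same
#'   codon set (names, if present, must match). Entries that are \code{NA}
#'   in either vector are dropped pairwise.
#' @return SiD in [0, 0.5].
#' @export
sid <- function(query_usage, host_usage) {
  if (!is.null(names(query_usage)) && !is.null(names(host_usage))) {
    shared <- intersect(names(query_usage), names(host_usage))
    if (length(shared) == 0L) stop("usage vectors share no codons")
    query_usage <- query_usage[shared]
    host_usage <- host_usage[shared]
  }
  if (length(query_usage) != length(host_usage)) {
    stop("usage vectors must have equal length")
  }
  ok <- !is.na(query_usage) & !is.na(host_usage)
  a <- as.numeric(query_usage[ok])
  b <- as.numeric(host_usage[ok])
  if (any(a < 0) || any(b < 0)) stop("usage vectors must be nonnegative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("usage vectors must not be all zero")
  (1 - sum(a * b) / (na * nb)) / 2
}

#' Organism-level RSCU vector from a codon count matrix
#'
#' Pools codon counts over all genes and computes genome-level RSCU,
#' restricted by default to the 59 informative codons — the standard input
#' for [sid()] and for the similarity screen's partner profile.
#'
#' @param counts A \code{codon_counts} matrix (or named 64-long vector of
#'   pooled counts).
#' @param code A \code{genetic_code}.
#' @param informative_only Drop Met/Trp/stop entries (default TRUE).
#' @return Named numeric RSCU vector.
#' @export
organism_rscu <- function(counts, code = standard_genetic_code(),
                          informative_only = TRUE) {
  x <- pooled_codon_vector(counts, code)
  r <- rscu(x, code)
  if (informative_only) r <- r[code$informative]
  r
}

pooled_codon_vector <- function(counts, code) {
  if (is.matrix(counts)) {
    if (!all(code$codons %in% colnames(counts))) {
      stop("count matrix must have all 64 codon columns")
    }
    counts <- colSums(counts[, code$codons, drop = FALSE])
  }
  as_codon_vector(counts, code)
}
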