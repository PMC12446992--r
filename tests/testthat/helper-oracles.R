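# Independent brute-force oracles for every index, kept deliberately naive
# and separate from the package implementation: plain loops over the genetic
# code, no shared helpers.

GC <- standard_genetic_code()

# amino acid of a codon, from Biostrings' code table directly
.aa_of <- function(codon) as.character(Biostrings::GENETIC_CODE[[codon]])

# synonymous family of a codon
.family_of <- function(codon) {
  a <- .aa_of(codon)
  GC$codons[vapply(GC$codons, .aa_of, character(1)) == a]
}

oracle_count_codons <- function(seq) {
  counts <- stats::setNames(integer(64), GC$codons)
  n <- nchar(seq)
  cods <- substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  if (cods[length(cods)] %in% c("TAA", "TAG", "TGA")) {
    cods <- cods[-length(cods)]
  }
  for (cd in cods) counts[cd] <- counts[cd] + 1L
  counts
}

oracle_rscu <- function(counts) {
  out <- stats::setNames(rep(NA_real_, 64), GC$codons)
  for (cd in GC$codons) {
    if (.aa_of(cd) == "*") next
    fam <- .family_of(cd)
    tot <- sum(counts[fam])
    if (tot > 0) out[cd] <- counts[cd] / (tot / length(fam))
  }
  out
}

oracle_enc <- function(counts) {
  fs <- list()
  aas <- unique(vapply(GC$codons[!GC$is_stop], .aa_of, character(1)))
  for (a in aas) {
    fam <- GC$codons[vapply(GC$codons, .aa_of, character(1)) == a]
    k <- length(fam)
    if (k < 2) next
    n <- sum(counts[fam])
    if (n < 2) next
    f <- (n * sum((counts[fam] / n)^2) - 1) / (n - 1)
    if (f > 0) fs[[length(fs) + 1]] <- c(k = k, f = f)
  }
  fm <- do.call(rbind, fs)
  fbar <- sapply(c(2, 3, 4, 6), function(k) {
    v <- fm[fm[, "k"] == k, "f"]
    if (length(v) == 0) NA_real_ else mean(v)
  })
  names(fbar) <- c("2", "3", "4", "6")
  if (is.na(fbar["3"])) fbar["3"] <- (fbar["2"] + fbar["4"]) / 2
  if (anyNA(fbar)) return(NA_real_)
  min(2 + 9 / fbar["2"] + 1 / fbar["3"] + 5 / fbar["4"] + 3 / fbar["6"], 61)
}

oracle_scuo <- function(counts) {
  num <- 0; N <- 0; terms <- list()
  aas <- unique(vapply(GC$codons[!GC$is_stop], .aa_of, character(1)))
  for (a in aas) {
    fam <- GC$codons[vapply(GC$codons, .aa_of, character(1)) == a]
    k <- length(fam)
    if (k < 2) next
    n <- sum(counts[fam])
    if (n == 0) next
    p <- counts[fam] / n
    p <- p[p > 0]
    h <- -sum(p * log2(p))
    terms[[a]] <- c(n = n, o = (log2(k) - h) / log2(k))
  }
  if (length(terms) == 0) return(NA_real_)
  tm <- do.call(rbind, terms)
  sum(tm[, "n"] / sum(tm[, "n"]) * tm[, "o"])
}

oracle_cai <- function(counts, host_counts) {
  # reference weights
  w <- stats::setNames(rep(NA_real_, 64), GC$codons)
  for (cd in GC$codons) {
    if (.aa_of(cd) == "*") next
    fam <- .family_of(cd)
    if (length(fam) < 2) next
    xf <- host_counts[fam]
    xf[xf == 0] <- 0.5
    w[cd] <- xf[cd] / max(xf)
  }
  logsum <- 0; L <- 0
  for (cd in GC$codons) {
    if (is.na(w[cd]) || counts[cd] == 0) next
    logsum <- logsum + counts[cd] * log(w[cd])
    L <- L + counts[cd]
  }
  if (L == 0) return(NA_real_)
  exp(logsum / L)
}

oracle_rcdi <- function(counts, host_counts) {
  total <- 0; N <- 0
  aas <- unique(vapply(GC$codons[!GC$is_stop], .aa_of, character(1)))
  for (a in aas) {
    fam <- GC$codons[vapply(GC$codons, .aa_of, character(1)) == a]
    if (length(fam) < 2) next
    hf <- host_counts[fam]
    hf[hf == 0] <- 0.5
    cifh <- hf / sum(hf)
    n <- sum(counts[fam])
    if (n == 0) next
    for (cd in fam) {
      total <- total + (counts[cd] / n) / cifh[cd] * counts[cd]
    }
    N <- N + n
  }
  if (N == 0) return(NA_real_)
  total / N
}

oracle_sid <- function(a, b) {
  (1 - sum(a * b) / sqrt(sum(a^2) * sum(b^2))) / 2
}

oracle_pr2 <- function(seq) {
  n <- nchar(seq)
  cods <- substring(seq, seq(1, n - 2, by = 3), seq(3, n, by = 3))
  if (cods[length(cods)] %in% c("TAA", "TAG", "TGA")) {
    cods <- cods[-length(cods)]
  }
  keep <- vapply(cods, .aa_of, character(1)) %in% c("A", "G", "P", "T", "V")
  third <- substring(cods[keep], 3, 3)
  g <- sum(third == "G"); c <- sum(third == "C")
  a <- sum(third == "A"); t <- sum(third == "T")
  list(x = if (g + c > 0) g / (g + c) else NA_real_,
       y = if (a + t > 0) a / (a + t) else NA_real_)
}

# Pearson r and two-sided p straight from the covariance formula + t CDF.
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  c(r = r, p = 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE), n = n)
}

# Random gene: draw codon counts from random positive usage, as a plain
# counts vector (not via the package generator).
random_gene_counts <- function(n_codons = 300) {
  probs <- stats::runif(61)
  sense <- GC$codons[!GC$is_stop]
  draws <- sample(sense, n_codons, replace = TRUE, prob = probs)
  counts <- stats::setNames(integer(64), GC$codons)
  tab <- table(draws)
  counts[names(tab)] <- as.integer(tab)
  counts
}

# Random valid CDS string (start codon, no internal stop, terminal stop).
random_cds <- function(n_codons = 100) {
  sense <- GC$codons[!GC$is_stop]
  paste0("ATG", paste(sample(sense, n_codons, replace = TRUE), collapse = ""),
         "TAA")
}
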