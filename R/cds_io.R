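#' Read a CDS FASTA file and apply quality control
#'
#' Reads a multi-record FASTA of coding sequences and retains those that look
#' like clean in-frame CDS: length divisible by 3, no internal stop codon,
#' no ambiguous base (strict mode), and at least \code{min_codons} codons
#' (terminal stop codon not counted). Sequence identifiers are the header
#' token before the first whitespace and must be unique.
#'
#' A terminal stop codon is allowed (and later excluded from codon counts);
#' sequences lacking one are kept, since CDS dumps are inconsistent about
#' including stops.
#'
#' @param fasta_path Path to a FASTA file.
#' @param min_codons Minimum number of codons (terminal stop excluded) a
#'   sequence must have to be retained. Default 30: shorter genes make ENC
#'   and RSCU unstable.
#' @param strict If TRUE (default), sequences containing ambiguous bases
#'   (anything outside A/C/G/T) are dropped; if FALSE they are retained and
#'   codons containing ambiguous bases are skipped at counting time.
#' @return A list with class \code{cds_set}:
#'   \describe{
#'     \item{sequences}{\code{Biostrings::DNAStringSet} of retained CDS, input
#'       order preserved.}
#'     \item{qc}{data.frame with columns \code{id}, \code{status}
#'       ("retained"/"removed"), \code{reason}.}
#'   }
#' @seealso [count_codons()], [base_composition()]
#' @export
read_and_qc <- function(fasta_path, min_codons = 30L, strict = TRUE) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("FASTA file contains no sequences: ", fasta_path)
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  qc_cds(seqs, min_codons = min_codons, strict = strict)
}

#' Apply CDS quality control to an in-memory sequence set
#'
#' Same filtering rules as [read_and_qc()], for sequences already loaded
#' (e.g. produced by the synthetic generator). Removal reasons, checked in
#' order per sequence: "not a codon multiple", "ambiguous base" (strict),
#' "internal stop", "too short".
#'
#' @param seqs Named \code{DNAStringSet} or named character vector.
#' @inheritParams read_and_qc
#' @return A \code{cds_set} list (see [read_and_qc()]).
#' @export
qc_cds <- function(seqs, min_codons = 30L, strict = TRUE) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("all sequences must carry a nonempty id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  gc <- standard_genetic_code()
  stops <- gc$codons[gc$is_stop]
  s <- as.character(seqs)
  reason <- rep(NA_character_, length(s))
  for (i in seq_along(s)) {
    x <- s[[i]]
    n <- nchar(x)
    if (n == 0L || n %% 3L != 0L) {
      reason[i] <- "not a codon multiple"
      next
    }
    ambiguous <- grepl("[^ACGT]", x)
    if (strict && ambiguous) {
      reason[i] <- "ambiguous base"
      next
    }
    cods <- substring(x, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
    ncod <- length(cods)
    internal_stop <- any(cods[-ncod] %in% stops)
    if (internal_stop) {
      reason[i] <- "internal stop"
      next
    }
    n_sense <- if (cods[ncod] %in% stops) ncod - 1L else ncod
    if (n_sense < min_codons) {
      reason[i] <- "too short"
      next
    }
  }
  keep <- is.na(reason)
  qc <- data.frame(
    id = ids,
    status = ifelse(keep, "retained", "removed"),
    reason = ifelse(keep, "", reason),
    stringsAsFactors = FALSE
  )
  structure(list(sequences = seqs[keep], qc = qc), class = "cds_set")
}

#' Count codons per gene
#'
#' Counts frame-0 codon occurrences for each sequence, returning a
#' genes x 64 integer matrix with codons in fixed alphabetical column order.
#' A terminal stop codon is excluded from the counts; internal codons
#' containing ambiguous bases (lenient QC mode) are skipped.
#'
#' @param cds A \code{cds_set} (from [read_and_qc()]/[qc_cds()]), a named
#'   \code{DNAStringSet}, or a named character vector of QC-passed CDS.
#' @param code A \code{genetic_code}; defaults to [standard_genetic_code()].
#' @return Integer matrix (genes x 64 codons) with class attribute
#'   \code{codon_counts}; rownames are gene ids, colnames codons.
#' @examples
#' count_codons(c(g1 = "ATGGCAGCATAA"))[1, c("ATG", "GCA")]
#' @export
count_codons <- function(cds, code = standard_genetic_code()) {
  seqs <- if (inherits(cds, "cds_set")) cds$sequences else cds
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (length(seqs) == 0L) {
    m <- matrix(0L, nrow = 0L, ncol = 64L,
                dimnames = list(NULL, code$codons))
    class(m) <- c("codon_counts", class(m))
    return(m)
  }
  # drop a terminal stop codon before counting
  stops <- code$codons[code$is_stop]
  last <- as.character(Biostrings::subseq(seqs, start = Biostrings::width(seqs) - 2L))
  trim <- ifelse(last %in% stops, 3L, 0L)
  seqs <- Biostrings::subseq(seqs, start = 1L,
                             end = Biostrings::width(seqs) - trim)
  m <- Biostrings::trinucleotideFrequency(seqs, step = 3L)
  m <- m[, code$codons, drop = FALSE]
  storage.mode(m) <- "integer"
  rownames(m) <- names(seqs)
  class(m) <- c("codon_counts", class(m))
  m
}

#' Positional base composition of a CDS
#'
#' Computes overall GC and per-codon-position GC fractions (GC1, GC2, GC3)
#' and third-position base counts, both over all codons and restricted to
#' codons of the fourfold-degenerate amino-acid families (Ala, Gly, Pro,
#' Thr, Val) — the restricted counts feed the PR2 parity plot, where base
#' choice at the third position is fully synonymous.
#'
#' A terminal stop codon is excluded, matching [count_codons()].
#'
#' @param seq A single CDS as a character string (QC-passed).
#' @param code A \code{genetic_code}.
#' @return A list with class \code{base_composition}: \code{gc}, \code{gc1},
#'   \code{gc2}, \code{gc3} (fractions over sense codons), \code{a3},
#'   \code{t3}, \code{g3}, \code{c3} (third-position counts, all sense
#'   codons) and \code{a3_4f} .. \code{c3_4f} (fourfold-family restricted).
#' @export
base_composition <- function(seq, code = standard_genetic_code()) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) {
    stop("sequence length must be a positive multiple of 3")
  }
  cods <- substring(seq, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  ncod <- length(cods)
  if (cods[ncod] %in% code$codons[code$is_stop]) {
    cods <- cods[-ncod]
  }
  if (length(cods) == 0L) stop("sequence contains no sense codons")
  pos <- function(k) substring(cods, k, k)
  frac_gc <- function(x) mean(x %in% c("G", "C"))
  p1 <- pos(1L); p2 <- pos(2L); p3 <- pos(3L)
  third_counts <- function(p) {
    c(a = sum(p == "A"), t = sum(p == "T"),
      g = sum(p == "G"), c = sum(p == "C"))
  }
  all3 <- third_counts(p3)
  is4f <- code$aa[cods] %in% FOURFOLD_AA
  ff3 <- third_counts(p3[is4f])
  structure(
    list(gc = frac_gc(c(p1, p2, p3)),
         gc1 = frac_gc(p1), gc2 = frac_gc(p2), gc3 = frac_gc(p3),
         a3 = unname(all3["a"]), t3 = unname(all3["t"]),
         g3 = unname(all3["g"]), c3 = unname(all3["c"]),
         a3_4f = unname(ff3["a"]), t3_4f = unname(ff3["t"]),
         g3_4f = unname(ff3["g"]), c3_4f = unname(ff3["c"]),
         n_codons = length(cods)),
    class = "base_composition"
  )
}

#' Write a QC report or codon count table to TSV
#'
#' @param x A \code{cds_set} QC data.frame or \code{codon_counts} matrix.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  if (inherits(x, "cds_set")) x <- x$qc
  if (is.matrix(x)) {
    x <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                    stringsAsFactors = FALSE)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
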