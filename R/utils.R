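# Shared low-level helpers: base encodings, codon tables, interval maths.
# All genomic coordinates in the package are 0-based half-open; conversion
# to 1-based inclusive happens only at the GFF3/BED boundary.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG")   # TGA is never treated as a stop here
SEC_CODON <- "TGA"

AA_LETTERS <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T","W","Y","V")

# integer encoding: A=1 C=2 G=3 T=4, anything else (N) = 5
seq_to_int <- function(seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], DNA_BASES)
  x[is.na(x)] <- 5L
  x
}

int_to_seq <- function(x) paste(c(DNA_BASES, "N")[x], collapse = "")

assert_dna <- function(seq, what = "sequence") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(seq)
}

# standard genetic code on DNA codons, with the option of decoding TGA as U
codon_table <- function(sec_readthrough = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  tab <- setNames(as.character(gc), chartr("U", "T", names(gc)))
  if (sec_readthrough) tab[["TGA"]] <- "U"
  tab
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("coding sequence length not divisible by 3", call. = FALSE)
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a coding sequence, reading in-frame TGA as selenocysteine
#'
#' Standard genetic code except that TGA is decoded as `U` (selenocysteine)
#' when `sec_readthrough` is `TRUE`. A terminal TAA/TAG stop, if present, is
#' dropped from the returned protein.
#'
#' @param cds Coding sequence (DNA, length divisible by 3).
#' @param sec_readthrough Decode TGA as `U` instead of a stop.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, sec_readthrough = TRUE) {
  assert_dna(cds, "cds")
  codons <- split_codons(toupper(cds))
  if (length(codons) && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
  }
  tab <- codon_table(sec_readthrough)
  aa <- tab[codons]
  if (anyNA(aa)) aa[is.na(aa)] <- "X"
  if (any(aa == "*")) {
    stop("internal stop codon in coding sequence", call. = FALSE)
  }
  paste(aa, collapse = "")
}

# interval helpers -----------------------------------------------------------

check_interval <- function(start, end, len = NULL) {
  if (any(start < 0L) || any(end <= start)) {
    stop("invalid interval: require 0 <= start < end", call. = FALSE)
  }
  if (!is.null(len) && any(end > len)) {
    stop("interval outside record bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Reflect an interval between a strand and its reverse complement
#'
#' Maps a 0-based half-open interval on one strand to the corresponding
#' interval on the reverse-complemented sequence of length `len`. The map
#' is an involution; it is how all minus-strand coordinates in the package
#' are produced.
#'
#' @param start,end Interval (0-based half-open); vectorised.
#' @param len Length of the sequence.
#' @return List with reflected `start` and `end` vectors.
#' @export
reflect_interval <- function(start, end, len) {
  list(start = len - end, end = len - start)
}

reflect_pos <- function(pos, width, len) len - pos - width

overlap_len <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2))
}

# total overlap between two exon sets given as start/end vectors
exon_set_overlap <- function(s1, e1, s2, e2) {
  tot <- 0L
  for (i in seq_along(s1)) {
    tot <- tot + sum(overlap_len(s1[i], e1[i], s2, e2))
  }
  tot
}

new_id <- function(prefix, i) sprintf("%s%04d", prefix, i)
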