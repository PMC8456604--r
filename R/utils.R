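# Small sequence utilities shared across modules. Coordinates are 0-based
# half-open internally; anything user-facing that prints positions says so.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA strings (A/C/G/T, case preserved).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), NULL)[[1L]]),
          collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Translate DNA in frame 1
#'
#' Standard genetic code; a trailing incomplete codon is dropped; codons
#' with ambiguous characters translate to "X"; stops are "*".
#'
#' @param dna a single DNA string.
#' @return a single amino-acid string.
#' @export
translate_dna <- function(dna) {
  stopifnot(length(dna) == 1L)
  n <- nchar(dna) %/% 3L
  if (n == 0L) return("")
  starts <- seq(1L, by = 3L, length.out = n)
  codons <- substring(toupper(dna), starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

# Random DNA of length n using the current RNG stream.
rand_dna <- function(n) {
  if (n == 0L) return("")
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Hamming distance of two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, NULL)[[1L]] != strsplit(b, NULL)[[1L]])
}

# Substitute k random positions (or each position with prob `rate`) by a
# different base. Returns the mutated string.
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (n == 0L || rate <= 0) return(seq)
  k <- stats::rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  ch <- strsplit(seq, NULL)[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# All match start positions (1-based) of a regex, allowing overlaps.
regex_starts <- function(pattern, x) {
  m <- gregexpr(paste0("(?=", pattern, ")"), x, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Degenerate CDR3 anchor motifs, exactly as used throughout the package:
# V side encodes Tyr-(Tyr/His)-Cys ending at the 2nd conserved cysteine,
# J side encodes Phe-Gly-X-Gly.
CDR3_V_MOTIF <- "TAC[TC]A[TC]TG[TC]"
CDR3_J_MOTIF <- "TT[CT]GG[CA][AT][CG][AT]GG[AT]"

`%||%` <- function(a, b) if (is.null(a)) b else a
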