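# Shared fixtures, built once per test run.

trg_db <- synthetic_germline_db()

# a small in-frame V segment built by hand for anchor/classification toys:
# FR1 23 codons ending TGT (C23), CDR1 12, FR2 17 with TGG at codon 41,
# CDR2 10, FR3 42 ending TAC TAT TGT (C104), 6-nt tail
make_toy_v <- function(fr3_tail = "TACTATTGT", w41 = "TGG",
                       stop_codon = NULL) {
  safe <- "GCT"                                 # Ala filler codon
  cods <- rep(safe, 104L)
  cods[23L] <- "TGT"
  cods[41L] <- w41
  cods[102:104] <- c(substr(fr3_tail, 1, 3), substr(fr3_tail, 4, 6),
                     substr(fr3_tail, 7, 9))
  if (!is.null(stop_codon)) cods[stop_codon] <- "TAA"
  seq_nt <- paste0(paste(cods, collapse = ""), "ACGTAG")
  seg <- list(
    id = "Vtoy", kind = "V", subgroup = NA_character_,
    functionality = "functional", seq_nt = seq_nt,
    leader_nt = paste0("ATG", strrep("GCT", 14L)),
    regions = list(FR1 = c(0L, 69L), CDR1 = c(69L, 105L),
                   FR2 = c(105L, 156L), CDR2 = c(156L, 186L),
                   FR3 = c(186L, 312L)),
    rss = list(spacer_len = 23L, heptamer_pos = NA_integer_,
               side = "three_prime"),
    locus = NULL
  )
  class(seg) <- "germline_segment"
  seg
}

# tiny clonotype table for stats toys
toy_clonotypes <- function() {
  data.frame(
    sequence_id = sprintf("c%d", 1:4),
    sample_id = c("S1", "S1", "S1", "S1"),
    v_call = c("Va", "Va", "Vb", "Vc"),
    j_call = c("J1", "J2", "J1", "J1"),
    cdr3 = c("GCTAGGTCAGAT", "GCTAGGTCAGATGCTAGGTCAGAT",
             "GCTGCTGCT", "GCTAGGTCAGATGCTAGGTCAGATGCTAGGTCAGAT"),
    cdr3_aa = c("ARSD", "ARSDARSD", "AAA", "ARSDARSDARSD"),
    productive = TRUE,
    duplicate_count = c(2L, 1L, 1L, 4L),
    sequence = "",
    stringsAsFactors = FALSE
  )
}
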