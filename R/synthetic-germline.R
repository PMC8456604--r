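# Synthetic germline database generator.
#
# The published chicken TRG germline inventory (44 V segments in six
# subgroups of 6/19/9/4/3/3 members with 28 functional, three functional J
# segments, one C gene) is reproduced here in *structure* with generated
# sequences: real germline sequences are not bundled. Sequences are
# engineered to satisfy the same classification criteria the annotation
# module implements (anchor residues, reading frame, subgroup identity
# >= 70% within and < 70% between subgroups), so the classifier and the
# clusterer can be exercised end to end. The packaged fixture files under
# inst/extdata (chicken-trg-synthetic.*) are written by this generator.

# V-REGION architecture used throughout the synthetic database, in codons:
# FR1 23 (ends at the 1st conserved Cys, position 23), CDR1 12, FR2 17
# (conserved Trp at position 41), CDR2 10, FR3 42 (ends Tyr-Tyr-Cys at
# positions 102-104), plus a short 3' germline-CDR3 tail after Cys104.
SYNTH_FR_CODONS <- c(FR1 = 23L, CDR1 = 12L, FR2 = 17L, CDR2 = 10L, FR3 = 42L)

SYNTH_SUBGROUPS <- list(
  list(name = "Vg1", n = 6L, tail = 7L, orf = c(1L, 5L), pseudo = 4L),
  list(name = "Vg2", n = 19L, tail = 7L, orf = 18L,
       pseudo = c(7L, 9L, 10L, 11L)),
  list(name = "Vg3", n = 9L, tail = 15L, orf = integer(0), pseudo = 5L),
  list(name = "Vg4", n = 4L, tail = 5L, orf = integer(0), pseudo = 4L),
  list(name = "Vg5", n = 3L, tail = 7L, orf = integer(0),
       pseudo = c(1L, 2L, 3L)),
  list(name = "Vg6", n = 3L, tail = 7L, orf = integer(0),
       pseudo = c(1L, 2L, 3L))
)

# non-stop codons
synth_codon_pool <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# run code with a locally seeded RNG, restoring the caller's stream
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# TRUE when the segment's 3' half is safe for anchor-based CDR3
# extraction: the Tyr-(Tyr/His)-Cys motif occurs exactly once at the FR3
# terminus in the 3' half, and no Phe-Gly-X-Gly match sits at or after the
# anchor.
synth_v_ok <- function(seq_nt, fr3_end) {
  anchor_start <- fr3_end - 9L + 1L                # 1-based
  tail_region <- substr(seq_nt, 250L, nchar(seq_nt))
  vhits <- regex_starts(CDR3_V_MOTIF, tail_region) + 249L
  if (!identical(vhits, anchor_start)) return(FALSE)
  jhits <- regex_starts(CDR3_J_MOTIF, seq_nt)
  !any(jhits >= anchor_start)
}

synth_make_member <- function(anc_codons, tail_nt, mut_rate, protected,
                              pool) {
  repeat {
    cod <- anc_codons
    for (k in seq_along(cod)) {
      if (k %in% protected) next
      if (stats::runif(1) < mut_rate) cod[k] <- sample(pool, 1L)
    }
    tl <- strsplit(tail_nt, NULL)[[1L]]
    for (k in seq_along(tl)) {
      if (stats::runif(1) < mut_rate) {
        tl[k] <- sample(setdiff(DNA_BASES, tl[k]), 1L)
      }
    }
    seq_nt <- paste0(paste(cod, collapse = ""), paste(tl, collapse = ""))
    fr3_end <- 3L * sum(SYNTH_FR_CODONS)
    # no stop in any complete codon of the tail
    tail_codons <- translate_dna(substr(seq_nt, fr3_end + 1L,
                                        nchar(seq_nt)))
    if (grepl("*", tail_codons, fixed = TRUE)) next
    if (synth_v_ok(seq_nt, fr3_end)) return(seq_nt)
  }
}

#' Synthetic germline database shaped like the chicken TRG locus
#'
#' Deterministically generates a germline database with the published
#' inventory structure: 44 V segments in six subgroups (6, 19, 9, 4, 3, 3
#' members; 28 functional, 3 ORF, 13 pseudogenes), three functional J
#' segments and a single C gene. ORF members carry an intact frame with
#' the conserved tryptophan replaced; pseudogenes carry an internal stop
#' (one member instead carries a 1-nt frameshift deletion). Sequences are
#' synthetic; only the structure and the classification criteria mirror
#' the real locus.
#'
#' @param seed integer seed for the generator (fixed default so the
#'   packaged fixture is reproducible).
#' @return a validated `germline_db`.
#' @seealso [write_germline_fixture()]
#' @export
synthetic_germline_db <- function(seed = 20210921L) {
  with_local_seed(seed, {
    # Trp codons only at the protected position 41, so breaking that codon
    # reliably removes the conserved W from FR2
    pool <- setdiff(synth_codon_pool(), "TGG")
    nfr <- SYNTH_FR_CODONS
    ncod <- sum(nfr)
    fr3_end <- 3L * ncod
    c23 <- nfr[["FR1"]]                               # codon 23
    w41 <- nfr[["FR1"]] + nfr[["CDR1"]] + 6L          # codon 41, in FR2
    protected <- c(c23, w41, ncod - 2L, ncod - 1L, ncod)

    fasta <- character(0)
    meta <- list()
    v_start <- 90000L                                # 3'-most V locus start
    for (sg in SYNTH_SUBGROUPS) {
      # subgroup ancestor
      repeat {
        cod <- sample(pool, ncod, replace = TRUE)
        cod[c23] <- "TGT"
        cod[w41] <- "TGG"
        cod[(ncod - 2L):ncod] <- c("TAC", "TAT", "TGT")
        tail_nt <- rand_dna(sg$tail)
        anc <- paste0(paste(cod, collapse = ""), tail_nt)
        if (synth_v_ok(anc, fr3_end) &&
            !grepl("*", translate_dna(substr(anc, 1L, fr3_end)),
                   fixed = TRUE)) break
      }
      leader <- paste0("ATG", paste(sample(pool, 14L, replace = TRUE),
                                    collapse = ""))

      for (m in seq_len(sg$n)) {
        id <- sprintf("%s.%d", sg$name, m)
        seq_nt <- synth_make_member(cod, tail_nt, 0.15, protected, pool)
        func <- "functional"
        bounds <- cumsum(c(0L, nfr)) * 3L             # region boundaries
        if (m %in% sg$orf) {
          func <- "ORF"
          substr(seq_nt, (w41 - 1L) * 3L + 1L, w41 * 3L) <- "CTG"
        } else if (m %in% sg$pseudo) {
          func <- "pseudo"
          if (id == "Vg1.4") {
            # frameshift: delete one nt inside FR2
            seq_nt <- paste0(substr(seq_nt, 1L, 149L),
                             substr(seq_nt, 151L, nchar(seq_nt)))
            bounds[4:6] <- bounds[4:6] - 1L
          } else {
            stop_at <- nfr[["FR1"]] + nfr[["CDR1"]] + nfr[["FR2"]] + 5L
            substr(seq_nt, (stop_at - 1L) * 3L + 1L, stop_at * 3L) <- "TAA"
          }
        }
        start <- v_start
        v_start <- v_start - 1500L
        fasta[id] <- paste0(leader, seq_nt)
        meta[[id]] <- data.frame(
          id = id, kind = "V", subgroup = sg$name, functionality = func,
          leader_end = nchar(leader),
          fr1_start = bounds[1L], fr1_end = bounds[2L],
          cdr1_end = bounds[3L], fr2_end = bounds[4L],
          cdr2_end = bounds[5L], fr3_end = bounds[6L],
          rss_heptamer_pos = NA_integer_, rss_spacer = 23L,
          contig = "TRG_synthetic", start = start,
          end = start + nchar(leader) + nchar(seq_nt), strand = "+",
          stringsAsFactors = FALSE
        )
      }
    }

    # J segments: 8-nt germline CDR3 contribution, a Phe-Gly-X-Gly motif
    # variant, then a 36-nt in-frame tail.
    j_motifs <- c(Jg1 = "TTCGGCACAGGA", Jg2 = "TTTGGAAGTGGT",
                  Jg3 = "TTTGGCTCAGGA")
    j_start <- 93000L
    for (jn in names(j_motifs)) {
      repeat {
        j5 <- rand_dna(8L)
        jtail <- paste(sample(pool, 12L, replace = TRUE), collapse = "")
        jseq <- paste0(j5, j_motifs[[jn]], jtail)
        ok <- identical(regex_starts(CDR3_J_MOTIF, jseq), 9L) &&
          !length(regex_starts(CDR3_V_MOTIF, jseq)) &&
          !grepl("*", translate_dna(substr(jseq, 9L, nchar(jseq))),
                 fixed = TRUE)
        if (ok) break
      }
      fasta[jn] <- jseq
      meta[[jn]] <- data.frame(
        id = jn, kind = "J", subgroup = NA_character_,
        functionality = "functional", leader_end = 0L,
        fr1_start = NA_integer_, fr1_end = NA_integer_,
        cdr1_end = NA_integer_, fr2_end = NA_integer_,
        cdr2_end = NA_integer_, fr3_end = NA_integer_,
        rss_heptamer_pos = NA_integer_, rss_spacer = 12L,
        contig = "TRG_synthetic", start = j_start,
        end = j_start + nchar(jseq), strand = "+",
        stringsAsFactors = FALSE
      )
      j_start <- j_start + 400L
    }

    cseq <- paste(sample(pool, 50L, replace = TRUE), collapse = "")
    fasta["Cg"] <- cseq
    meta[["Cg"]] <- data.frame(
      id = "Cg", kind = "C", subgroup = NA_character_,
      functionality = "functional", leader_end = 0L,
      fr1_start = NA_integer_, fr1_end = NA_integer_, cdr1_end = NA_integer_,
      fr2_end = NA_integer_, cdr2_end = NA_integer_, fr3_end = NA_integer_,
      rss_heptamer_pos = NA_integer_, rss_spacer = NA_integer_,
      contig = "TRG_synthetic", start = 95000L,
      end = 95000L + nchar(cseq), strand = "+", stringsAsFactors = FALSE
    )

    build_germline_db(fasta, do.call(rbind, meta))
  })
}

#' Write the synthetic germline fixture files
#'
#' Writes `chicken-trg-synthetic.fasta` and `chicken-trg-synthetic.tsv`
#' (the format read by [read_germline_db()]) to a directory.
#'
#' @param dir output directory (created if missing).
#' @param seed generator seed, as in [synthetic_germline_db()].
#' @return invisibly, the two file paths.
#' @export
write_germline_fixture <- function(dir, seed = 20210921L) {
  db <- synthetic_germline_db(seed)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fasta_path <- file.path(dir, "chicken-trg-synthetic.fasta")
  meta_path <- file.path(dir, "chicken-trg-synthetic.tsv")
  recs <- vapply(db$segments, function(s) paste0(s$leader_nt, s$seq_nt),
                 character(1L))
  writeLines(paste0(">", names(recs), "\n", recs), fasta_path)
  utils::write.table(db$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta_path, metadata = meta_path))
}

#' Path to the packaged synthetic germline fixture
#'
#' @return named character vector with the `fasta` and `metadata` paths of
#'   the bundled synthetic chicken TRG germline database.
#' @export
germline_fixture_path <- function() {
  c(fasta = system.file("extdata", "chicken-trg-synthetic.fasta",
                        package = "tcrgamma", mustWork = TRUE),
    metadata = system.file("extdata", "chicken-trg-synthetic.tsv",
                           package = "tcrgamma", mustWork = TRUE))
}
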