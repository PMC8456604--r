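# Germline V/J/C segment modelling for the TCR gamma locus.
#
# A germline database couples a FASTA of coding sequences (leader + V-REGION
# for V segments, J-REGION for J, concatenated exons for C) with a metadata
# table carrying functionality calls, IMGT-style region boundaries and locus
# coordinates. All stored intervals are 0-based half-open.

RSS_HEPTAMER <- "CACAGTG"
RSS_NONAMER <- "ACAAAAACC"

GERMLINE_META_COLS <- c(
  "id", "kind", "subgroup", "functionality", "leader_end",
  "fr1_start", "fr1_end", "cdr1_end", "fr2_end", "cdr2_end", "fr3_end",
  "rss_heptamer_pos", "rss_spacer", "contig", "start", "end", "strand"
)

#' Read a germline V/J/C segment database
#'
#' Loads a segment FASTA plus its tab-separated metadata table and validates
#' the database: ids must be unique and present in both files, region
#' intervals must be ordered and lie within the sequence, functional V
#' segments must translate without internal stops and carry the conserved
#' anchor residues, and functional J segments must contain the
#' Phe-Gly-X-Gly nucleotide motif.
#'
#' The FASTA record of a V segment is leader plus V-REGION; `leader_end`
#' marks the boundary (0 when there is no leader in the record). Region
#' columns (`fr1_start` .. `fr3_end`) are 0-based half-open offsets on the
#' V-REGION itself.
#'
#' @param fasta_path path to the segment FASTA.
#' @param metadata_path path to the tab-separated metadata table with
#'   columns `id, kind, subgroup, functionality, leader_end, fr1_start,
#'   fr1_end, cdr1_end, fr2_end, cdr2_end, fr3_end, rss_heptamer_pos,
#'   rss_spacer, contig, start, end, strand` (empty where not applicable).
#' @return an object of class `germline_db`: a list with `segments`
#'   (named list, one entry per segment) and `meta` (the metadata
#'   data.frame). A database without at least one functional V and one
#'   functional J is valid but flagged unusable for the read pipeline
#'   (attribute `pipeline_ready`, plus a warning).
#' @export
read_germline_db <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  names(seqs) <- ids
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  missing_cols <- setdiff(GERMLINE_META_COLS, names(meta))
  if (length(missing_cols)) {
    stop("germline metadata is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  build_germline_db(stats::setNames(as.character(seqs), ids), meta)
}

# Shared constructor/validator used by read_germline_db() and the synthetic
# database generator.
build_germline_db <- function(seqs, meta) {
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate metadata id(s): ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  no_meta <- setdiff(ids, meta$id)
  if (length(no_meta)) {
    stop("FASTA record(s) without metadata row: ",
         paste(no_meta, collapse = ", "))
  }
  no_seq <- setdiff(meta$id, ids)
  if (length(no_seq)) {
    stop("metadata row(s) without FASTA record: ",
         paste(no_seq, collapse = ", "))
  }

  segments <- vector("list", nrow(meta))
  names(segments) <- meta$id
  for (i in seq_len(nrow(meta))) {
    row <- meta[i, ]
    rec <- toupper(seqs[[row$id]])
    kind <- row$kind
    if (!kind %in% c("V", "J", "C")) {
      stop("segment ", row$id, ": kind must be V, J or C")
    }
    leader_end <- if (is.na(row$leader_end)) 0L else as.integer(row$leader_end)
    if (leader_end < 0L || leader_end > nchar(rec)) {
      stop("segment ", row$id, ": leader_end outside record")
    }
    leader_nt <- substr(rec, 1L, leader_end)
    seq_nt <- substr(rec, leader_end + 1L, nchar(rec))

    regions <- NULL
    if (kind == "V") {
      bounds <- as.integer(c(row$fr1_start, row$fr1_end, row$cdr1_end,
                             row$fr2_end, row$cdr2_end, row$fr3_end))
      if (anyNA(bounds)) {
        stop("segment ", row$id, ": V segment with malformed/missing ",
             "region boundaries")
      }
      if (any(diff(bounds) < 0L) || bounds[1L] < 0L ||
          bounds[6L] > nchar(seq_nt)) {
        stop("segment ", row$id, ": region intervals must be ordered, ",
             "non-overlapping and within the V-REGION")
      }
      regions <- list(
        FR1 = c(bounds[1L], bounds[2L]), CDR1 = c(bounds[2L], bounds[3L]),
        FR2 = c(bounds[3L], bounds[4L]), CDR2 = c(bounds[4L], bounds[5L]),
        FR3 = c(bounds[5L], bounds[6L])
      )
    }

    rss <- NULL
    if (!is.na(row$rss_spacer)) {
      spacer <- as.integer(row$rss_spacer)
      if (!spacer %in% c(12L, 23L)) {
        stop("segment ", row$id, ": RSS spacer must be 12 or 23")
      }
      rss <- list(
        spacer_len = spacer,
        heptamer_pos = if (is.na(row$rss_heptamer_pos)) NA_integer_ else
          as.integer(row$rss_heptamer_pos),
        side = if (kind == "V") "three_prime" else "five_prime"
      )
    }

    locus <- NULL
    if (!is.na(row$contig)) {
      locus <- list(contig = row$contig, start = as.integer(row$start),
                    end = as.integer(row$end), strand = row$strand)
    }

    seg <- list(
      id = row$id, kind = kind,
      subgroup = if (is.na(row$subgroup)) NA_character_ else row$subgroup,
      functionality = row$functionality,
      seq_nt = seq_nt, leader_nt = leader_nt,
      regions = regions, rss = rss, locus = locus
    )
    class(seg) <- "germline_segment"

    if (kind == "V" && identical(row$functionality, "functional")) {
      rep <- validate_anchor_residues(seg)
      orf <- paste0(leader_nt, substr(seq_nt, regions$FR1[1L] + 1L,
                                      regions$FR3[2L]))
      aa <- translate_dna(orf)
      if (rep$frameshift || grepl("*", aa, fixed = TRUE)) {
        stop("segment ", row$id, ": declared functional but reading frame ",
             "is broken")
      }
      if (!(rep$C23_present && rep$W41_present && rep$C104_present)) {
        stop("segment ", row$id, ": declared functional but conserved ",
             "anchor residue(s) absent")
      }
    }
    if (kind == "J" && identical(row$functionality, "functional") &&
        !grepl(CDR3_J_MOTIF, seq_nt)) {
      stop("segment ", row$id, ": functional J without Phe-Gly-X-Gly motif")
    }
    segments[[row$id]] <- seg
  }

  db <- structure(list(segments = segments, meta = meta),
                  class = "germline_db")
  n_func_v <- sum(meta$kind == "V" & meta$functionality == "functional")
  n_func_j <- sum(meta$kind == "J" & meta$functionality == "functional")
  ready <- n_func_v >= 1L && n_func_j >= 1L
  attr(db, "pipeline_ready") <- ready
  if (!ready) {
    warning("germline database lacks a functional V and/or J segment; ",
            "valid, but unusable for the read pipeline", call. = FALSE)
  }
  db
}

#' @export
print.germline_db <- function(x, ...) {
  m <- x$meta
  cat("Germline TCR gamma segment database\n")
  for (k in c("V", "J", "C")) {
    sel <- m$kind == k
    if (!any(sel)) next
    cat(sprintf("  %s: %d segments (%d functional)\n", k, sum(sel),
                sum(sel & m$functionality == "functional")))
  }
  if (any(m$kind == "V" & !is.na(m$subgroup))) {
    tab <- table(m$subgroup[m$kind == "V"])
    cat("  V subgroups:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract segments from a germline database
#'
#' @param db a `germline_db`.
#' @param kind optional filter, one of "V", "J", "C".
#' @param functionality optional filter ("functional", "ORF", "pseudo").
#' @return named list of segments.
#' @export
germline_segments <- function(db, kind = NULL, functionality = NULL) {
  segs <- db$segments
  if (!is.null(kind)) {
    segs <- Filter(function(s) s$kind %in% kind, segs)
  }
  if (!is.null(functionality)) {
    segs <- Filter(function(s) s$functionality %in% functionality, segs)
  }
  segs
}

#' Check conserved V anchor residues
#'
#' Translates a V segment in the frame annotated by its region map and
#' reports whether the three conserved anchors are present: the first
#' cysteine (last codon of FR1, IMGT position 23), the conserved tryptophan
#' (within FR2, IMGT position 41) and the second cysteine (last codon of
#' FR3, IMGT position 104). If the annotated span is incompatible with the
#' reading frame, all anchors are reported absent and `frameshift` is set.
#'
#' @param seg a V `germline_segment` with region annotations.
#' @return list with logicals `C23_present`, `W41_present`, `C104_present`,
#'   the amino-acid positions checked (`C23_pos`, `C104_pos`, 1-based), and
#'   a `frameshift` flag.
#' @export
validate_anchor_residues <- function(seg) {
  if (!identical(seg$kind, "V")) {
    stop("anchor validation applies to V segments only")
  }
  if (is.null(seg$regions)) {
    stop("segment ", seg$id, ": region annotation missing")
  }
  r <- seg$regions
  fr1 <- r$FR1; fr2 <- r$FR2; fr3 <- r$FR3
  span_ok <- (fr3[2L] - fr1[1L]) %% 3L == 0L &&
    (fr1[2L] - fr1[1L]) %% 3L == 0L &&
    (fr2[1L] - fr1[1L]) %% 3L == 0L && (fr2[2L] - fr1[1L]) %% 3L == 0L
  if (!span_ok) {
    return(list(C23_present = FALSE, W41_present = FALSE,
                C104_present = FALSE, C23_pos = NA_integer_,
                C104_pos = NA_integer_, frameshift = TRUE))
  }
  aa <- translate_dna(substr(seg$seq_nt, fr1[1L] + 1L, fr3[2L]))
  aachr <- strsplit(aa, NULL)[[1L]]
  c23_pos <- (fr1[2L] - fr1[1L]) %/% 3L            # last codon of FR1
  c104_pos <- (fr3[2L] - fr1[1L]) %/% 3L           # last codon of FR3
  fr2_aa <- aachr[seq.int((fr2[1L] - fr1[1L]) %/% 3L + 1L,
                          (fr2[2L] - fr1[1L]) %/% 3L)]
  list(
    C23_present = identical(aachr[c23_pos], "C"),
    W41_present = "W" %in% fr2_aa,
    C104_present = identical(aachr[c104_pos], "C"),
    C23_pos = c23_pos, C104_pos = c104_pos,
    frameshift = FALSE
  )
}

#' Classify V segment functionality
#'
#' IMGT-style three-way call. `pseudo` when the reading frame across
#' leader + V-REGION is broken (frameshift or internal stop); `ORF` when
#' the frame is intact but a conserved anchor residue is missing, or (with
#' `require_rss = TRUE`) no RSS annotation is present; `functional`
#' otherwise.
#'
#' @param seg a V `germline_segment`.
#' @param require_rss also demand an RSS annotation for a functional call.
#' @return one of "functional", "ORF", "pseudo".
#' @export
classify_functionality <- function(seg, require_rss = FALSE) {
  anchors <- validate_anchor_residues(seg)
  broken <- anchors$frameshift
  if (!broken) {
    orf <- paste0(seg$leader_nt,
                  substr(seg$seq_nt, seg$regions$FR1[1L] + 1L,
                         seg$regions$FR3[2L]))
    if (nchar(seg$leader_nt) %% 3L != 0L) {
      broken <- TRUE
    } else if (grepl("*", translate_dna(orf), fixed = TRUE)) {
      broken <- TRUE
    }
  }
  if (broken) return("pseudo")
  if (!(anchors$C23_present && anchors$W41_present &&
        anchors$C104_present)) {
    return("ORF")
  }
  if (require_rss && is.null(seg$rss)) return("ORF")
  "functional"
}

#' Scan for recombination signal sequences
#'
#' Slides the canonical heptamer (CACAGTG) and nonamer (ACAAAAACC) with a
#' fixed 12- or 23-nt spacer across a sequence and reports every offset
#' where both motifs are within their mismatch budgets. For
#' `side = "three_prime"` (the V side) the given strand is scanned as
#' written, heptamer first. For `side = "five_prime"` (the J side, where
#' the RSS lies upstream in reverse orientation) the reverse complement of
#' the input is scanned and positions refer to that reverse-complemented
#' sequence.
#'
#' @param dna a single DNA string.
#' @param side "three_prime" or "five_prime".
#' @param spacer_len 12 or 23.
#' @param max_mismatch_heptamer,max_mismatch_nonamer mismatch budgets.
#' @return data.frame with one row per hit (`position` is the 0-based
#'   heptamer offset on the scanned strand), sorted by total mismatches
#'   then position. Zero rows when the sequence is shorter than the motif
#'   span.
#' @export
scan_rss <- function(dna, side = c("three_prime", "five_prime"),
                     spacer_len = 12L, max_mismatch_heptamer = 2L,
                     max_mismatch_nonamer = 3L) {
  side <- match.arg(side)
  stopifnot(spacer_len %in% c(12L, 23L))
  subject <- toupper(if (side == "five_prime") revcomp(dna) else dna)
  span <- 7L + spacer_len + 9L
  n <- nchar(subject)
  empty <- data.frame(
    position = integer(0), side = character(0), spacer_len = integer(0),
    heptamer = character(0), nonamer = character(0),
    heptamer_mismatches = integer(0), nonamer_mismatches = integer(0),
    stringsAsFactors = FALSE
  )
  if (n < span) return(empty)

  ch <- strsplit(subject, NULL)[[1L]]
  hep <- strsplit(RSS_HEPTAMER, NULL)[[1L]]
  non <- strsplit(RSS_NONAMER, NULL)[[1L]]
  offsets <- 0:(n - span)                      # 0-based heptamer offsets
  hmm <- integer(length(offsets))
  for (k in 1:7) hmm <- hmm + (ch[offsets + k] != hep[k])
  nmm <- integer(length(offsets))
  for (k in 1:9) nmm <- nmm + (ch[offsets + 7L + spacer_len + k] != non[k])
  keep <- hmm <= max_mismatch_heptamer & nmm <= max_mismatch_nonamer
  if (!any(keep)) return(empty)
  pos <- offsets[keep]
  out <- data.frame(
    position = pos, side = side, spacer_len = spacer_len,
    heptamer = substring(subject, pos + 1L, pos + 7L),
    nonamer = substring(subject, pos + 7L + spacer_len + 1L, pos + span),
    heptamer_mismatches = hmm[keep], nonamer_mismatches = nmm[keep],
    stringsAsFactors = FALSE
  )
  out[order(out$heptamer_mismatches + out$nonamer_mismatches,
            out$position), , drop = FALSE]
}

# Global (end-gap-penalized) alignment identity: matches / alignment
# columns, in [0, 1].
alignment_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  cols <- nchar(as.character(Biostrings::pattern(aln)))
  Biostrings::nmatch(aln) / cols
}

#' Cluster V segments into subgroups by nucleotide identity
#'
#' Computes pairwise global-alignment nucleotide identity over the
#' FR1-start .. FR3-end span of each V segment (the span conventionally
#' used for tree building) and single-linkage clusters at the given
#' threshold (inclusive). Subgroup labels "1", "2", ... are assigned by
#' the 3' to 5' locus order of each cluster's first member, matching the
#' naming direction used for the locus; segments without locus coordinates
#' fall back to input order.
#'
#' @param v_segments list of V `germline_segment`s, or a `germline_db`
#'   (its V segments are used).
#' @param identity_threshold minimum within-subgroup identity (default
#'   0.70, inclusive).
#' @return named character vector mapping segment id to subgroup label.
#'   Segments lacking region annotation are excluded and reported in the
#'   `excluded` attribute.
#' @export
cluster_subgroups <- function(v_segments, identity_threshold = 0.70) {
  if (inherits(v_segments, "germline_db")) {
    v_segments <- germline_segments(v_segments, kind = "V")
  }
  has_regions <- vapply(v_segments, function(s) !is.null(s$regions),
                        logical(1L))
  excluded <- vapply(v_segments[!has_regions], `[[`, character(1L), "id")
  segs <- v_segments[has_regions]
  n <- length(segs)
  if (n == 0L) {
    out <- character(0)
    attr(out, "excluded") <- unname(excluded)
    return(out)
  }
  ids <- vapply(segs, `[[`, character(1L), "id")
  frs <- vapply(segs, function(s) {
    substr(s$seq_nt, s$regions$FR1[1L] + 1L, s$regions$FR3[2L])
  }, character(1L))

  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1L) {
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        if (alignment_identity(frs[i], frs[j]) >= identity_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1L))

  # 3' -> 5' rank: on '+' strand the 3'-most segment has the largest start.
  rank3p <- vapply(seq_len(n), function(i) {
    loc <- segs[[i]]$locus
    if (is.null(loc) || is.na(loc$start)) return(as.numeric(i))
    if (identical(loc$strand, "-")) as.numeric(loc$start)
    else -as.numeric(loc$start)
  }, numeric(1L))
  ord <- order(rank3p)
  label_of_root <- list()
  nxt <- 1L
  labels <- character(n)
  for (i in ord) {
    key <- as.character(roots[i])
    if (is.null(label_of_root[[key]])) {
      label_of_root[[key]] <- as.character(nxt)
      nxt <- nxt + 1L
    }
  }
  for (i in seq_len(n)) labels[i] <- label_of_root[[as.character(roots[i])]]
  out <- stats::setNames(labels, ids)
  attr(out, "excluded") <- unname(excluded)
  out
}
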