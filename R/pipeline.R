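# Read-processing chain for 5' RACE TCR gamma amplicons: merge read pairs,
# demultiplex by the 12-nt barcode, dereplicate, assign germline V/J by
# seeded local alignment, filter pseudo/ORF assignments, extract CDR3 by
# the degenerate anchor motifs, classify productivity, and collapse to
# clonotypes.

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  # Biostrings warns that FASTQ metadata columns are dropped; we only
  # need id/seq/qual
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = as.character(x),
    qual = as.character(Biostrings::quality(x)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Merge an overlapping read pair
#'
#' Finds the largest overlap between R1 and the reverse complement of R2
#' whose mismatch ratio does not exceed `max_mismatch_ratio`, seeding the
#' search with exact 16-mers of the reverse-complemented R2 and falling
#' back to an exhaustive overlap scan when no seed survives. At
#' mismatching overlap positions the consensus takes the base with the
#' higher quality (R1 on ties).
#'
#' @param r1,r2 read sequences.
#' @param qual1,qual2 quality strings (optional; constant quality
#'   assumed when absent).
#' @param min_overlap minimum admissible overlap (default 10).
#' @param max_mismatch_ratio maximum mismatches/overlap (default 0.25).
#' @return list with `merged` (logical); when merged also `seq`, `qual`,
#'   `overlap_len`, `overlap_mismatches`.
#' @export
merge_pairs <- function(r1, r2, qual1 = NULL, qual2 = NULL,
                        min_overlap = 10L, max_mismatch_ratio = 0.25) {
  len1 <- nchar(r1); len2 <- nchar(r2)
  if (!len1 || !len2) stop("reads must be nonempty")
  rc2 <- revcomp(r2)
  c1 <- strsplit(r1, NULL)[[1L]]
  c2 <- strsplit(rc2, NULL)[[1L]]
  if (is.null(qual1)) qual1 <- strrep("I", len1)
  if (is.null(qual2)) qual2 <- strrep("I", len2)
  q1 <- utf8ToInt(qual1)
  q2 <- rev(utf8ToInt(qual2))               # qualities of rc2

  eval_offset <- function(o) {
    ov <- min(len1 - o, len2)
    if (ov < min_overlap) return(NULL)
    mism <- sum(c1[(o + 1L):(o + ov)] != c2[1:ov])
    if (mism / ov > max_mismatch_ratio) return(NULL)
    list(o = o, ov = ov, mism = mism)
  }

  # seeded candidates: exact 16-mers of rc2 located in r1
  best <- NULL
  seen <- integer(0)
  for (off in c(0L, 16L, 32L)) {
    if (off + 16L > len2) break
    km <- substr(rc2, off + 1L, off + 16L)
    hit <- gregexpr(km, r1, fixed = TRUE)[[1L]]
    if (hit[1L] == -1L) next
    for (p in as.integer(hit)) {
      o <- p - 1L - off
      if (o < 0L || o %in% seen) next
      seen <- c(seen, o)
      cand <- eval_offset(o)
      if (!is.null(cand) && (is.null(best) || cand$ov > best$ov)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    # exhaustive: largest admissible overlap
    for (ov in seq.int(min(len1, len2), min_overlap)) {
      cand <- eval_offset(len1 - ov)
      if (!is.null(cand)) { best <- cand; break }
    }
  }
  if (is.null(best)) return(list(merged = FALSE))

  o <- best$o; ov <- best$ov
  out <- c(c1[seq_len(o)], character(ov), c2[seq.int(ov + 1L, length.out = len2 - ov)])
  oq <- c(q1[seq_len(o)], integer(ov), q2[seq.int(ov + 1L, length.out = len2 - ov)])
  i1 <- (o + 1L):(o + ov)
  take2 <- c1[i1] != c2[1:ov] & q2[1:ov] > q1[i1]
  ovl_base <- ifelse(take2, c2[1:ov], c1[i1])
  out[i1] <- ovl_base
  oq[i1] <- pmax(q1[i1], q2[1:ov])
  list(merged = TRUE, seq = paste(out, collapse = ""),
       qual = intToUtf8(oq), overlap_len = ov,
       overlap_mismatches = best$mism)
}

#' Demultiplex a merged read by its sample barcode
#'
#' The 12-nt barcode is carried on the C-gene primer, so in transcript
#' (V-to-C) orientation its reverse complement terminates the amplicon.
#' Both orientations of the input are tried; the matching orientation's
#' insert is returned with the barcode (and, when `primer` is supplied,
#' the adjacent primer site) stripped.
#'
#' @param seq merged read sequence.
#' @param barcodes named character vector of 12-nt sample barcodes with
#'   pairwise Hamming distance > `2 * max_mismatch`.
#' @param max_mismatch allowed barcode mismatches (default 1).
#' @param primer optional primer-site sequence expected immediately
#'   upstream of the barcode (stripped when it matches with at most
#'   `primer_max_mismatch` mismatches).
#' @param primer_max_mismatch mismatch allowance for the primer strip.
#' @return list with `sample_id` (NA when unassigned), `insert` and
#'   `orientation` ("forward" or "reverse").
#' @export
demultiplex <- function(seq, barcodes, max_mismatch = 1L, primer = NULL,
                        primer_max_mismatch = 2L) {
  stopifnot(all(nchar(barcodes) == 12L))
  if (length(barcodes) > 1L) {
    for (i in 1:(length(barcodes) - 1L)) {
      for (j in (i + 1L):length(barcodes)) {
        if (hamming(barcodes[[i]], barcodes[[j]]) <= 2L * max_mismatch) {
          stop("barcodes too similar for max_mismatch = ", max_mismatch)
        }
      }
    }
  }
  tags <- revcomp(barcodes)                 # expected read 3' terminus
  for (orient in c("forward", "reverse")) {
    s <- if (orient == "forward") seq else revcomp(seq)
    n <- nchar(s)
    if (n < 12L) next
    tail12 <- substr(s, n - 11L, n)
    d <- vapply(tags, hamming, integer(1L), a = tail12)
    k <- which.min(d)
    if (d[k] <= max_mismatch) {
      insert <- substr(s, 1L, n - 12L)
      if (!is.null(primer) && nchar(insert) > nchar(primer)) {
        pl <- nchar(primer)
        tailp <- substr(insert, nchar(insert) - pl + 1L, nchar(insert))
        if (hamming(tailp, primer) <= primer_max_mismatch) {
          insert <- substr(insert, 1L, nchar(insert) - pl)
        }
      }
      return(list(sample_id = names(barcodes)[k], insert = insert,
                  orientation = orient))
    }
  }
  list(sample_id = NA_character_, insert = NA_character_,
       orientation = NA_character_)
}

# ---- seeded gap-free local alignment -----------------------------------

#' Build a k-mer seed index over a germline database
#'
#' @param db a `germline_db`.
#' @param k seed length (default 12).
#' @return opaque index object consumed by [assign_vj()].
#' @export
build_vj_index <- function(db, k = 12L) {
  vsegs <- germline_segments(db, kind = "V")
  jsegs <- germline_segments(db, kind = "J")
  env <- new.env(hash = TRUE, size = 65536L)
  v_ids <- names(vsegs)
  v_chars <- lapply(vsegs, function(s) strsplit(s$seq_nt, NULL)[[1L]])
  for (s in seq_along(vsegs)) {
    seqs <- vsegs[[s]]$seq_nt
    np <- nchar(seqs) - k + 1L
    if (np < 1L) next
    kms <- substring(seqs, 1:np, k:(np + k - 1L))
    for (t in seq_len(np)) {
      km <- kms[t]
      env[[km]] <- c(env[[km]], s, t)
    }
  }
  j_ids <- names(jsegs)
  j_chars <- lapply(jsegs, function(s) strsplit(s$seq_nt, NULL)[[1L]])
  j_seeds <- lapply(jsegs, function(s) {
    np <- nchar(s$seq_nt) - k + 1L
    pos <- seq.int(1L, np, by = 4L)
    list(pos = pos, kms = substring(s$seq_nt, pos, pos + k - 1L))
  })
  func_v <- vapply(vsegs, function(s) s$functionality, character(1L))
  structure(list(env = env, k = k, v_ids = v_ids, v_chars = v_chars,
                 j_ids = j_ids, j_chars = j_chars, j_seeds = j_seeds,
                 v_functionality = func_v),
            class = "vj_index")
}

# maximal-scoring gap-free segment (match +1, mismatch -2) of germline
# gchars against rchars along a fixed diagonal; optional lower bound on
# the read position.
kadane_diag <- function(rchars, gchars, diag, r_min = 1L) {
  glen <- length(gchars); rlen <- length(rchars)
  g_lo <- max(1L, 1L - diag, r_min - diag)
  g_hi <- min(glen, rlen - diag)
  if (g_hi < g_lo) return(NULL)
  g <- g_lo:g_hi
  m <- rchars[g + diag] == gchars[g]
  x <- ifelse(m, 1, -2)
  P <- cumsum(x)
  pm <- cummin(c(0, P))[seq_along(P)]       # min prefix before each i
  gains <- P - pm
  end <- which.max(gains)
  start <- which.min(c(0, P)[seq_len(end)])
  cm <- cumsum(m)
  matches <- cm[end] - if (start > 1L) cm[start - 1L] else 0L
  span <- end - start + 1L
  list(g_start = g[start], g_end = g[end],
       r_start = g[start] + diag, r_end = g[end] + diag,
       score = gains[end], span = span, matches = matches,
       identity = matches / span)
}

#' Assign germline V and J segments to a read
#'
#' Seeded gap-free local alignment: exact k-mer seeds (default k = 12)
#' vote for candidate segment/diagonal pairs, and each candidate is scored
#' by its maximal-scoring ungapped segment (match +1, mismatch -2) along
#' the diagonal. The best-scoring V is taken (ties broken by higher
#' identity, then lexicographically smaller id); J is searched downstream
#' of the V alignment end. Assignments below the identity or span floors
#' are returned unassigned.
#'
#' @param seq read sequence (transcript orientation).
#' @param db a `germline_db` (used when `index` is NULL).
#' @param index optional prebuilt [build_vj_index()] object.
#' @param min_v_identity,min_j_identity identity floors (default 0.80).
#' @param min_v_span,min_j_span minimum aligned bases (defaults 50, 20).
#' @return list with `v_call`, `j_call` (NA when unassigned), `v_score`,
#'   `j_score`, `v_identity`, `j_identity`, `v_span`, `j_span` (0-based
#'   half-open read intervals) and `v_germline_end` (0-based exclusive end
#'   of the V alignment on the germline).
#' @export
assign_vj <- function(seq, db = NULL, index = NULL, min_v_identity = 0.80,
                      min_v_span = 50L, min_j_span = 20L,
                      min_j_identity = 0.80) {
  if (is.null(index)) index <- build_vj_index(db)
  k <- index$k
  unassigned <- list(v_call = NA_character_, j_call = NA_character_,
                     v_score = NA_real_, j_score = NA_real_,
                     v_identity = NA_real_, j_identity = NA_real_,
                     v_span = c(NA_integer_, NA_integer_),
                     j_span = c(NA_integer_, NA_integer_),
                     v_germline_end = NA_integer_)
  n <- nchar(seq)
  if (n < k) return(unassigned)
  rchars <- strsplit(seq, NULL)[[1L]]

  # V: collect (segment, diagonal) votes from sampled read k-mers
  kpos <- seq.int(1L, n - k + 1L, by = 4L)
  kms <- substring(seq, kpos, kpos + k - 1L)
  segs <- integer(0); diags <- integer(0)
  for (t in seq_along(kms)) {
    v <- index$env[[kms[t]]]
    if (is.null(v)) next
    s <- v[c(TRUE, FALSE)]
    g <- v[c(FALSE, TRUE)]
    segs <- c(segs, s)
    diags <- c(diags, kpos[t] - g)
  }
  if (!length(segs)) return(unassigned)
  key <- segs * 4096L + (diags + 1024L)
  r <- rle(sort(key))
  ord <- order(-r$lengths)
  cand_seg <- integer(0); cand_diag <- integer(0)
  for (idx in ord) {
    s <- r$values[idx] %/% 4096L
    d <- r$values[idx] %% 4096L - 1024L
    if (s %in% cand_seg) next
    cand_seg <- c(cand_seg, s); cand_diag <- c(cand_diag, d)
    if (length(cand_seg) >= 3L) break
  }
  best_v <- NULL; best_v_id <- NULL
  for (ci in seq_along(cand_seg)) {
    al <- kadane_diag(rchars, index$v_chars[[cand_seg[ci]]], cand_diag[ci])
    if (is.null(al)) next
    id <- index$v_ids[cand_seg[ci]]
    if (is.null(best_v) || al$score > best_v$score ||
        (al$score == best_v$score &&
         (al$identity > best_v$identity ||
          (al$identity == best_v$identity && id < best_v_id)))) {
      best_v <- al; best_v_id <- id
    }
  }
  if (is.null(best_v) || best_v$span < min_v_span ||
      best_v$identity < min_v_identity) {
    return(unassigned)
  }

  # J: seed (fallback: offset scan) downstream of the V alignment
  r_min <- best_v$r_end + 1L
  best_j <- NULL; best_j_id <- NULL
  for (ji in seq_along(index$j_ids)) {
    jchars <- index$j_chars[[ji]]
    sd <- index$j_seeds[[ji]]
    votes <- integer(0)
    for (t in seq_along(sd$pos)) {
      p <- regexpr(sd$kms[t], seq, fixed = TRUE)
      if (p > 0L) {
        hits <- as.integer(gregexpr(sd$kms[t], seq, fixed = TRUE)[[1L]])
        hits <- hits[hits + 1L - sd$pos[t] >= r_min - length(jchars)]
        votes <- c(votes, hits - sd$pos[t])
      }
    }
    diags_j <- if (length(votes)) {
      rv <- rle(sort(votes))
      rv$values[order(-rv$lengths)][seq_len(min(2L, length(rv$values)))]
    } else {
      # rare fallback: score every admissible offset, keep the top two
      dmin <- r_min - 1L - length(jchars) + as.integer(min_j_span)
      dmin <- max(dmin, r_min - 1L)
      dd <- seq.int(max(0L, r_min - 1L), n - as.integer(min_j_span))
      if (!length(dd)) next
      sc <- vapply(dd, function(d) {
        g_hi <- min(length(jchars), n - d)
        if (g_hi < 1L) return(-Inf)
        mm <- rchars[(1:g_hi) + d] == jchars[1:g_hi]
        sum(ifelse(mm, 1, -2))
      }, numeric(1L))
      dd[order(-sc)][seq_len(min(2L, length(dd)))]
    }
    for (d in diags_j) {
      al <- kadane_diag(rchars, jchars, d, r_min = r_min)
      if (is.null(al)) next
      id <- index$j_ids[ji]
      if (is.null(best_j) || al$score > best_j$score ||
          (al$score == best_j$score &&
           (al$identity > best_j$identity ||
            (al$identity == best_j$identity && id < best_j_id)))) {
        best_j <- al; best_j_id <- id
      }
    }
  }
  j_ok <- !is.null(best_j) && best_j$span >= min_j_span &&
    best_j$identity >= min_j_identity
  list(
    v_call = best_v_id,
    j_call = if (j_ok) best_j_id else NA_character_,
    v_score = best_v$score,
    j_score = if (j_ok) best_j$score else NA_real_,
    v_identity = best_v$identity,
    j_identity = if (j_ok) best_j$identity else NA_real_,
    v_span = c(best_v$r_start - 1L, best_v$r_end),
    j_span = if (j_ok) c(best_j$r_start - 1L, best_j$r_end) else
      c(NA_integer_, NA_integer_),
    v_germline_end = best_v$g_end
  )
}

#' Drop records assigned to pseudo or ORF V segments
#'
#' @param records data.frame with a `v_call` column.
#' @param db the `germline_db` the calls refer to.
#' @return list with `kept` (data.frame) and `dropped` (count).
#' @export
filter_pseudo_orf <- function(records, db) {
  if (!nrow(records)) return(list(kept = records, dropped = 0L))
  func <- vapply(db$segments, function(s) s$functionality, character(1L))
  unknown <- setdiff(records$v_call, names(func))
  if (length(unknown)) {
    stop("v_call(s) absent from germline database: ",
         paste(unknown, collapse = ", "))
  }
  keep <- func[records$v_call] == "functional"
  list(kept = records[keep, , drop = FALSE], dropped = sum(!keep))
}

#' Extract the CDR3 between the degenerate anchor motifs
#'
#' The V-side anchor is the *last* match of the 9-nt Tyr-(Tyr/His)-Cys
#' pattern `TAC(T|C)A(T|C)TG(T|C)` whose 0-based start lies in
#' `[v_read_end - v_motif_window, v_read_end + 9)`; the J-side anchor is
#' the *first* match of the 12-nt Phe-Gly-X-Gly pattern
#' `TT(C|T)GG(C|A)(A|T)(C|G)(A|T)GG(A|T)` after the V anchor. The CDR3 is
#' the stretch strictly between the two motifs (anchor codons excluded).
#'
#' @param seq read sequence.
#' @param v_read_end 0-based exclusive end of the V alignment on the read
#'   (`v_span[2]` of [assign_vj()]).
#' @param v_motif_window how far upstream of `v_read_end` the V anchor may
#'   start, in bp (default 54).
#' @return the CDR3 nucleotide string, or NA when either motif is absent.
#' @export
extract_cdr3 <- function(seq, v_read_end, v_motif_window = 54L) {
  vs <- regex_starts(CDR3_V_MOTIF, seq)           # 1-based starts
  lo <- v_read_end - v_motif_window + 1L          # 1-based window bounds
  hi <- v_read_end + 9L
  vs <- vs[vs >= lo & vs <= hi]
  if (!length(vs)) return(NA_character_)
  va <- max(vs)
  js <- regex_starts(CDR3_J_MOTIF, seq)
  js <- js[js >= va + 9L]
  if (!length(js)) return(NA_character_)
  jb <- min(js)
  substr(seq, va + 9L, jb - 1L)
}

#' Classify CDR3 productivity
#'
#' Productive iff the length is a multiple of three and the standard-code
#' translation contains no stop codon.
#'
#' @param cdr3_nt CDR3 nucleotide string.
#' @return list with `productive` (logical) and `cdr3_aa` (peptide, empty
#'   when non-productive).
#' @export
classify_productive <- function(cdr3_nt) {
  if (is.na(cdr3_nt) || !nzchar(cdr3_nt)) {
    stop("cdr3_nt must be a nonempty DNA string")
  }
  if (grepl("[^ACGTacgt]", cdr3_nt)) {
    stop("cdr3_nt contains non-DNA characters")
  }
  if (nchar(cdr3_nt) %% 3L != 0L) {
    return(list(productive = FALSE, cdr3_aa = ""))
  }
  aa <- translate_dna(cdr3_nt)
  if (grepl("*", aa, fixed = TRUE)) {
    return(list(productive = FALSE, cdr3_aa = ""))
  }
  list(productive = TRUE, cdr3_aa = aa)
}

# pipeline-internal: an extracted-but-empty junction (anchors adjacent
# after maximal trimming) is non-productive, not an error
productive_or_empty <- function(cdr3_nt) {
  if (is.na(cdr3_nt) || !nzchar(cdr3_nt)) {
    return(list(productive = FALSE, cdr3_aa = ""))
  }
  classify_productive(cdr3_nt)
}

#' Dereplicate full V-region sequences
#'
#' Exact-string deduplication per sample; duplicate counts accumulate and
#' the first-seen read id is kept as representative.
#'
#' @param records data.frame with columns `sample_id`, `seq` and
#'   optionally `read_id`.
#' @return data.frame with `sample_id`, `seq`, `duplicate_count`,
#'   `read_id`.
#' @export
dereplicate_vregion <- function(records) {
  if (!nrow(records)) {
    return(data.frame(sample_id = character(0), seq = character(0),
                      duplicate_count = integer(0), read_id = character(0),
                      stringsAsFactors = FALSE))
  }
  if (is.null(records$read_id)) records$read_id <- as.character(seq_len(nrow(records)))
  key <- paste(records$sample_id, records$seq, sep = "\r")
  first <- !duplicated(key)
  counts <- table(key)
  out <- records[first, c("sample_id", "seq", "read_id"), drop = FALSE]
  out$duplicate_count <- as.integer(counts[paste(out$sample_id, out$seq,
                                                 sep = "\r")])
  rownames(out) <- NULL
  out[, c("sample_id", "seq", "duplicate_count", "read_id")]
}

#' Collapse records to clonotypes
#'
#' One clonotype per distinct (sample, V, J, CDR3 nucleotide) combination;
#' duplicate counts are summed and the highest-count member becomes the
#' representative sequence. Idempotent.
#'
#' @param records data.frame with `sample_id`, `v_call`, `j_call`, `cdr3`,
#'   and optionally `duplicate_count` (default 1) and `sequence`.
#' @return clonotype data.frame with columns `sequence_id`, `sample_id`,
#'   `v_call`, `j_call`, `cdr3`, `cdr3_aa`, `productive`,
#'   `duplicate_count`, `sequence`.
#' @export
collapse_clonotypes <- function(records) {
  if (!nrow(records)) {
    return(data.frame(
      sequence_id = character(0), sample_id = character(0),
      v_call = character(0), j_call = character(0), cdr3 = character(0),
      cdr3_aa = character(0), productive = logical(0),
      duplicate_count = integer(0), sequence = character(0),
      stringsAsFactors = FALSE))
  }
  if (is.null(records$duplicate_count)) records$duplicate_count <- 1L
  if (is.null(records$sequence)) records$sequence <- records$seq %||% ""
  key <- paste(records$sample_id, records$v_call, records$j_call,
               records$cdr3, sep = "\r")
  ord <- order(key, -records$duplicate_count)
  rec <- records[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  total <- as.vector(tapply(rec$duplicate_count, k, sum)[k[first]])
  out <- rec[first, , drop = FALSE]
  out$duplicate_count <- as.integer(total)
  prod <- lapply(out$cdr3, productive_or_empty)
  out$productive <- vapply(prod, `[[`, logical(1L), "productive")
  out$cdr3_aa <- vapply(prod, `[[`, character(1L), "cdr3_aa")
  out$sequence_id <- sprintf("clonotype-%s-%05d", out$sample_id,
                             stats::ave(seq_len(nrow(out)), out$sample_id,
                                        FUN = seq_along))
  rownames(out) <- NULL
  out[, c("sequence_id", "sample_id", "v_call", "j_call", "cdr3",
          "cdr3_aa", "productive", "duplicate_count", "sequence")]
}

#' Run the full read-processing pipeline
#'
#' Stages: merge pairs, demultiplex, dereplicate full V-region sequences,
#' assign V/J, drop pseudo/ORF V assignments, extract CDR3, classify
#' productivity, collapse to clonotypes. All drops are counted per stage;
#' no read disappears unaccounted.
#'
#' @param r1,r2 FASTQ paths or data.frames (`id`, `seq`, `qual`).
#' @param db a `germline_db`.
#' @param barcodes named 12-nt sample barcodes.
#' @param primer optional primer-site sequence stripped next to the
#'   barcode (e.g. the simulated C-prefix).
#' @param min_overlap,max_mismatch_ratio pair-merge parameters.
#' @param bc_max_mismatch barcode mismatch allowance.
#' @param min_v_identity,min_v_span,min_j_span V/J assignment floors.
#' @param v_motif_window CDR3 V-anchor search window (bp).
#' @return object of class `trg_pipeline`: list with `clonotypes` (all
#'   extractable clonotypes, productive flagged), `sequences` (per unique
#'   V-region sequence: calls, CDR3, productivity, counts, representative
#'   read id) and `report` (per-sample stage counts).
#' @export
run_pipeline <- function(r1, r2, db, barcodes, primer = NULL,
                         min_overlap = 10L, max_mismatch_ratio = 0.25,
                         bc_max_mismatch = 1L, min_v_identity = 0.80,
                         min_v_span = 50L, min_j_span = 20L,
                         v_motif_window = 54L) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  stopifnot(nrow(r1) == nrow(r2))
  n_pairs <- nrow(r1)

  merged_seq <- character(n_pairs)
  keep <- logical(n_pairs)
  for (i in seq_len(n_pairs)) {
    m <- merge_pairs(r1$seq[i], r2$seq[i], r1$qual[i], r2$qual[i],
                     min_overlap = min_overlap,
                     max_mismatch_ratio = max_mismatch_ratio)
    if (m$merged) { merged_seq[i] <- m$seq; keep[i] <- TRUE }
  }
  n_merged <- sum(keep)

  ids <- r1$id[keep]; seqs <- merged_seq[keep]
  sample_id <- character(length(seqs)); insert <- character(length(seqs))
  for (i in seq_along(seqs)) {
    d <- demultiplex(seqs[i], barcodes, max_mismatch = bc_max_mismatch,
                     primer = primer)
    sample_id[i] <- d$sample_id
    insert[i] <- if (is.na(d$sample_id)) NA_character_ else d$insert
  }
  assigned_bc <- !is.na(sample_id)
  dem <- data.frame(sample_id = sample_id[assigned_bc],
                    seq = insert[assigned_bc],
                    read_id = ids[assigned_bc], stringsAsFactors = FALSE)

  uniq <- dereplicate_vregion(dem)

  index <- build_vj_index(db)
  asn <- vector("list", nrow(uniq))
  for (i in seq_len(nrow(uniq))) {
    asn[[i]] <- assign_vj(uniq$seq[i], index = index,
                          min_v_identity = min_v_identity,
                          min_v_span = min_v_span, min_j_span = min_j_span)
  }
  uniq$v_call <- vapply(asn, `[[`, character(1L), "v_call")
  uniq$j_call <- vapply(asn, `[[`, character(1L), "j_call")
  uniq$v_read_end <- vapply(asn, function(a) a$v_span[2L], integer(1L))
  assigned <- !is.na(uniq$v_call) & !is.na(uniq$j_call)
  uniq_a <- uniq[assigned, , drop = FALSE]

  fp <- filter_pseudo_orf(uniq_a, db)
  func <- fp$kept

  func$cdr3 <- NA_character_
  if (nrow(func)) {
    func$cdr3 <- mapply(extract_cdr3, func$seq, func$v_read_end,
                        MoreArgs = list(v_motif_window = v_motif_window),
                        USE.NAMES = FALSE)
  }
  extr <- func[!is.na(func$cdr3), , drop = FALSE]
  prod <- lapply(extr$cdr3, productive_or_empty)
  extr$productive <- vapply(prod, `[[`, logical(1L), "productive")
  extr$cdr3_aa <- vapply(prod, `[[`, character(1L), "cdr3_aa")
  extr$sequence <- extr$seq

  clono <- collapse_clonotypes(extr)

  samples <- names(barcodes)
  cnt <- function(x, col = "sample_id") {
    tab <- table(factor(x[[col]], levels = samples))
    as.integer(tab)
  }
  report <- data.frame(
    sample_id = samples,
    demultiplexed = cnt(dem),
    unique_vregion = cnt(uniq),
    vj_assigned = cnt(uniq_a),
    functional_v = cnt(func),
    cdr3_extracted = cnt(extr),
    productive = cnt(extr[extr$productive, , drop = FALSE]),
    clonotypes = cnt(clono),
    stringsAsFactors = FALSE
  )
  attr(report, "n_pairs") <- n_pairs
  attr(report, "n_merged") <- n_merged
  attr(report, "n_barcode_unassigned") <- sum(!assigned_bc)

  structure(list(clonotypes = clono, sequences = extr, report = report),
            class = "trg_pipeline")
}

#' @export
print.trg_pipeline <- function(x, ...) {
  cat("TRG read-processing result\n")
  cat(sprintf("  pairs: %d, merged: %d, barcode-unassigned: %d\n",
              attr(x$report, "n_pairs"), attr(x$report, "n_merged"),
              attr(x$report, "n_barcode_unassigned")))
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a clonotype table as AIRR-style TSV
#'
#' @param clonotypes clonotype data.frame from the pipeline.
#' @param path output path.
#' @export
write_clonotypes <- function(clonotypes, path) {
  utils::write.table(clonotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
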