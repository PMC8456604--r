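# Repertoire summaries: segment and subgroup usage, V-J pairing, CDR3
# length distributions, amino-acid composition with the normal/ultralong
# split, and retention (filter-percentage) reporting.

#' Segment or subgroup usage frequencies
#'
#' Frequencies of V segments, J segments or V subgroups across a
#' clonotype table. By default each unique clonotype counts once;
#' `weighting = "abundance"` weights by `duplicate_count`.
#'
#' @param clonotypes clonotype data.frame (pipeline output).
#' @param level "V", "J" or "subgroup".
#' @param db `germline_db`, required for `level = "subgroup"`.
#' @param weighting "unique" (default) or "abundance".
#' @param per_sample also return a sample-by-segment frequency matrix.
#' @return data.frame with `segment` and `freq` (summing to 1), sorted by
#'   frequency; with `per_sample = TRUE`, the matrix in attribute
#'   `per_sample`.
#' @export
segment_usage <- function(clonotypes, level = c("V", "J", "subgroup"),
                          db = NULL, weighting = c("unique", "abundance"),
                          per_sample = FALSE) {
  level <- match.arg(level)
  weighting <- match.arg(weighting)
  if (!nrow(clonotypes)) stop("empty clonotype table")
  lab <- switch(level,
    V = clonotypes$v_call,
    J = clonotypes$j_call,
    subgroup = {
      if (is.null(db)) stop("subgroup usage requires a germline database")
      sg <- vapply(db$segments, function(s) s$subgroup %||% NA_character_,
                   character(1L))
      unname(sg[clonotypes$v_call])
    })
  w <- if (weighting == "abundance") clonotypes$duplicate_count else
    rep(1L, nrow(clonotypes))
  tab <- tapply(w, lab, sum)
  freq <- as.vector(tab) / sum(w)
  out <- data.frame(segment = names(tab), freq = freq,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$freq, out$segment), , drop = FALSE]
  rownames(out) <- NULL
  if (per_sample) {
    m <- tapply(w, list(clonotypes$sample_id, lab), sum, default = 0L)
    attr(out, "per_sample") <- sweep(m, 1L, rowSums(m), "/")
  }
  out
}

#' Joint V-J pair usage frequencies
#'
#' Empirical joint frequency matrix of (V, J) calls; row and column sums
#' equal the corresponding [segment_usage()] frequencies.
#'
#' @inheritParams segment_usage
#' @return V x J numeric matrix summing to 1.
#' @export
vj_pair_frequencies <- function(clonotypes,
                                weighting = c("unique", "abundance")) {
  weighting <- match.arg(weighting)
  if (!nrow(clonotypes)) stop("empty clonotype table")
  w <- if (weighting == "abundance") clonotypes$duplicate_count else
    rep(1L, nrow(clonotypes))
  m <- tapply(w, list(clonotypes$v_call, clonotypes$j_call), sum,
              default = 0)
  m / sum(m)
}

#' CDR3 length summaries
#'
#' Nucleotide-length statistics of productive CDR3s, overall or grouped by
#' V call, J call or V subgroup. Lengths of productive CDR3s are always
#' multiples of three, so the amino-acid mean is the nucleotide mean / 3.
#'
#' @param clonotypes clonotype data.frame; non-productive rows are
#'   ignored.
#' @param group_by "none", "V", "J" or "subgroup".
#' @param db `germline_db`, required for subgroup grouping.
#' @param sd_type "sample" (n-1 denominator, default) or "population".
#' @return data.frame with one row per group: `group`, `n`, `mean_nt`,
#'   `sd_nt`, `median_nt`, `q1_nt`, `q3_nt`, `mean_aa`. Nucleotide-length
#'   histograms per group are in attribute `histograms`.
#' @export
cdr3_length_summary <- function(clonotypes,
                                group_by = c("none", "V", "J", "subgroup"),
                                db = NULL,
                                sd_type = c("sample", "population")) {
  group_by <- match.arg(group_by)
  sd_type <- match.arg(sd_type)
  cl <- clonotypes[clonotypes$productive, , drop = FALSE]
  if (!nrow(cl)) stop("no productive clonotypes")
  len <- nchar(cl$cdr3)
  grp <- switch(group_by,
    none = rep("all", nrow(cl)),
    V = cl$v_call,
    J = cl$j_call,
    subgroup = {
      if (is.null(db)) stop("subgroup grouping requires a germline database")
      sg <- vapply(db$segments, function(s) s$subgroup %||% NA_character_,
                   character(1L))
      unname(sg[cl$v_call])
    })
  sdfun <- function(x) {
    if (length(x) < 2L) return(0)
    s <- stats::sd(x)
    if (sd_type == "population") s * sqrt((length(x) - 1L) / length(x))
    else s
  }
  groups <- sort(unique(grp))
  rows <- lapply(groups, function(g) {
    x <- len[grp == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(x), mean_nt = mean(x),
               sd_nt = sdfun(x), median_nt = q[2L], q1_nt = q[1L],
               q3_nt = q[3L], mean_aa = mean(x) / 3,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "histograms") <- lapply(stats::setNames(groups, groups),
                                    function(g) table(len[grp == g]))
  out
}

#' Default four-class amino-acid table
#'
#' Hydrophobic, neutral-hydrophilic, acidic and basic classes used for
#' CDR3 composition summaries. The membership is a documented convention:
#' tyrosine, serine, threonine, asparagine and glutamine are treated as
#' neutral and hydrophilic.
#'
#' @return named character vector mapping each of the 20 amino acids to a
#'   class.
#' @export
default_aa_classes <- function() {
  c(A = "hydrophobic", V = "hydrophobic", L = "hydrophobic",
    I = "hydrophobic", P = "hydrophobic", F = "hydrophobic",
    M = "hydrophobic", W = "hydrophobic", G = "hydrophobic",
    C = "hydrophobic",
    S = "neutral_hydrophilic", T = "neutral_hydrophilic",
    N = "neutral_hydrophilic", Q = "neutral_hydrophilic",
    Y = "neutral_hydrophilic",
    D = "acidic", E = "acidic",
    K = "basic", R = "basic", H = "basic")
}

#' CDR3 amino-acid composition by length band
#'
#' Pools residues of productive CDR3 peptides within a normal and an
#' ultralong length band and reports per-amino-acid and per-class
#' frequencies for each band. Clonotypes outside both bands are counted
#' in an `other` bucket.
#'
#' @param clonotypes clonotype data.frame; non-productive rows ignored.
#' @param class_table named vector assigning each amino acid to a class
#'   (default [default_aa_classes()]).
#' @param normal_band,ultralong_band inclusive amino-acid length bands
#'   (defaults 4-22 and 23-36).
#' @return list with `per_aa` (data.frame aa, class, and one frequency
#'   column per band), `per_class` (class frequencies per band) and
#'   `other_count`.
#' @export
aa_composition <- function(clonotypes, class_table = default_aa_classes(),
                           normal_band = c(4L, 22L),
                           ultralong_band = c(23L, 36L)) {
  stopifnot(setequal(names(class_table), strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                  NULL)[[1L]]))
  cl <- clonotypes[clonotypes$productive, , drop = FALSE]
  if (!nrow(cl)) stop("no productive clonotypes")
  alen <- nchar(cl$cdr3_aa)
  band <- ifelse(alen >= normal_band[1L] & alen <= normal_band[2L],
                 "normal",
                 ifelse(alen >= ultralong_band[1L] &
                          alen <= ultralong_band[2L], "ultralong", "other"))
  aas <- names(class_table)
  per_aa <- data.frame(aa = aas, class = unname(class_table[aas]),
                       stringsAsFactors = FALSE)
  per_class <- list()
  for (b in c("normal", "ultralong")) {
    res <- unlist(strsplit(cl$cdr3_aa[band == b], NULL))
    if (length(res)) {
      tab <- table(factor(res, levels = aas))
      fr <- as.vector(tab) / length(res)
    } else {
      fr <- rep(NA_real_, length(aas))
    }
    per_aa[[b]] <- fr
    per_class[[b]] <- tapply(fr, class_table[aas], sum)
  }
  list(per_aa = per_aa,
       per_class = do.call(cbind, per_class),
       other_count = sum(band == "other"))
}

#' Retention report: filter percentages per sample
#'
#' From per-sample stage counts (unique V-region sequences, pseudo/ORF
#' drops, productive sequences) computes the post-filter count and the
#' productive percentage `100 * productive / (unique - dropped)`, plus the
#' min-max range across samples.
#'
#' @param stage_counts data.frame with columns `sample_id`,
#'   `unique_vregion`, `pseudo_orf_dropped`, `productive`.
#' @return list with `per_sample` (adds `post_filter` and
#'   `productive_pct`) and `productive_pct_range` (min, max).
#' @export
retention_report <- function(stage_counts) {
  req <- c("sample_id", "unique_vregion", "pseudo_orf_dropped",
           "productive")
  missing <- setdiff(req, names(stage_counts))
  if (length(missing)) {
    stop("stage_counts missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(stage_counts$pseudo_orf_dropped > stage_counts$unique_vregion)) {
    stop("inconsistent counts: dropped exceeds unique")
  }
  out <- stage_counts
  out$post_filter <- out$unique_vregion - out$pseudo_orf_dropped
  if (any(out$productive > out$post_filter)) {
    stop("inconsistent counts: productive exceeds post-filter")
  }
  out$productive_pct <- 100 * out$productive / out$post_filter
  list(per_sample = out,
       productive_pct_range = c(min = min(out$productive_pct),
                                max = max(out$productive_pct)))
}

#' Bundle repertoire summaries into one profile
#'
#' @param clonotypes clonotype data.frame.
#' @param db optional `germline_db` (enables subgroup usage).
#' @param stage_counts optional retention input (see
#'   [retention_report()]).
#' @return object of class `repertoire_profile`.
#' @export
repertoire_profile <- function(clonotypes, db = NULL, stage_counts = NULL) {
  prod <- clonotypes[clonotypes$productive, , drop = FALSE]
  structure(list(
    v_usage = segment_usage(clonotypes, "V"),
    j_usage = segment_usage(clonotypes, "J"),
    subgroup_usage = if (!is.null(db))
      segment_usage(clonotypes, "subgroup", db = db) else NULL,
    vj_matrix = vj_pair_frequencies(clonotypes),
    cdr3_len = cdr3_length_summary(prod),
    aa_composition = aa_composition(prod),
    retention = if (!is.null(stage_counts)) retention_report(stage_counts)
      else NULL,
    n_clonotypes = nrow(clonotypes), n_productive = nrow(prod)
  ), class = "repertoire_profile")
}

#' @export
print.repertoire_profile <- function(x, ...) {
  cat("TRG repertoire profile\n")
  cat(sprintf("  clonotypes: %d (%d productive)\n", x$n_clonotypes,
              x$n_productive))
  top <- utils::head(x$v_usage, 4L)
  cat("  top V usage:",
      paste(sprintf("%s %.1f%%", top$segment, 100 * top$freq),
            collapse = ", "), "\n")
  cat("  J usage:",
      paste(sprintf("%s %.1f%%", x$j_usage$segment, 100 * x$j_usage$freq),
            collapse = ", "), "\n")
  cat(sprintf("  mean CDR3 length: %.2f nt (%.2f aa)\n",
              x$cdr3_len$mean_nt[1L], x$cdr3_len$mean_aa[1L]))
  if (!is.null(x$retention)) {
    r <- x$retention$productive_pct_range
    cat(sprintf("  productive retention: %.2f%% - %.2f%%\n", r[1L], r[2L]))
  }
  invisible(x)
}
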