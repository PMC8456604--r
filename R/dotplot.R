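# Windowed-identity dot-plot (dotmatcher-style) and detection of
# off-diagonal homology runs, the signature of tandem duplication inside a
# locus. Windows are ungapped, forward-strand, anchored at their midpoint;
# windows clipped by a sequence boundary are skipped.

#' Windowed-identity dot plot
#'
#' Places a dot at (i, j) (0-based window midpoints) whenever the ungapped
#' windows `a[i-w/2, i+w/2)` and `b[j-w/2, j+w/2)` share at least
#' `threshold` identity. Comparison is forward strand only. For a
#' self-comparison (`b = NULL`) only the upper diagonals are computed and
#' mirrored, so the dot set is symmetric and always contains the full main
#' diagonal.
#'
#' @param a,b DNA strings; `b = NULL` compares `a` against itself.
#' @param window window size in bp (default 300).
#' @param threshold identity fraction in (0, 1] (default 0.70).
#' @param stride spacing of evaluated midpoints in bp. Default 1, or 10
#'   when the longer sequence exceeds 50 kb.
#' @return a `dot_matrix`: list with `dots` (data.frame `i`, `j`,
#'   `identity`), `window`, `threshold`, `stride`, `len_a`, `len_b`,
#'   `self`.
#' @export
windowed_dotplot <- function(a, b = NULL, window = 300L, threshold = 0.70,
                             stride = NULL) {
  self <- is.null(b)
  if (self) b <- a
  a <- toupper(a); b <- toupper(b)
  len_a <- nchar(a); len_b <- nchar(b)
  if (len_a < window || len_b < window) {
    stop("sequences must be at least one window long")
  }
  if (is.null(stride)) {
    stride <- if (max(len_a, len_b) > 50000L) 10L else 1L
  }
  stride <- as.integer(stride)
  half <- window %/% 2L

  ca <- strsplit(a, NULL)[[1L]]
  cb <- if (self) ca else strsplit(b, NULL)[[1L]]

  # midpoint grids (0-based, multiples of stride)
  grid_lo_a <- ((half + stride - 1L) %/% stride) * stride
  grid_hi_a <- len_a - half
  grid_lo_b <- grid_lo_a
  grid_hi_b <- len_b - half

  d_min <- if (self) 0L else -(((grid_hi_a - grid_lo_b) %/% stride) * stride)
  d_max <- ((grid_hi_b - grid_lo_a) %/% stride) * stride

  res_i <- list(); res_j <- list(); res_id <- list(); nres <- 0L
  for (d in seq.int(d_min, d_max, by = stride)) {
    i_lo <- max(grid_lo_a, grid_lo_b - d)
    i_hi <- min(grid_hi_a, grid_hi_b - d)
    if (i_lo > i_hi) next
    # match indicator along the diagonal over t in [i_lo-half, i_hi+half)
    t0 <- i_lo - half                     # 0-based
    t1 <- i_hi + half - 1L
    m <- ca[(t0 + 1L):(t1 + 1L)] == cb[(t0 + d + 1L):(t1 + d + 1L)]
    cs <- c(0L, cumsum(m))
    first <- ((i_lo + stride - 1L) %/% stride) * stride
    if (first > i_hi) next
    iis <- seq.int(first, i_hi, by = stride)
    # identity of window centred at i: matches in [i-half, i+half)
    idx_hi <- iis + half - t0
    idx_lo <- iis - half - t0
    ident <- (cs[idx_hi + 1L] - cs[idx_lo + 1L]) / window
    keep <- ident >= threshold
    if (!any(keep)) next
    nres <- nres + 1L
    res_i[[nres]] <- iis[keep]
    res_j[[nres]] <- iis[keep] + d
    res_id[[nres]] <- ident[keep]
  }
  dots <- data.frame(
    i = unlist(res_i) %||% integer(0),
    j = unlist(res_j) %||% integer(0),
    identity = unlist(res_id) %||% numeric(0)
  )
  if (self && nrow(dots)) {
    off <- dots$i != dots$j
    dots <- rbind(dots,
                  data.frame(i = dots$j[off], j = dots$i[off],
                             identity = dots$identity[off]))
    dots <- dots[order(dots$i, dots$j), , drop = FALSE]
    rownames(dots) <- NULL
  }
  structure(
    list(dots = dots, window = as.integer(window), threshold = threshold,
         stride = stride, len_a = len_a, len_b = len_b, self = self),
    class = "dot_matrix"
  )
}

#' @export
print.dot_matrix <- function(x, ...) {
  cat(sprintf(
    "Dot matrix: %d x %d bp, window %d, identity >= %.2f, stride %d\n",
    x$len_a, x$len_b, x$window, x$threshold, x$stride))
  cat(sprintf("  %d dots%s\n", nrow(x$dots),
              if (x$self) " (self comparison)" else ""))
  invisible(x)
}

#' @export
plot.dot_matrix <- function(x, ...) {
  graphics::plot(x$dots$i, x$dots$j, pch = ".", xlab = "sequence A (bp)",
                 ylab = "sequence B (bp)", xlim = c(0, x$len_a),
                 ylim = c(0, x$len_b), ...)
  invisible(x)
}

#' Detect homology runs on dot-plot diagonals
#'
#' Collects maximal stretches of consecutive dots on each diagonal,
#' tolerating gaps up to twice the stride (one missing window), filters
#' them to a minimum length, and excludes the main diagonal of a
#' self-comparison. Off-diagonal runs at a common offset are the dot-plot
#' signature of a tandemly duplicated unit whose length equals the offset.
#'
#' @param m a `dot_matrix`.
#' @param min_run minimum run extent on sequence A in bp (default 1000).
#' @return data.frame with one row per run: `diagonal_offset` (j - i),
#'   `start_i`, `end_i`, `length`, `mean_identity`, sorted by length
#'   descending.
#' @export
find_homology_runs <- function(m, min_run = 1000L) {
  stopifnot(inherits(m, "dot_matrix"))
  dots <- m$dots
  empty <- data.frame(diagonal_offset = integer(0), start_i = integer(0),
                      end_i = integer(0), length = integer(0),
                      mean_identity = numeric(0))
  if (!nrow(dots)) return(empty)
  d <- dots$j - dots$i
  if (m$self) {
    keep <- d != 0L
    dots <- dots[keep, , drop = FALSE]
    d <- d[keep]
    if (!nrow(dots)) return(empty)
  }
  max_gap <- 2L * m$stride
  runs <- lapply(split(seq_len(nrow(dots)), d), function(idx) {
    ii <- dots$i[idx]
    ord <- order(ii)
    ii <- ii[ord]
    ident <- dots$identity[idx][ord]
    brk <- c(0L, cumsum(diff(ii) > max_gap))
    do.call(rbind, lapply(split(seq_along(ii), brk), function(g) {
      data.frame(start_i = ii[g[1L]], end_i = ii[g[length(g)]],
                 mean_identity = mean(ident[g]))
    }))
  })
  out <- do.call(rbind, Map(function(df, off) {
    df$diagonal_offset <- as.integer(off)
    df
  }, runs, names(runs)))
  out$length <- out$end_i - out$start_i
  out <- out[out$length >= min_run,
             c("diagonal_offset", "start_i", "end_i", "length",
               "mean_identity"), drop = FALSE]
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent identity between two sequence spans
#'
#' Global (end-gap-penalized) alignment identity, expressed as a
#' percentage of alignment columns. Used to quantify the similarity of
#' duplicated homology units.
#'
#' @param a_span,b_span nonempty DNA strings.
#' @return percent identity in [0, 100].
#' @export
unit_identity <- function(a_span, b_span) {
  stopifnot(nzchar(a_span), nzchar(b_span))
  100 * alignment_identity(toupper(a_span), toupper(b_span))
}
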