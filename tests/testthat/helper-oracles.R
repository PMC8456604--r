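# Independent brute-force oracles, deliberately written differently from
# the package implementations they check.

# all-offsets RSS scan by direct string comparison
brute_rss <- function(dna, spacer_len, max_hep = 2L, max_non = 3L) {
  hep <- "CACAGTG"; non <- "ACAAAAACC"
  span <- 7L + spacer_len + 9L
  n <- nchar(dna)
  hits <- list()
  if (n >= span) {
    for (off in 0:(n - span)) {
      h <- substr(dna, off + 1L, off + 7L)
      nm <- substr(dna, off + 7L + spacer_len + 1L, off + span)
      dh <- sum(strsplit(h, NULL)[[1L]] != strsplit(hep, NULL)[[1L]])
      dn <- sum(strsplit(nm, NULL)[[1L]] != strsplit(non, NULL)[[1L]])
      if (dh <= max_hep && dn <= max_non) {
        hits[[length(hits) + 1L]] <- c(pos = off, hmm = dh, nmm = dn)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(pos = integer(0), hmm = integer(0),
                      nmm = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df[order(df$hmm + df$nmm, df$pos), , drop = FALSE]
}

# naive O(len_a * len_b) windowed dot-plot recomputation
brute_dotplot <- function(a, b, window, threshold, stride) {
  half <- window %/% 2L
  ca <- strsplit(a, NULL)[[1L]]
  cb <- strsplit(b, NULL)[[1L]]
  iis <- seq(0L, nchar(a), by = stride)
  iis <- iis[iis >= half & iis + half <= nchar(a)]
  jjs <- seq(0L, nchar(b), by = stride)
  jjs <- jjs[jjs >= half & jjs + half <= nchar(b)]
  out <- list()
  for (i in iis) {
    wa <- ca[(i - half + 1L):(i + half)]
    for (j in jjs) {
      idn <- mean(wa == cb[(j - half + 1L):(j + half)])
      if (idn >= threshold) {
        out[[length(out) + 1L]] <- c(i = i, j = j, identity = idn)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(0), j = integer(0),
                      identity = numeric(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$i, df$j), , drop = FALSE]
}

# full-sequence dual-motif CDR3 scan (no window restriction): last V-side
# anchor that still has a J-side anchor after it
brute_cdr3 <- function(seq) {
  vm <- "TAC[TC]A[TC]TG[TC]"
  jm <- "TT[CT]GG[CA][AT][CG][AT]GG[AT]"
  vs <- gregexpr(paste0("(?=", vm, ")"), seq, perl = TRUE)[[1L]]
  js <- gregexpr(paste0("(?=", jm, ")"), seq, perl = TRUE)[[1L]]
  if (vs[1L] == -1L || js[1L] == -1L) return(NA_character_)
  vs <- as.integer(vs); js <- as.integer(js)
  ok <- vs[vapply(vs, function(v) any(js >= v + 9L), logical(1L))]
  if (!length(ok)) return(NA_character_)
  va <- max(ok)
  jb <- min(js[js >= va + 9L])
  substr(seq, va + 9L, jb - 1L)
}

# mean of a geometric distribution truncated (renormalized) to 0..cap
trunc_geom_mean <- function(p, cap) {
  k <- 0:cap
  w <- p * (1 - p)^k
  sum(k * w) / sum(w)
}
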