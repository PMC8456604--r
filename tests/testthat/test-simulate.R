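test_that("germline junction reproduces the germline CDR3 of the pair", {
  cfg <- sim_config(trg_db, n_sequences = 1L, seed = 3L,
                    barcodes = default_barcodes(1L))
  # force no junctional modification
  cfg$trim_geom_p <- 1 - 1e-12   # trims ~ always 0
  cfg$p_nt_max <- 0L
  cfg$n_geom_p <- 1 - 1e-12      # N length ~ always 0
  set.seed(9)
  rr <- sample_rearrangement(cfg, trg_db)
  tr <- rr$truth
  vseg <- trg_db$segments[[tr$v_id]]
  jseg <- trg_db$segments[[tr$j_id]]
  v3 <- substr(vseg$seq_nt, vseg$regions$FR3[2L] + 1L,
               nchar(vseg$seq_nt))
  jm <- regexpr("TT[CT]GG[CA][AT][CG][AT]GG[AT]", jseg$seq_nt)
  j5 <- substr(jseg$seq_nt, 1L, jm - 1L)
  expect_identical(tr$cdr3_nt_truth, paste0(v3, j5))
  expect_identical(tr$v_trim + tr$j_trim, 0L)
  expect_identical(paste0(tr$p_v, tr$n_insert, tr$p_j), "")
})

test_that("P nucleotides are the reverse complement of the retained end", {
  cfg <- sim_config(trg_db, n_sequences = 1L, seed = 3L)
  set.seed(11)
  for (i in 1:200) {
    tr <- sample_rearrangement(cfg, trg_db)$truth
    if (nzchar(tr$p_v)) {
      expect_identical(tr$v_trim, 0L)         # only at untrimmed ends
      vseq <- trg_db$segments[[tr$v_id]]$seq_nt
      tail_v <- substr(vseq, nchar(vseq) - nchar(tr$p_v) + 1L,
                       nchar(vseq))
      expect_identical(tr$p_v, revcomp(tail_v))
    }
    if (nzchar(tr$p_j)) {
      expect_identical(tr$j_trim, 0L)
      jseq <- trg_db$segments[[tr$j_id]]$seq_nt
      expect_identical(tr$p_j, revcomp(substr(jseq, 1L, nchar(tr$p_j))))
    }
  }
})

test_that("trim lengths follow the truncated geometric distribution", {
  # concentrate on one long-tailed V so the cap is the configured trim_max
  cfg <- sim_config(trg_db, n_sequences = 1L, seed = 3L,
                    v_weights = c(Vg3.1 = 1), j_weights = c(Jg1 = 1),
                    trim_geom_p = 0.3, trim_max = 10L)
  set.seed(12)
  n <- 10000L
  vt <- integer(n)
  for (i in seq_len(n)) {
    vt[i] <- sample_rearrangement(cfg, trg_db)$truth$v_trim
  }
  mu <- trunc_geom_mean(0.3, 10L)
  se <- sd(vt) / sqrt(n)
  expect_lt(abs(mean(vt) - mu), 3 * se + 1e-9)
})

test_that("read pairs reconstruct the amplicon and respect length bounds", {
  cfg <- sim_config(trg_db, n_sequences = 1L, seed = 3L)
  set.seed(13)
  rr <- sample_rearrangement(cfg, trg_db)
  pr <- emit_paired_reads(rr$mrna, cfg$barcodes[[1L]], cfg)
  L <- nchar(pr$amplicon)
  expect_true(L >= cfg$read_len && L < 2L * cfg$read_len)
  # error-free mates tile the amplicon exactly
  expect_identical(pr$r1, substr(pr$amplicon, 1L, 250L))
  expect_identical(revcomp(pr$r2), substr(pr$amplicon, L - 249L, L))

  # an amplicon of exactly read_len: r1 is the amplicon, r2 its revcomp
  short <- substr(pr$amplicon, 1L, 250L)
  pr2 <- emit_paired_reads(substr(short, 1L, 238L), cfg$barcodes[[1L]], cfg)
  expect_identical(pr2$r1, pr2$amplicon)
  expect_identical(pr2$r2, revcomp(pr2$amplicon))

  # no mate overlap -> error
  expect_error(emit_paired_reads(strrep("A", 600L), cfg$barcodes[[1L]],
                                 cfg), "overlap")
})

test_that("substitution errors match the binomial expectation", {
  cfg <- sim_config(trg_db, n_sequences = 200L, seed = 17L,
                    subst_error_rate = 0.01)
  sim <- simulate_dataset(cfg, trg_db)
  clean <- sim_config(trg_db, n_sequences = 200L, seed = 17L)
  sim0 <- simulate_dataset(clean, trg_db)
  # same seed, same rearrangements: only the error process differs
  expect_identical(sim$truth$cdr3_nt_truth, sim0$truth$cdr3_nt_truth)
  nerr <- sum(mapply(function(a, b) {
    sum(strsplit(a, NULL)[[1L]] != strsplit(b, NULL)[[1L]])
  }, sim$r1$seq, sim0$r1$seq))
  nbase <- sum(nchar(sim0$r1$seq))
  expect_lt(abs(nerr - 0.01 * nbase), 3 * sqrt(nbase * 0.01 * 0.99))
})

test_that("datasets are byte-deterministic given the seed", {
  cfg <- sim_config(trg_db, n_sequences = 50L, seed = 23L)
  td <- withr::local_tempdir()
  simulate_dataset(cfg, trg_db, out_prefix = file.path(td, "a"))
  simulate_dataset(cfg, trg_db, out_prefix = file.path(td, "b"))
  for (suf in c("_R1.fastq", "_R2.fastq", "_truth.tsv")) {
    expect_identical(readLines(file.path(td, paste0("a", suf))),
                     readLines(file.path(td, paste0("b", suf))))
  }
})

test_that("truth records reassemble the emitted amplicons exactly", {
  cfg <- sim_config(trg_db, n_sequences = 100L, seed = 29L)
  sim <- simulate_dataset(cfg, trg_db)
  # zero error: merged mates equal the rebuilt amplicon
  for (i in seq_len(20L)) {
    amp <- rebuild_amplicon(sim$truth[i, ], trg_db, cfg)
    m <- merge_pairs(sim$r1$seq[i], sim$r2$seq[i])
    expect_true(m$merged)
    expect_identical(m$seq, amp)
    expect_identical(nchar(amp), sim$truth$amplicon_len[i])
  }
})

test_that("concentrated V-J weights propagate to every truth record", {
  cfg <- sim_config(trg_db, n_sequences = 60L, seed = 31L,
                    v_weights = c(Vg2.13 = 1), j_weights = c(Jg3 = 1))
  sim <- simulate_dataset(cfg, trg_db)
  expect_true(all(sim$truth$v_id == "Vg2.13"))
  expect_true(all(sim$truth$j_id == "Jg3"))
})

test_that("truth V usage follows the configured weights", {
  w <- c(Vg3.7 = 0.6, Vg2.13 = 0.3, Vg1.6 = 0.1)
  cfg <- sim_config(trg_db, n_sequences = 10000L, seed = 37L,
                    v_weights = w, barcodes = default_barcodes(1L))
  sim <- simulate_dataset(cfg, trg_db)
  tab <- table(factor(sim$truth$v_id, levels = names(w)))
  gof <- suppressWarnings(chisq.test(tab, p = w))
  expect_gt(gof$p.value, 0.01)
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(trg_db, barcodes = c(S1 = "ACGT")), "12 nt")
  expect_error(sim_config(trg_db,
                          barcodes = c(S1 = "AAACCCGGGTTT",
                                       S2 = "AAACCCGGGTTT")),
               "duplicate")
  expect_error(sim_config(trg_db, v_weights = c(`Vg5.1` = 1)),
               "non-functional")
  expect_error(sim_config(trg_db, read_len = 30L), "read_len")
})
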