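test_that("segment usage counts unique clonotypes and normalizes", {
  cl <- toy_clonotypes()
  u <- segment_usage(cl, "V")
  expect_equal(sum(u$freq), 1)
  expect_equal(u$freq[u$segment == "Va"], 0.50)
  expect_equal(u$freq[u$segment == "Vb"], 0.25)
  expect_equal(u$freq[u$segment == "Vc"], 0.25)
  # single segment -> frequency 1
  one <- segment_usage(cl[cl$v_call == "Vb", , drop = FALSE], "V")
  expect_equal(one$freq, 1)
  # abundance weighting uses duplicate counts
  ab <- segment_usage(cl, "V", weighting = "abundance")
  expect_equal(ab$freq[ab$segment == "Vc"], 4 / 8)
  expect_error(segment_usage(cl[0, , drop = FALSE], "V"), "empty")
})

test_that("V-J matrix normalizes and marginalizes consistently", {
  cl <- toy_clonotypes()
  m <- vj_pair_frequencies(cl)
  expect_equal(sum(m), 1)
  vu <- segment_usage(cl, "V")
  ju <- segment_usage(cl, "J")
  expect_equal(rowSums(m)[vu$segment], setNames(vu$freq, vu$segment))
  expect_equal(colSums(m)[ju$segment], setNames(ju$freq, ju$segment))
  # one pair only -> single unit cell
  m1 <- vj_pair_frequencies(cl[1L, , drop = FALSE])
  expect_equal(as.vector(m1), 1)
})

test_that("CDR3 length summaries are frame-consistent", {
  cl <- data.frame(
    sample_id = "S1", v_call = "Va", j_call = "J1",
    cdr3 = c(strrep("GCT", 12L), strrep("GCA", 13L), strrep("GCC", 14L)),
    cdr3_aa = c(strrep("A", 12L), strrep("A", 13L), strrep("A", 14L)),
    productive = TRUE, duplicate_count = 1L, stringsAsFactors = FALSE)
  s <- cdr3_length_summary(cl)
  expect_equal(s$mean_nt, 39)
  expect_equal(s$median_nt, 39)
  expect_equal(s$mean_aa, 13)                  # aa mean = nt mean / 3
  # single clonotype: sd 0
  s1 <- cdr3_length_summary(cl[1L, , drop = FALSE])
  expect_equal(s1$sd_nt, 0)
  # every productive length is a multiple of 3 on pipeline output
  expect_true(all(nchar(cl$cdr3) %% 3L == 0L))
})

test_that("amino-acid composition pools residues per band and class", {
  cl <- data.frame(
    sample_id = "S1", v_call = "Va", j_call = "J1",
    cdr3 = c("TATTAT", "TATTCT"),
    cdr3_aa = c("YY", "YS"), productive = TRUE, duplicate_count = 1L,
    stringsAsFactors = FALSE)
  comp <- aa_composition(cl, normal_band = c(1L, 22L))
  pa <- comp$per_aa
  expect_equal(pa$normal[pa$aa == "Y"], 0.75)
  expect_equal(pa$normal[pa$aa == "S"], 0.25)
  expect_equal(sum(pa$normal), 1)
  expect_equal(sum(comp$per_class[, "normal"]), 1)
  expect_identical(comp$other_count, 0L)
  # classes partition the 20 amino acids
  expect_identical(sort(as.integer(table(default_aa_classes()))),
                   sort(c(10L, 5L, 2L, 3L)))
})

test_that("junction-driven composition approaches codon multiplicities", {
  # uniform random N-dominated junctions: residue frequencies follow the
  # standard-code codon multiplicities among non-stop codons
  cfg <- sim_config(trg_db, n_sequences = 1500L, seed = 61L,
                    barcodes = default_barcodes(1L),
                    trim_geom_p = 0.15, n_geom_p = 0.05, n_max = 15L)
  sim <- simulate_dataset(cfg, trg_db)
  tr <- sim$truth[sim$truth$productive_truth, ]
  aa <- unlist(strsplit(vapply(tr$cdr3_nt_truth, translate_dna,
                               character(1L)), NULL))
  obs <- table(factor(aa, levels = names(default_aa_classes())))
  gc <- Biostrings::GENETIC_CODE
  mult <- table(factor(gc[gc != "*"],
                       levels = names(default_aa_classes())))
  # germline V/J contributions distort the pure codon model; demand only
  # broad agreement for the abundant residues
  expect_gt(suppressWarnings(cor(as.vector(obs), as.vector(mult))), 0.5)
})

test_that("retention arithmetic reproduces filter percentages", {
  sc <- data.frame(
    sample_id = c("A", "B", "C"),
    unique_vregion = c(200114L, 121916L, 100L),
    pseudo_orf_dropped = c(369L, 222L, 0L),
    productive = c(183476L, 112860L, 100L))
  r <- retention_report(sc)
  expect_identical(r$per_sample$post_filter, c(199745L, 121694L, 100L))
  expect_equal(round(r$per_sample$productive_pct, 2),
               c(91.86, 92.74, 100.00), tolerance = 1e-8)
  expect_error(retention_report(transform(sc, pseudo_orf_dropped = 1e6)),
               "inconsistent")
})

test_that("usage recovery from a simulated run matches the configuration", {
  w <- c(Vg3.7 = 0.6, Vg2.13 = 0.3, Vg1.6 = 0.1)
  cfg <- sim_config(trg_db, n_sequences = 4000L, seed = 67L,
                    v_weights = w, barcodes = default_barcodes(1L))
  sim <- simulate_dataset(cfg, trg_db)
  primer <- substr(trg_db$segments[["Cg"]]$seq_nt, 1L, cfg$c_prefix_len)
  res <- run_pipeline(sim$r1, sim$r2, trg_db, cfg$barcodes,
                      primer = primer)
  u <- segment_usage(res$clonotypes, "V", weighting = "abundance")
  got <- setNames(u$freq, u$segment)[names(w)]
  expect_true(all(abs(got - w) < 0.02))
})

test_that("repertoire profile bundles the summaries coherently", {
  cl <- toy_clonotypes()
  sc <- data.frame(sample_id = "S1", unique_vregion = 100L,
                   pseudo_orf_dropped = 5L, productive = 90L)
  p <- repertoire_profile(cl, stage_counts = sc)
  expect_s3_class(p, "repertoire_profile")
  expect_equal(sum(p$v_usage$freq), 1)
  expect_equal(sum(p$vj_matrix), 1)
  expect_equal(unname(p$retention$productive_pct_range["min"]),
               100 * 90 / 95)
  expect_output(print(p), "repertoire profile")
})
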