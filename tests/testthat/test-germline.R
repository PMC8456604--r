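test_that("packaged fixture loads with the published inventory structure", {
  paths <- germline_fixture_path()
  db <- read_germline_db(paths["fasta"], paths["metadata"])
  m <- db$meta
  expect_identical(sum(m$kind == "V"), 44L)
  expect_identical(sum(m$kind == "J"), 3L)
  expect_identical(sum(m$kind == "C"), 1L)
  expect_identical(sum(m$kind == "V" & m$functionality == "functional"),
                   28L)
  tot <- table(m$subgroup[m$kind == "V"])
  expect_identical(as.integer(tot[paste0("Vg", 1:6)]),
                   c(6L, 19L, 9L, 4L, 3L, 3L))
  func <- table(factor(m$subgroup[m$kind == "V" &
                                    m$functionality == "functional"],
                       levels = paste0("Vg", 1:6)))
  expect_identical(as.integer(func), c(3L, 14L, 8L, 3L, 0L, 0L))
  expect_true(attr(db, "pipeline_ready"))
})

test_that("database loading rejects mismatched or malformed inputs", {
  td <- withr::local_tempdir()
  fa <- file.path(td, "g.fasta"); tsv <- file.path(td, "g.tsv")
  paths <- germline_fixture_path()
  meta <- read.delim(paths["metadata"])

  # FASTA record with no metadata row -> error naming the id
  seqs <- Biostrings::readDNAStringSet(paths["fasta"])
  writeLines(c(">NotInMeta", "ACGTACGT"), fa)
  write.table(meta, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_germline_db(fa, tsv), "NotInMeta")

  # malformed interval -> load error
  bad <- meta
  bad$fr3_end[bad$id == "Vg1.2"] <- 10L   # before fr1_end
  writeLines(paste0(">", names(seqs), "\n", as.character(seqs)), fa)
  write.table(bad, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_germline_db(fa, tsv), "Vg1.2")

  # empty database: valid but flagged unusable
  writeLines(character(0), fa)
  write.table(meta[0, ], tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(db0 <- read_germline_db(fa, tsv), "unusable")
  expect_length(db0$segments, 0L)
  expect_false(attr(db0, "pipeline_ready"))
})

test_that("anchor validation reads the conserved residues off the regions", {
  v <- make_toy_v()
  rep <- validate_anchor_residues(v)
  expect_true(rep$C23_present)
  expect_true(rep$W41_present)
  expect_true(rep$C104_present)
  expect_identical(rep$C104_pos, 104L)
  expect_false(rep$frameshift)

  # FR3 end mutated TGT -> TGG: no cysteine 104
  v2 <- make_toy_v(fr3_tail = "TACTATTGG")
  expect_false(validate_anchor_residues(v2)$C104_present)

  # frame-incompatible annotation: all anchors reported absent
  v3 <- make_toy_v()
  v3$regions$FR3[2L] <- v3$regions$FR3[2L] - 1L
  rep3 <- validate_anchor_residues(v3)
  expect_true(rep3$frameshift)
  expect_false(any(rep3$C23_present, rep3$W41_present, rep3$C104_present))

  expect_error(validate_anchor_residues(
    structure(list(kind = "J"), class = "germline_segment")), "V segments")
})

test_that("functionality classification partitions frame/anchor defects", {
  expect_identical(classify_functionality(make_toy_v()), "functional")
  # conserved Trp absent, frame intact -> ORF
  expect_identical(classify_functionality(make_toy_v(w41 = "CTG")), "ORF")
  # internal stop -> pseudo
  expect_identical(classify_functionality(make_toy_v(stop_codon = 60L)),
                   "pseudo")
  # missing RSS only demotes when required
  v <- make_toy_v(); v$rss <- NULL
  expect_identical(classify_functionality(v), "functional")
  expect_identical(classify_functionality(v, require_rss = TRUE), "ORF")

  # classification of every fixture V agrees with its recorded class
  vsegs <- germline_segments(trg_db, kind = "V")
  cls <- vapply(vsegs, classify_functionality, character(1L))
  recorded <- vapply(vsegs, `[[`, character(1L), "functionality")
  expect_identical(unname(cls), unname(recorded))
})

test_that("RSS scanning finds consensus motifs and honours budgets", {
  set.seed(101)
  spacer <- rand_dna(12L)
  exact <- paste0("CACAGTG", spacer, "ACAAAAACC")
  h <- scan_rss(exact, side = "three_prime", spacer_len = 12L,
                max_mismatch_heptamer = 0L, max_mismatch_nonamer = 0L)
  expect_identical(nrow(h), 1L)
  expect_identical(h$position, 0L)
  expect_identical(h$heptamer_mismatches + h$nonamer_mismatches, 0L)

  # the same signal embedded on the opposite strand, found via five_prime
  h5 <- scan_rss(revcomp(exact), side = "five_prime", spacer_len = 12L,
                 max_mismatch_heptamer = 0L, max_mismatch_nonamer = 0L)
  expect_identical(nrow(h5), 1L)
  expect_identical(h5$position, 0L)

  # one heptamer mutation: rejected at budget 0, reported at budget 1
  mut <- paste0("CACTGTG", spacer, "ACAAAAACC")
  expect_identical(nrow(scan_rss(mut, spacer_len = 12L,
                                 max_mismatch_heptamer = 0L)), 0L)
  h1 <- scan_rss(mut, spacer_len = 12L, max_mismatch_heptamer = 1L,
                 max_mismatch_nonamer = 0L)
  expect_identical(h1$heptamer_mismatches, 1L)

  # too short -> empty
  expect_identical(nrow(scan_rss("CACAGTG", spacer_len = 12L)), 0L)
})

test_that("RSS scan agrees with the exhaustive oracle on random DNA", {
  set.seed(77)
  for (rep in 1:20) {
    dna <- rand_dna(sample(28:400, 1L))
    spacer <- sample(c(12L, 23L), 1L)
    got <- scan_rss(dna, side = "three_prime", spacer_len = spacer,
                    max_mismatch_heptamer = 2L, max_mismatch_nonamer = 3L)
    want <- brute_rss(dna, spacer)
    expect_identical(got$position, as.integer(want$pos))
    expect_identical(got$heptamer_mismatches, as.integer(want$hmm))
    expect_identical(got$nonamer_mismatches, as.integer(want$nmm))
  }
})

test_that("subgroup clustering is single-linkage at 70% and order-stable", {
  mk <- function(id, seq) {
    structure(list(id = id, kind = "V", seq_nt = seq, leader_nt = "",
                   regions = list(FR1 = c(0L, 30L), CDR1 = c(30L, 40L),
                                  FR2 = c(40L, 60L), CDR2 = c(60L, 70L),
                                  FR3 = c(70L, 100L)),
                   rss = NULL, locus = NULL),
              class = "germline_segment")
  }
  set.seed(5)
  base <- rand_dna(100L)
  mut_at <- function(s, pos) {
    ch <- strsplit(s, NULL)[[1L]]
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    paste(ch, collapse = "")
  }
  a <- base
  b <- mut_at(base, 1:25)                      # A~B 75%
  c_ <- mut_at(b, 26:53)                       # B~C 72%, A~C 47%
  # identical sequences cluster together; dissimilar ones do not
  two <- cluster_subgroups(list(mk("X", a), mk("Y", a),
                                mk("Z", mut_at(base, 1:50))))
  expect_identical(two[["X"]], two[["Y"]])
  expect_false(two[["X"]] == two[["Z"]])
  # single linkage chains A-B-C into one subgroup despite A~C < 70%
  one <- cluster_subgroups(list(mk("A", a), mk("B", b), mk("C", c_)))
  expect_identical(length(unique(one)), 1L)

  # permutation invariance on fixture subgroups (labels canonicalized)
  vs <- germline_segments(trg_db, kind = "V")[c("Vg1.1", "Vg1.2", "Vg3.1",
                                                "Vg3.2", "Vg2.1")]
  l1 <- cluster_subgroups(vs)
  l2 <- cluster_subgroups(rev(vs))
  expect_identical(l1[names(l1)], l2[names(l1)])
})

test_that("fixture V segments cluster into the six recorded subgroups", {
  labels <- cluster_subgroups(trg_db)
  truth <- with(trg_db$meta[trg_db$meta$kind == "V", ],
                stats::setNames(subgroup, id))
  expect_identical(length(unique(labels)), 6L)
  # one-to-one correspondence, and label order follows 3'->5' numbering
  expect_identical(as.character(labels),
                   unname(sub("^Vg", "", truth[names(labels)])))
})
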