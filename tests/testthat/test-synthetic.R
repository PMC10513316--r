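tpls <- build_fixture_templates()
panel <- braf_panel()

test_that("fixture templates embed the whole detection panel on the right strands", {
  det <- tpls$detection
  expect_equal(nchar(det$wt_seq), nchar(det$mu_seq))
  # the two alleles differ at exactly the recorded offset
  d <- which(strsplit(det$wt_seq, "")[[1]] != strsplit(det$mu_seq, "")[[1]])
  expect_equal(d - 1L, det$snv_offset)
  expect_equal(substr(det$wt_seq, d, d), "T")
  expect_equal(substr(det$mu_seq, d, d), "A")
  # wild-type blocker footprints sit on the wild-type template only
  expect_true(grepl("CTAGCCACAGTGAAATCTCGA", det$wt_seq, fixed = TRUE))
  expect_true(grepl("CTAGCCACAGAGAAATCTCGA", det$mu_seq, fixed = TRUE))
  sel <- panel[panel$group == "selection", ]
  for (i in seq_len(nrow(sel))) {
    s <- sel$bases[i]
    hits <- c(grepl(s, det$wt_seq, fixed = TRUE),
              grepl(s, det$mu_seq, fixed = TRUE),
              grepl(revcomp(s), det$wt_seq, fixed = TRUE),
              grepl(revcomp(s), det$mu_seq, fixed = TRUE))
    role <- sel$role[i]
    if (role == "opposite_primer") expect_true(sum(hits) >= 2)
    if (role == "allele_primer") {
      expect_true(hits[2] || hits[4])   # mutant allele only
      expect_false(hits[1] || hits[3])
    }
    if (role == "blocker") {
      expect_true(hits[1] || hits[3])   # wild type only
      expect_false(hits[2] || hits[4])
    }
  }
})

test_that("the sequencing template is the 137-bp amplicon bounded by its primers", {
  np <- tpls$nanopore
  expect_equal(nchar(np$wt_seq), 137L)
  expect_true(startsWith(np$wt_seq, "CACCTCAGATATTTTTCTTCA"))
  expect_true(endsWith(np$wt_seq, revcomp("CAATTCTTACCATCCACAAA")))
  # with the 39 pad+barcode bases the read body totals 176
  bc1 <- default_barcode_panel()[1, ]
  expect_equal(nchar(paste0(bc1$pad_seq, bc1$barcode_seq, np$wt_seq)), 176L)
  # no barcode sequence occurs in either template on either strand
  for (b in default_barcode_panel()$barcode_seq) {
    expect_false(grepl(b, np$wt_seq, fixed = TRUE) ||
                   grepl(revcomp(b), np$wt_seq, fixed = TRUE))
  }
})

test_that("standard mixing is linear in volume fractions", {
  mu <- standard_sample("Mu")
  wt <- standard_sample("WT")
  expect_equal(mu$mu_copies_per_uL, 1.8e4)
  half <- mix_standards(mu, wt)
  expect_equal(half$mu_copies_per_uL, 9000)
  expect_equal(half$wt_copies_per_uL, 9000)
  expect_equal(half$carrier_ng_per_uL, 50)
  # idempotent on identical inputs, identity at the extremes
  expect_equal(mix_standards(mu, mu), mu)
  expect_equal(mix_standards(mu, wt, ratio = 0), wt)
  expect_equal(standard_sample("NC1")$mu_copies_per_uL, 0)
  expect_equal(standard_sample("NC2")$carrier_ng_per_uL, 0)
  expect_error(mix_standards(mu, wt, ratio = 1.5), "ratio")
})

test_that("read simulation is seed-deterministic down to the FASTQ bytes", {
  cfg <- read_sim_config(n_reads = 200, true_mu_fraction = 0.1, seed = 77)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(tpls$nanopore, "BC1", cfg, fastq = f1)
  simulate_reads(tpls$nanopore, "BC1", cfg, fastq = f2)
  expect_identical(readLines(f1), readLines(f2))
  # different seed, different reads
  cfg2 <- read_sim_config(n_reads = 200, true_mu_fraction = 0.1, seed = 78)
  f3 <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(tpls$nanopore, "BC1", cfg2, fastq = f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("error-free simulated reads all classify, none ambiguous", {
  sig <- fixture_sig()
  cfg <- read_sim_config(n_reads = 1000, true_mu_fraction = 0.25,
                         sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 9)
  tally <- tally_reads(simulate_reads(tpls$nanopore, "BC4", cfg), sig = sig)
  expect_equal(attr(tally, "n_unassigned"), 0L)
  expect_equal(sum(tally$n_ambiguous), 0L)
  expect_equal(sum(tally$n_barcode_only), 0L)
  expect_equal(tally$n_wt[4] + tally$n_mu[4], 1000L)
  # no mutants injected, none reported
  cfg0 <- read_sim_config(n_reads = 500, true_mu_fraction = 0,
                          sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 10)
  t0 <- tally_reads(simulate_reads(tpls$nanopore, "BC1", cfg0), sig = sig)
  expect_equal(t0$n_mu[1], 0L)
  expect_equal(t0$ratio_percent[1], 0.0)
})

test_that("the default indel error profile cannot fabricate mutant calls", {
  # substitution-free errors can drop reads from the exact-match count but
  # cannot convert a wild-type read into a mutant signature match
  sig <- fixture_sig()
  cfg <- read_sim_config(n_reads = 3000, true_mu_fraction = 0, seed = 13)
  tally <- tally_reads(simulate_reads(tpls$nanopore, "BC2", cfg), sig = sig)
  expect_equal(tally$n_mu[2], 0L)
  expect_equal(tally$ratio_percent[2], 0.0)
  expect_gt(tally$n_barcode_only[2], 0L)  # indels do cost reads
})

test_that("simulated qPCR wells follow the log-linear standard curve", {
  rec <- simulate_qpcr("Mu", 9000, qpcr_sim_config(seed = 1))
  expect_lt(abs(rec$ct - 30), 2)
  expect_true(classify_specific(rec))
  # nothing amplifies without template or with breakthrough disabled
  quiet <- simulate_qpcr(c("NC1", "NC2", "WT", "Mu"), c(0, 0, 0, 0),
                         qpcr_sim_config(wt_breakthrough_prob = 0, seed = 2))
  expect_true(all(is.na(quiet$ct)))
  # breakthrough events are always late
  cfg_bt <- qpcr_sim_config(wt_breakthrough_prob = 1, seed = 3)
  bt <- simulate_qpcr(rep("WT", 50), 0, cfg_bt)
  expect_true(all(is.na(bt$ct) | bt$ct > 60))
  # identical seeds give identical records
  expect_equal(simulate_qpcr("Mu", 333, qpcr_sim_config(seed = 4)),
               simulate_qpcr("Mu", 333, qpcr_sim_config(seed = 4)))
})

test_that("simulated dilution series support a tight Ct regression", {
  rs <- vapply(1:100, function(s) {
    pts <- as_dilution_points(simulate_dilution(qpcr_sim_config(seed = s)))
    fit_ct_vs_logcopies(pts)$r
  }, numeric(1))
  expect_true(all(abs(rs) > 0.98))
})
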