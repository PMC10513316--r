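tpl <- build_fixture_templates()$nanopore
sig <- fixture_sig()
panel <- default_barcode_panel()

test_that("the default barcode panel assembles 60-mer three-part primers", {
  expect_equal(nrow(panel), 6L)
  expect_equal(panel$barcode_id, paste0("BC", 1:6))
  expect_equal(unique(nchar(panel$pad_seq)), 15L)
  expect_equal(unique(nchar(panel$barcode_seq)), 24L)
  expect_equal(unique(nchar(panel$annealing_seq)), 21L)
  expect_equal(unique(nchar(assemble_barcoded_primer(panel))), 60L)
  # only barcodes 1-4 carry the 5'-phosphate for bidirectional reading
  expect_equal(panel$five_prime_phosphate, c(rep(TRUE, 4), rep(FALSE, 2)))
})

test_that("allele signatures differ at one position and are allele-exclusive", {
  expect_equal(nchar(sig$wt_signature), 11L)
  d <- which(strsplit(sig$wt_signature, "")[[1]] !=
               strsplit(sig$mu_signature, "")[[1]])
  expect_equal(length(d), 1L)
  expect_equal(d, 6L)  # SNV centred
  expect_false(grepl(sig$wt_signature, tpl$mu_seq, fixed = TRUE))
  expect_false(grepl(sig$mu_signature, tpl$wt_seq, fixed = TRUE))
})

test_that("constructed reads classify by barcode/signature co-occurrence", {
  bc1 <- panel[1, ]
  read_mu <- paste0(assemble_barcoded_primer(bc1),
                    substr(tpl$mu_seq, 22, nchar(tpl$mu_seq)))
  cls <- classify_reads(read_mu, panel, sig)
  expect_equal(cls$barcode_id, "BC1")
  expect_equal(cls$allele, "mu")
  expect_equal(cls$orientation, "forward")
  # the reverse complement classifies identically, flagged as reverse
  cls_rc <- classify_reads(revcomp(read_mu), panel, sig)
  expect_equal(cls_rc$barcode_id, "BC1")
  expect_equal(cls_rc$allele, "mu")
  expect_equal(cls_rc$orientation, "reverse")
  # an error inside the signature leaves the read barcode-only at exact match
  broken <- paste0(assemble_barcoded_primer(panel[2, ]),
                   sub(sig$wt_signature, "GGGGGGGGGGG",
                       substr(tpl$wt_seq, 22, nchar(tpl$wt_seq)), fixed = TRUE))
  cls_b <- classify_reads(broken, panel, sig)
  expect_equal(cls_b$barcode_id, "BC2")
  expect_equal(cls_b$allele, "unassigned")
  # two barcodes in one read: chimera, not assigned
  chimera <- paste0(assemble_barcoded_primer(panel[1, ]),
                    assemble_barcoded_primer(panel[2, ]), tpl$wt_seq)
  cls_c <- classify_reads(chimera, panel, sig)
  expect_true(is.na(cls_c$barcode_id))
  expect_equal(cls_c$allele, "ambiguous")
  # both signatures in one read: ambiguous
  twosig <- paste0(assemble_barcoded_primer(panel[1, ]), sig$wt_signature,
                   "ACGT", sig$mu_signature)
  expect_equal(classify_reads(twosig, panel, sig)$allele, "ambiguous")
})

test_that("a single mismatch is tolerated only in approximate mode", {
  bc2 <- panel[2, ]
  body <- substr(tpl$wt_seq, 22, nchar(tpl$wt_seq))
  hit <- regexpr(sig$wt_signature, body, fixed = TRUE)
  substr(body, hit + 2L, hit + 2L) <- "A"  # one substitution in the signature
  read <- paste0(assemble_barcoded_primer(bc2), body)
  expect_equal(classify_reads(read, panel, sig)$allele, "unassigned")
  expect_equal(classify_reads(read, panel, sig, max_mismatch = 1)$allele, "wt")
})

test_that("ratio arithmetic: rounding half-up to one decimal, depth flags", {
  mk <- function(n_wt, n_mu) {
    reads <- c(rep(paste0(assemble_barcoded_primer(panel[1, ]),
                          substr(tpl$wt_seq, 22, nchar(tpl$wt_seq))), n_wt),
               rep(paste0(assemble_barcoded_primer(panel[1, ]),
                          substr(tpl$mu_seq, 22, nchar(tpl$mu_seq))), n_mu))
    tally_reads(reads, panel, sig)[1, ]
  }
  t1 <- mk(986, 14)
  expect_equal(t1$ratio_percent, 1.4)
  expect_true(t1$sufficient_depth)
  t2 <- mk(2000, 0)
  expect_equal(t2$ratio_percent, 0.0)
  expect_true(t2$sufficient_depth)
  t3 <- mk(399, 1)  # 0.25% rounds half-up to 0.3
  expect_equal(t3$ratio_percent, 0.3)
  expect_false(t3$sufficient_depth)
  # no informative reads: ratio undefined
  t4 <- tally_reads(character(0), panel, sig)
  expect_true(all(is.na(t4$ratio_percent)))
})

test_that("ratio calls: positive, negative, insufficient", {
  tally <- data.frame(ratio_percent = c(1.4, 0.0, 0.7, NA),
                      sufficient_depth = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(call_from_ratio(tally),
               c("positive", "negative", "insufficient", "insufficient"))
  expect_equal(call_from_ratio(tally, positive_threshold_percent = 2)[1],
               "negative")
})

test_that("tallies equal the brute-force counting oracle on random reads", {
  set.seed(7137)
  body_wt <- substr(tpl$wt_seq, 22, nchar(tpl$wt_seq))
  body_mu <- substr(tpl$mu_seq, 22, nchar(tpl$mu_seq))
  reads <- character(1000)
  for (i in 1:1000) {
    kind <- sample(c("wt", "mu", "junk", "bconly", "chimera"), 1,
                   prob = c(0.4, 0.2, 0.2, 0.1, 0.1))
    bc <- panel[sample(6, 1), ]
    r <- switch(kind,
      wt = paste0(assemble_barcoded_primer(bc), body_wt),
      mu = paste0(assemble_barcoded_primer(bc), body_mu),
      junk = random_dna(1, 150),
      bconly = paste0(assemble_barcoded_primer(bc), random_dna(1, 80)),
      chimera = paste0(assemble_barcoded_primer(panel[1, ]),
                       assemble_barcoded_primer(panel[sample(2:6, 1), ]),
                       body_wt))
    if (runif(1) < 0.5) r <- revcomp(r)
    reads[i] <- r
  }
  got <- tally_reads(reads, panel, sig)
  want <- oracle_tally(reads, panel$barcode_id, panel$barcode_seq,
                       sig$wt_signature, sig$mu_signature)
  expect_equal(got$n_wt, want$n_wt)
  expect_equal(got$n_mu, want$n_mu)
  expect_equal(got$n_ambiguous, want$n_ambiguous)
  expect_equal(got$n_barcode_only, want$n_barcode_only)
  expect_equal(attr(got, "n_unassigned"), attr(want, "n_unassigned"))
  # conservation: every read lands in exactly one bucket
  expect_equal(sum(got$n_wt, got$n_mu, got$n_ambiguous, got$n_barcode_only) +
                 attr(got, "n_unassigned"), length(reads))
  # strand invariance: reverse-complementing every read changes nothing
  flipped <- tally_reads(revcomp(reads), panel, sig)
  expect_equal(flipped$n_wt, got$n_wt)
  expect_equal(flipped$n_mu, got$n_mu)
})

test_that("FASTQ input works, with malformed records skipped and logged", {
  cfg <- read_sim_config(n_reads = 50, true_mu_fraction = 0.3,
                         sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 5)
  path <- withr::local_tempfile(fileext = ".fastq")
  simulate_reads(tpl, "BC3", cfg, fastq = path)
  t_file <- tally_reads(path, panel, sig, min_reads = 10)
  expect_equal(t_file$n_wt[3] + t_file$n_mu[3], 50L)
  expect_equal(attr(t_file, "n_skipped"), 0L)
  # corrupt one record: non-nucleotide garbage in the sequence line
  lines <- readLines(path)
  lines[2] <- paste0("!!!", substr(lines[2], 4, nchar(lines[2])))
  writeLines(lines, path)
  expect_warning(t_bad <- tally_reads(path, panel, sig, min_reads = 10),
                 "skipped 1 malformed")
  expect_equal(attr(t_bad, "n_skipped"), 1L)
  expect_equal(t_bad$n_wt[3] + t_bad$n_mu[3], 49L)
})
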