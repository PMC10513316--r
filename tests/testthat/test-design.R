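panel <- braf_panel()
locus <- locus_from_template(build_fixture_templates()$detection)
panel_seq <- function(nm) panel$bases[panel$name == nm]

test_that("allele primers end 3' on the variant with the mutant base", {
  expect_equal(make_allele_primer(locus, 18, "downstream")$bases,
               panel_seq("F4"))
  expect_equal(make_allele_primer(locus, 19, "downstream")$bases,
               panel_seq("F5"))
  expect_equal(make_allele_primer(locus, 20, "downstream")$bases,
               panel_seq("F6"))
  expect_equal(make_allele_primer(locus, 17, "upstream")$bases,
               panel_seq("R1"))
  expect_equal(make_allele_primer(locus, 18, "upstream")$bases,
               panel_seq("R2"))
  expect_equal(make_allele_primer(locus, 19, "upstream")$bases,
               panel_seq("R3"))
  # degenerate length: just the mutant base
  expect_equal(make_allele_primer(locus, 1, "downstream")$bases,
               locus$mut_base)
  expect_error(make_allele_primer(locus, 1000, "downstream"), "flank")
})

test_that("the allele primer 3' terminus always mismatches wild type", {
  for (orient in c("downstream", "upstream")) {
    for (len in c(5, 12, 18, 25)) {
      p <- make_allele_primer(locus, len, orient)
      last <- substr(p$bases, nchar(p$bases), nchar(p$bases))
      wt3 <- if (orient == "downstream") locus$wt_base
             else chartr("ACGT", "TGCA", locus$wt_base)
      expect_false(last == wt3)
      expect_equal(p$role, "allele_primer")
    }
  }
})

test_that("blockers are wild-type complementary and centred on the SNV", {
  expect_equal(make_blocker(locus, 21, "downstream")$bases, panel_seq("BF1"))
  expect_equal(make_blocker(locus, 23, "downstream")$bases, panel_seq("BF2"))
  expect_equal(make_blocker(locus, 25, "downstream")$bases, panel_seq("BF3"))
  expect_equal(make_blocker(locus, 21, "upstream")$bases, panel_seq("BR1"))
  expect_equal(make_blocker(locus, 23, "upstream")$bases, panel_seq("BR2"))
  # even length: SNV one base 5' of exact centre on the blocker strand
  expect_equal(make_blocker(locus, 24, "upstream")$bases, panel_seq("BR3"))
  # minimal blocker: wild-type base flanked by one base each side
  b3 <- make_blocker(locus, 3, "downstream")
  expect_equal(nchar(b3$bases), 3L)
  expect_equal(substr(b3$bases, 2, 2), locus$wt_base)
})

test_that("every blocker matches wild type exactly and mutant at one mismatch", {
  tpls <- build_fixture_templates()$detection
  for (orient in c("downstream", "upstream")) {
    for (len in c(11, 21, 22, 23, 24, 25)) {
      b <- make_blocker(locus, len, orient)
      expect_true(b$three_prime_phosphate)
      # the template-strand footprint of the blocker
      fwd <- if (orient == "downstream") b$bases else revcomp(b$bases)
      expect_true(grepl(fwd, tpls$wt_seq, fixed = TRUE))
      # exactly one mismatch against the mutant template footprint
      pos <- regexpr(fwd, tpls$wt_seq, fixed = TRUE)
      mu_win <- substr(tpls$mu_seq, pos, pos + len - 1L)
      expect_equal(sum(strsplit(fwd, "")[[1]] != strsplit(mu_win, "")[[1]]), 1L)
    }
  }
})

test_that("candidate enumeration produces the full Cartesian product", {
  up_opp <- panel[panel$name %in% c("F1", "F2", "F3"), ]
  down_opp <- panel[panel$name %in% c("R4", "R5", "R6", "R7", "R8"), ]
  up <- enumerate_candidates(locus, c(17, 18, 19), c(21, 23, 24), up_opp,
                             orientation = "upstream")
  expect_equal(nrow(up), 27L)
  down <- enumerate_candidates(locus, 18:20, c(21, 23, 25), down_opp,
                               orientation = "downstream")
  expect_equal(nrow(down), 45L)
  # empty input -> empty output
  expect_equal(nrow(enumerate_candidates(locus, integer(0), c(21), down_opp)),
               0L)
  set.seed(404)
  for (i in 1:20) {
    k <- sample(1:4, 3, replace = TRUE)
    cand <- enumerate_candidates(locus, sample(12:20, k[1]),
                                 sample(c(11, 15, 19, 21, 23), k[2]),
                                 down_opp[sample(5, k[3]), , drop = FALSE])
    expect_equal(nrow(cand), prod(k))
  }
})

test_that("scoring prefers a moderate blocker-primer Tm gap", {
  # identical except the blocker runs 15 C vs 4 C hotter than the primer
  expect_gt(score_candidate(60, 64, FALSE, FALSE),
            score_candidate(60, 75, FALSE, FALSE))
  # determinism: identical candidates score identically
  expect_equal(score_candidate(61.2, 67.9, TRUE, FALSE),
               score_candidate(61.2, 67.9, TRUE, FALSE))
  # the hottest blocker of its family is penalised: with R8 fixed, the
  # 21-mer blocker outranks the 25-mer
  down_opp <- panel[panel$name %in% c("R4", "R5", "R6", "R7", "R8"), ]
  cand <- enumerate_candidates(locus, 18:20, c(21, 23, 25), down_opp)
  f4r8 <- cand[cand$allele_seq == panel_seq("F4") &
                 cand$opposite_name == "R8", ]
  s21 <- f4r8$score[f4r8$blocker_seq == panel_seq("BF1")]
  s25 <- f4r8$score[f4r8$blocker_seq == panel_seq("BF3")]
  expect_gt(s21, s25)
})

test_that("loci round-trip through the 4-field text format", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(paste(locus$left_flank, locus$wt_base, locus$mut_base,
                   locus$right_flank), path)
  loc2 <- read_locus(path)
  expect_equal(loc2, locus)
  expect_error(snv_locus("ACGT", "T", "T", "ACGT"), "differ")
})
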