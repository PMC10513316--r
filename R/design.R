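# Allele-specific primer / blocker design around a single-nucleotide
# substitution.
#
# Geometry conventions.  The "forward" strand is the strand on which the
# allele primers of the downstream panel are written.  A "downstream"
# assay amplifies 3' of the SNV: the allele primer is a forward-strand
# oligo whose 3' terminal base sits on the SNV and carries the mutant
# base, and the blocker is a forward-strand oligo fully complementary to
# the wild-type template across the SNV.  An "upstream" assay mirrors
# this on the reverse strand.

#' Describe a single-nucleotide variant locus
#'
#' @param left_flank Forward-strand sequence 5' of the SNV.
#' @param wt_base Wild-type base at the SNV (single character).
#' @param mut_base Mutant base at the SNV; must differ from `wt_base`.
#' @param right_flank Forward-strand sequence 3' of the SNV.
#' @return A list of class `"snv_locus"`.
#' @export
#' @examples
#' tpl <- build_fixture_templates()$detection
#' loc <- locus_from_template(tpl)
#' make_allele_primer(loc, 18, "downstream")$bases  # primer F4
snv_locus <- function(left_flank, wt_base, mut_base, right_flank) {
  assert_bases(left_flank, min_len = 1L, what = "left_flank")
  assert_bases(right_flank, min_len = 1L, what = "right_flank")
  assert_bases(wt_base, min_len = 1L, what = "wt_base")
  assert_bases(mut_base, min_len = 1L, what = "mut_base")
  if (nchar(wt_base) != 1L || nchar(mut_base) != 1L) {
    stop("wt_base and mut_base must be single bases", call. = FALSE)
  }
  if (wt_base == mut_base) stop("wt_base and mut_base must differ", call. = FALSE)
  structure(list(left_flank = left_flank, wt_base = wt_base,
                 mut_base = mut_base, right_flank = right_flank),
            class = "snv_locus")
}

#' @rdname snv_locus
#' @param template An `"amplicon_template"` (see [amplicon_template()]).
#' @export
locus_from_template <- function(template) {
  stopifnot(inherits(template, "amplicon_template"))
  off <- template$snv_offset  # 0-based
  snv_locus(left_flank = str_head(template$wt_seq, off),
            wt_base = substr(template$wt_seq, off + 1L, off + 1L),
            mut_base = substr(template$mu_seq, off + 1L, off + 1L),
            right_flank = substr(template$wt_seq, off + 2L,
                                 nchar(template$wt_seq)))
}

#' Read a locus from a 4-field text record
#'
#' The file holds one whitespace-separated record:
#' `left_flank wt_base mut_base right_flank`.
#'
#' @param path Path to the locus file.
#' @return An `"snv_locus"`.
#' @export
read_locus <- function(path) {
  fields <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(fields) != 4L) {
    stop("locus file must contain exactly 4 fields: ",
         "left_flank wt_base mut_base right_flank", call. = FALSE)
  }
  snv_locus(fields[1], fields[2], fields[3], fields[4])
}

#' Build an allele-specific primer with its 3' end on the SNV
#'
#' The primer terminates (3') exactly at the variant position and carries
#' the mutant base there, so extension requires a matched 3' terminus on
#' mutant template.  For `orientation = "downstream"` the primer is the
#' forward strand; for `"upstream"` it is the reverse-complement strand.
#'
#' @param locus An [snv_locus()].
#' @param length Primer length (>= 1).
#' @param orientation `"downstream"` (forward-strand primer) or
#'   `"upstream"` (reverse-strand primer).
#' @return An [oligo()] with `role = "allele_primer"`.
#' @export
make_allele_primer <- function(locus, length,
                               orientation = c("downstream", "upstream")) {
  stopifnot(inherits(locus, "snv_locus"))
  orientation <- match.arg(orientation)
  length <- as.integer(length)
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  flank <- if (orientation == "downstream") locus$left_flank else locus$right_flank
  if (length - 1L > nchar(flank)) {
    stop(sprintf("allele primer length %d exceeds available flank (%d + SNV)",
                 length, nchar(flank)), call. = FALSE)
  }
  bases <- if (orientation == "downstream") {
    paste0(str_tail(locus$left_flank, length - 1L), locus$mut_base)
  } else {
    revcomp(paste0(locus$mut_base, str_head(locus$right_flank, length - 1L)))
  }
  oligo(sprintf("allele_%s_%d", orientation, length), bases,
        role = "allele_primer")
}

#' Build a wild-type blocker centred on the SNV
#'
#' The blocker is fully complementary to the wild-type template across the
#' variant, carries the SNV at position `ceiling(length / 2)` of its own
#' strand (exact centre for odd lengths, one base 5' of centre for even
#' lengths), and is 3'-phosphorylated so it cannot prime extension.  A
#' `"downstream"` blocker lies on the forward strand, competing with the
#' forward allele primer; an `"upstream"` blocker lies on the reverse
#' strand.
#'
#' @inheritParams make_allele_primer
#' @param length Blocker length (>= 3).
#' @return An [oligo()] with `role = "blocker"` and a 3'-phosphate.
#' @export
make_blocker <- function(locus, length,
                         orientation = c("downstream", "upstream")) {
  stopifnot(inherits(locus, "snv_locus"))
  orientation <- match.arg(orientation)
  length <- as.integer(length)
  if (length < 3L) stop("blocker length must be >= 3", call. = FALSE)
  centre <- ceiling(length / 2)           # SNV position on the blocker strand
  if (orientation == "downstream") {
    n_left <- centre - 1L; n_right <- length - centre
  } else {
    n_left <- length - centre; n_right <- centre - 1L
  }
  if (n_left > nchar(locus$left_flank) || n_right > nchar(locus$right_flank)) {
    stop(sprintf("blocker length %d exceeds available flanks", length),
         call. = FALSE)
  }
  fwd <- paste0(str_tail(locus$left_flank, n_left), locus$wt_base,
                str_head(locus$right_flank, n_right))
  bases <- if (orientation == "downstream") fwd else revcomp(fwd)
  oligo(sprintf("blocker_%s_%d", orientation, length), bases,
        role = "blocker", three_prime_phosphate = TRUE)
}

#' Enumerate allele-primer / blocker / opposite-primer combinations
#'
#' Builds every combination (Cartesian product) of allele primers at the
#' requested lengths, blockers at the requested lengths, and the supplied
#' opposite primers, computes each oligo's melting temperature, and scores
#' the combinations with [score_candidate()].
#'
#' @inheritParams make_allele_primer
#' @param allele_lengths Integer vector of allele-primer lengths.
#' @param blocker_lengths Integer vector of blocker lengths.
#' @param opposite_primers An `"oligo_panel"` data frame (or list of
#'   [oligo()]s) of opposite primers.
#' @param context A [thermo_context()].
#' @param delta_star Target Tm gap (blocker minus allele primer, deg C)
#'   passed to [score_candidate()].
#' @param family_penalty Penalty applied to combinations using the
#'   highest-Tm member of the allele-primer or blocker family.
#' @return A data frame of class `"assay_candidates"`, one row per
#'   combination, with oligo sequences, Tms (0.1 C), `score` and `rank`
#'   (1 = best).  Empty inputs give a zero-row frame.
#' @export
enumerate_candidates <- function(locus, allele_lengths, blocker_lengths,
                                 opposite_primers,
                                 orientation = c("downstream", "upstream"),
                                 context = thermo_context(),
                                 delta_star = 5, family_penalty = 2) {
  orientation <- match.arg(orientation)
  if (is.data.frame(opposite_primers)) {
    opp_name <- opposite_primers$name; opp_seq <- opposite_primers$bases
  } else {
    opp_name <- vapply(opposite_primers, `[[`, character(1), "name")
    opp_seq <- vapply(opposite_primers, `[[`, character(1), "bases")
  }
  empty <- data.frame(orientation = character(0),
                      allele_name = character(0), allele_seq = character(0),
                      blocker_name = character(0), blocker_seq = character(0),
                      opposite_name = character(0), opposite_seq = character(0),
                      tm_allele = numeric(0), tm_blocker = numeric(0),
                      tm_opposite = numeric(0),
                      allele_is_family_max = logical(0),
                      blocker_is_family_max = logical(0),
                      score = numeric(0), rank = integer(0))
  class(empty) <- c("assay_candidates", "data.frame")
  if (length(allele_lengths) == 0L || length(blocker_lengths) == 0L ||
      length(opp_seq) == 0L) {
    return(empty)
  }
  alleles <- lapply(allele_lengths, make_allele_primer, locus = locus,
                    orientation = orientation)
  blockers <- lapply(blocker_lengths, make_blocker, locus = locus,
                     orientation = orientation)
  tm_a <- oligo_tm(vapply(alleles, `[[`, character(1), "bases"), context)
  tm_b <- oligo_tm(vapply(blockers, `[[`, character(1), "bases"), context)
  tm_o <- oligo_tm(opp_seq, context)
  grid <- expand.grid(a = seq_along(alleles), b = seq_along(blockers),
                      o = seq_along(opp_seq), KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(
    orientation = orientation,
    allele_name = vapply(alleles, `[[`, character(1), "name")[grid$a],
    allele_seq = vapply(alleles, `[[`, character(1), "bases")[grid$a],
    blocker_name = vapply(blockers, `[[`, character(1), "name")[grid$b],
    blocker_seq = vapply(blockers, `[[`, character(1), "bases")[grid$b],
    opposite_name = opp_name[grid$o], opposite_seq = opp_seq[grid$o],
    tm_allele = round(tm_a[grid$a], 1), tm_blocker = round(tm_b[grid$b], 1),
    tm_opposite = round(tm_o[grid$o], 1),
    allele_is_family_max = tm_a[grid$a] >= max(tm_a) - 1e-9,
    blocker_is_family_max = tm_b[grid$b] >= max(tm_b) - 1e-9,
    stringsAsFactors = FALSE)
  out$score <- score_candidate(out$tm_allele, out$tm_blocker,
                               out$allele_is_family_max,
                               out$blocker_is_family_max,
                               delta_star = delta_star,
                               family_penalty = family_penalty)
  out$rank <- rank(-out$score, ties.method = "first")
  class(out) <- c("assay_candidates", "data.frame")
  out
}

#' Score a primer/blocker combination
#'
#' A deterministic design heuristic: the balance between the blocker and
#' allele-primer melting temperatures drives specificity, so the score
#' decreases with the distance of the observed Tm gap
#' (`tm_blocker - tm_allele`) from a target gap `delta_star`.  Combinations
#' whose allele primer is the hottest of its family, or whose blocker is
#' the hottest of its family, are additionally penalised: in screening,
#' the highest-Tm allele primer amplified wild-type template and the
#' highest-Tm blocker slowed or distorted mutant amplification.  Higher
#' scores are better.  The heuristic is a configurable pre-ranking aid,
#' not a replacement for empirical screening.
#'
#' @param tm_allele,tm_blocker Melting temperatures (deg C); vectorised.
#' @param allele_is_family_max,blocker_is_family_max Logical flags marking
#'   the highest-Tm member of each candidate family.
#' @param delta_star Target blocker-minus-allele Tm gap (deg C).
#' @param family_penalty Score penalty per triggered family-maximum flag.
#' @return Numeric score vector (dimensionless; higher is better).
#' @export
#' @examples
#' # a blocker 4 C hotter than the primer beats one 15 C hotter
#' score_candidate(60, 64, FALSE, FALSE) > score_candidate(60, 75, FALSE, FALSE)
score_candidate <- function(tm_allele, tm_blocker,
                            allele_is_family_max = FALSE,
                            blocker_is_family_max = FALSE,
                            delta_star = 5, family_penalty = 2) {
  10 - abs(tm_blocker - tm_allele - delta_star) -
    family_penalty * as.numeric(allele_is_family_max) -
    family_penalty * as.numeric(blocker_is_family_max)
}

#' Write ranked assay candidates as TSV
#'
#' @param candidates An `"assay_candidates"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_tsv <- function(candidates, path) {
  ord <- order(candidates$rank)
  utils::write.table(candidates[ord, , drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
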