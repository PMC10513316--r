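# Demultiplexing of barcoded amplicon reads and estimation of the mutant
# allele ratio by counting reads in which a barcode and an allele
# signature co-occur.  The default exact-match mode mirrors counting reads
# with a fixed-string (regular-expression) search; an optional
# mismatch-tolerant mode uses Biostrings approximate matching.

#' Default barcoded sequencing primer panel
#'
#' The six three-part barcoded forward primers shipped with the package:
#' a 15-mer pad (so the sequencer reads well into the barcode), a 24-mer
#' sample barcode, and a 21-mer annealing part, assembling to a 60-mer.
#'
#' @return Data frame of class `"barcode_panel"` with columns `barcode_id`,
#'   `pad_seq`, `barcode_seq`, `annealing_seq`, `five_prime_phosphate`.
#' @export
#' @examples
#' nchar(assemble_barcoded_primer(default_barcode_panel()[1, ]))  # 60
default_barcode_panel <- function() {
  panel <- braf_panel()
  bc <- panel[panel$role == "barcoded_primer" & !is.na(panel$barcode_seq), ,
              drop = FALSE]
  out <- data.frame(barcode_id = sub("^.*_(BC[0-9]+)$", "\\1", bc$name),
                    pad_seq = bc$pad_seq, barcode_seq = bc$barcode_seq,
                    annealing_seq = bc$annealing_seq,
                    five_prime_phosphate = bc$five_prime_phosphate,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$barcode_seq)) {
    stop("barcode sequences must be unique within a panel", call. = FALSE)
  }
  class(out) <- c("barcode_panel", "data.frame")
  out
}

#' Assemble the full 60-mer barcoded primer of one panel row
#'
#' @param spec One row of a `"barcode_panel"` data frame.
#' @return The assembled primer sequence `pad + barcode + annealing`.
#' @export
assemble_barcoded_primer <- function(spec) {
  paste0(spec$pad_seq, spec$barcode_seq, spec$annealing_seq)
}

#' Allele signature k-mers spanning the SNV
#'
#' Extracts the wild-type and mutant k-mers centred on the variant
#' position of an amplicon template.  The two signatures differ at exactly
#' one position and neither may occur anywhere in the other allele's
#' template (either strand); both conditions are checked.  The default
#' k = 11 is long enough to be unique within a short amplicon yet short
#' enough to survive read errors reasonably often.
#'
#' @param template An `"amplicon_template"`.
#' @param k Signature length; the SNV sits at position `ceiling(k / 2)`.
#' @return A list of class `"allele_signature"` with `wt_signature` and
#'   `mu_signature`.
#' @export
#' @examples
#' allele_signature(build_fixture_templates()$nanopore)
allele_signature <- function(template, k = 11L) {
  stopifnot(inherits(template, "amplicon_template"))
  k <- as.integer(k)
  if (k < 3L) stop("signature length k must be >= 3", call. = FALSE)
  centre <- ceiling(k / 2)
  start <- template$snv_offset + 1L - (centre - 1L)  # 1-based
  end <- start + k - 1L
  if (start < 1L || end > nchar(template$wt_seq)) {
    stop("signature window extends beyond the template", call. = FALSE)
  }
  wt <- substr(template$wt_seq, start, end)
  mu <- substr(template$mu_seq, start, end)
  ndiff <- sum(strsplit(wt, "")[[1]] != strsplit(mu, "")[[1]])
  if (ndiff != 1L) stop("signatures must differ at exactly one position",
                        call. = FALSE)
  cross <- function(sig, seq) {
    grepl(sig, seq, fixed = TRUE) || grepl(revcomp(sig), seq, fixed = TRUE)
  }
  if (cross(wt, template$mu_seq) || cross(mu, template$wt_seq)) {
    stop("each signature must be absent from the other allele's template",
         call. = FALSE)
  }
  structure(list(wt_signature = wt, mu_signature = mu, k = k),
            class = "allele_signature")
}

# occurrence counts of one pattern in a read set (plus reverse strand)
.count_occurrences <- function(pattern, reads, reads_rc, max_mismatch,
                               both_strands) {
  n <- Biostrings::vcountPattern(pattern, reads, max.mismatch = max_mismatch,
                                 with.indels = max_mismatch > 0L)
  if (both_strands) {
    n_rc <- Biostrings::vcountPattern(pattern, reads_rc,
                                      max.mismatch = max_mismatch,
                                      with.indels = max_mismatch > 0L)
  } else {
    n_rc <- integer(length(reads))
  }
  cbind(fwd = n, rev = n_rc)
}

#' Classify reads by barcode and allele signature co-occurrence
#'
#' Each read (and, when `both_strands`, its reverse complement) is searched
#' for the panel's barcode sequences and the two allele signatures.  With
#' the default `max_mismatch = 0` this reproduces an exact
#' fixed-string search; `max_mismatch > 0` allows that many
#' mismatches/indels per pattern via [Biostrings::vcountPattern()].
#'
#' Bucket rules: a read matching two or more different barcodes is a
#' presumed chimera and left unassigned with `allele = "ambiguous"`; a read
#' with exactly one barcode and both allele signatures is `"ambiguous"`;
#' one barcode and one signature gives `"wt"` or `"mu"`; one barcode and no
#' signature gives `"unassigned"`; no barcode leaves `barcode_id = NA`.
#'
#' @param reads A [Biostrings::DNAStringSet], character vector, or path to
#'   a FASTQ file (plain or gzip).
#' @param panel A `"barcode_panel"` data frame
#'   (default [default_barcode_panel()]).
#' @param sig An [allele_signature()].
#' @param max_mismatch Mismatches tolerated per pattern match (default 0).
#' @param both_strands Also search the reverse complement (default `TRUE`).
#' @return Data frame with one row per read: `barcode_id` (or `NA`),
#'   `allele` (`"wt"`, `"mu"`, `"ambiguous"`, `"unassigned"`) and
#'   `orientation` (`"forward"`, `"reverse"`, or `NA` when no barcode).
#' @export
classify_reads <- function(reads, panel = default_barcode_panel(), sig,
                           max_mismatch = 0L, both_strands = TRUE) {
  stopifnot(inherits(sig, "allele_signature"), nrow(panel) >= 1L)
  reads <- as_read_set(reads)
  n_reads <- length(reads)
  if (n_reads == 0L) {
    return(data.frame(barcode_id = character(0), allele = character(0),
                      orientation = character(0)))
  }
  reads_rc <- if (both_strands) Biostrings::reverseComplement(reads) else NULL
  bc_f <- bc_r <- matrix(0L, n_reads, nrow(panel))
  for (j in seq_len(nrow(panel))) {
    cnt <- .count_occurrences(panel$barcode_seq[j], reads, reads_rc,
                              max_mismatch, both_strands)
    bc_f[, j] <- cnt[, "fwd"]; bc_r[, j] <- cnt[, "rev"]
  }
  bc_hit <- (bc_f + bc_r) > 0L
  n_bc <- rowSums(bc_hit)
  wt_cnt <- .count_occurrences(sig$wt_signature, reads, reads_rc,
                               max_mismatch, both_strands)
  mu_cnt <- .count_occurrences(sig$mu_signature, reads, reads_rc,
                               max_mismatch, both_strands)
  wt_hit <- rowSums(wt_cnt) > 0L
  mu_hit <- rowSums(mu_cnt) > 0L

  barcode_id <- rep(NA_character_, n_reads)
  one <- n_bc == 1L
  barcode_id[one] <- panel$barcode_id[max.col(bc_hit, ties.method = "first")[one]]
  allele <- rep("unassigned", n_reads)
  allele[n_bc >= 2L] <- "ambiguous"            # multi-barcode chimera guard
  allele[one & wt_hit & mu_hit] <- "ambiguous"
  allele[one & wt_hit & !mu_hit] <- "wt"
  allele[one & !wt_hit & mu_hit] <- "mu"
  orientation <- rep(NA_character_, n_reads)
  fwd_bc <- bc_f[cbind(seq_len(n_reads),
                       max.col(bc_hit, ties.method = "first"))] > 0L
  orientation[one] <- ifelse(fwd_bc[one], "forward", "reverse")
  data.frame(barcode_id = barcode_id, allele = allele,
             orientation = orientation, stringsAsFactors = FALSE)
}

# coerce character / file path / DNAStringSet input to a DNAStringSet;
# attaches attr "n_skipped" when a loose FASTQ parse had to drop records
as_read_set <- function(reads) {
  if (inherits(reads, "DNAStringSet")) return(reads)
  if (inherits(reads, "QualityScaledDNAStringSet")) {
    return(Biostrings::DNAStringSet(reads))
  }
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    return(read_fastq_reads(reads))
  }
  Biostrings::DNAStringSet(reads)
}

#' Read FASTQ sequences, skipping malformed records
#'
#' Reads a FASTQ file (plain or gzip) with [Biostrings::readDNAStringSet()].
#' If the file contains malformed records the well-formed ones are salvaged
#' with a line-level fallback parser and the number skipped is reported in
#' a warning and in the `"n_skipped"` attribute.
#'
#' @param path FASTQ path.
#' @return A [Biostrings::DNAStringSet] (qualities are ignored: counting is
#'   sequence-only).
#' @export
read_fastq_reads <- function(path) {
  out <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                  error = function(e) NULL)
  if (!is.null(out)) {
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  n_rec <- length(lines) %/% 4L
  seqs <- character(0); ids <- character(0); skipped <- length(lines) %% 4L > 0L
  n_skipped <- 0L
  for (i in seq_len(n_rec)) {
    block <- lines[(4L * (i - 1L) + 1L):(4L * i)]
    ok <- startsWith(block[1], "@") && startsWith(block[3], "+") &&
      nchar(block[2]) == nchar(block[4]) &&
      grepl("^[ACGTNacgtn]*$", block[2])
    if (ok) {
      seqs <- c(seqs, toupper(block[2]))
      ids <- c(ids, sub("^@", "", block[1]))
    } else {
      n_skipped <- n_skipped + 1L
    }
  }
  if (n_skipped > 0L || skipped) {
    warning(sprintf("skipped %d malformed FASTQ record(s) in %s",
                    n_skipped, path), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Tally per-barcode allele counts and the mutation ratio
#'
#' Classifies every read with [classify_reads()] and aggregates one row per
#' panel barcode.  The mutation ratio is
#' `100 * n_mu / (n_wt + n_mu)`, rounded half-up to one decimal; it is `NA`
#' when no allele-informative reads were seen.  `sufficient_depth` flags
#' barcodes with at least `min_reads` allele-informative reads, the depth
#' required before a ratio is considered reportable.
#'
#' @inheritParams classify_reads
#' @param min_reads Minimum `n_wt + n_mu` for `sufficient_depth`
#'   (default 1000).
#' @return Data frame of class `"barcode_tally"`, one row per barcode:
#'   `barcode_id`, `n_wt`, `n_mu`, `n_ambiguous`, `n_barcode_only`,
#'   `ratio_percent`, `sufficient_depth`.  Attributes `n_reads`,
#'   `n_unassigned` (reads without exactly one barcode) and `n_skipped`
#'   (malformed FASTQ records) carry the whole-run bookkeeping.
#' @export
#' @examples
#' tpl <- build_fixture_templates()$nanopore
#' sig <- allele_signature(tpl)
#' cfg <- read_sim_config(n_reads = 200, true_mu_fraction = 0.5, seed = 1)
#' reads <- simulate_reads(tpl, "BC1", cfg)
#' tally_reads(reads, sig = sig, min_reads = 100)
tally_reads <- function(reads, panel = default_barcode_panel(), sig,
                        max_mismatch = 0L, both_strands = TRUE,
                        min_reads = 1000L) {
  reads <- as_read_set(reads)
  cls <- classify_reads(reads, panel, sig, max_mismatch, both_strands)
  count_of <- function(id, what) {
    sum(cls$barcode_id == id & cls$allele == what, na.rm = TRUE)
  }
  out <- data.frame(
    barcode_id = panel$barcode_id,
    n_wt = vapply(panel$barcode_id, count_of, integer(1), "wt"),
    n_mu = vapply(panel$barcode_id, count_of, integer(1), "mu"),
    n_ambiguous = vapply(panel$barcode_id, count_of, integer(1), "ambiguous"),
    n_barcode_only = vapply(panel$barcode_id, count_of, integer(1),
                            "unassigned"),
    row.names = NULL, stringsAsFactors = FALSE)
  informative <- out$n_wt + out$n_mu
  out$ratio_percent <- ifelse(informative > 0L,
                              round_half_up(100 * out$n_mu / informative, 1),
                              NA_real_)
  out$sufficient_depth <- informative >= min_reads
  attr(out, "n_reads") <- length(reads)
  attr(out, "n_unassigned") <- sum(is.na(cls$barcode_id))
  attr(out, "n_skipped") <- attr(reads, "n_skipped") %||% 0L
  class(out) <- c("barcode_tally", "data.frame")
  out
}

#' Call samples positive, negative or insufficient from a tally
#'
#' A barcode with insufficient depth cannot be called; otherwise the call
#' is positive when the mutation ratio exceeds `positive_threshold_percent`.
#' The default threshold of 0 treats any mutant reads as a positive, the
#' most sensitive choice; raise it to trade sensitivity for robustness to
#' read errors.
#'
#' @param tally A `"barcode_tally"` data frame.
#' @param positive_threshold_percent Ratio (in percent) that must be
#'   exceeded for a positive call.
#' @return Character vector (`"positive"`, `"negative"`, `"insufficient"`),
#'   one element per tally row.
#' @export
call_from_ratio <- function(tally, positive_threshold_percent = 0) {
  stopifnot(is.data.frame(tally))
  ifelse(!tally$sufficient_depth | is.na(tally$ratio_percent), "insufficient",
         ifelse(tally$ratio_percent > positive_threshold_percent,
                "positive", "negative"))
}

#' Write a barcode tally as TSV
#'
#' Appends comment lines recording total, unassigned and skipped read
#' counts, then the per-barcode table.
#'
#' @param tally A `"barcode_tally"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tally_tsv <- function(tally, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_reads=%d unassigned=%d skipped=%d",
                     attr(tally, "n_reads") %||% NA_integer_,
                     attr(tally, "n_unassigned") %||% NA_integer_,
                     attr(tally, "n_skipped") %||% 0L), con)
  utils::write.table(tally, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
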