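# Synthetic-data generators: amplicon templates stitched from the shipped
# oligo panel, standard-sample compositions, barcoded amplicon reads with a
# configurable error model, and qPCR records with log-linear Ct behaviour.
# All simulators are deterministic for a fixed seed.

#' Construct an amplicon template pair
#'
#' @param name Template name.
#' @param wt_seq,mu_seq Equal-length wild-type and mutant sequences
#'   differing at exactly one position.
#' @return A list of class `"amplicon_template"` with fields `name`,
#'   `wt_seq`, `mu_seq` and `snv_offset` (0-based position of the
#'   difference).
#' @export
amplicon_template <- function(name, wt_seq, mu_seq) {
  assert_bases(wt_seq, min_len = 2L, what = "wt_seq")
  assert_bases(mu_seq, min_len = 2L, what = "mu_seq")
  if (nchar(wt_seq) != nchar(mu_seq)) {
    stop("wt_seq and mu_seq must have equal length", call. = FALSE)
  }
  diff <- which(strsplit(wt_seq, "")[[1]] != strsplit(mu_seq, "")[[1]])
  if (length(diff) != 1L) {
    stop("wt_seq and mu_seq must differ at exactly one position (found ",
         length(diff), ")", call. = FALSE)
  }
  structure(list(name = name, wt_seq = wt_seq, mu_seq = mu_seq,
                 snv_offset = diff - 1L),
            class = "amplicon_template")
}

#' @export
print.amplicon_template <- function(x, ...) {
  cat(sprintf("<amplicon_template> %s: %d bp, SNV %s>%s at offset %d (0-based)\n",
              x$name, nchar(x$wt_seq),
              substr(x$wt_seq, x$snv_offset + 1, x$snv_offset + 1),
              substr(x$mu_seq, x$snv_offset + 1, x$snv_offset + 1),
              x$snv_offset))
  invisible(x)
}

# Fixed filler segments used between the oligo landmarks of the fixture
# templates.  The stretch between the printed oligos is not recoverable
# from any published sequence, so these are arbitrary synthetic spacers,
# chosen once and checked (in the test suite) not to collide with any
# panel oligo, barcode or allele signature.
.fixture_segments <- list(
  pre      = "TCCTTTACTTACTA",         # 5' extension carrying primer F1
  anneal   = "CACCTCAGATATTTTTCTTCA",  # F3 / TA / sequencing annealing part
  gap1     = "ATCACTGACTGG",           # synthetic spacer
  pre_snv  = "GATTTTGGTCTAGCCACAG",    # F4-F6 family, 5' of the SNV
  post_snv = "GAAATCTCGATGGAGTGG",     # R1-R3 family (reverse complement)
  gap2     = "CAGTTCAGGAAC",           # synthetic spacer
  r5_rc    = "CCATTTCTCCATTAATTAAA",   # R4/R5 site (reverse complement)
  gap3     = "TGACCTTAGCAT",           # synthetic spacer
  r68_rc   = "ATTTTGTGGATGGTAAGAATTG"  # R6-R8 site (reverse complement)
)

#' Built-in synthetic amplicon templates
#'
#' Deterministically stitches the two fixture templates from the shipped
#' oligo panel: every primer and blocker of the detection panel occurs
#' character-exact on its proper strand and allele.  The `nanopore`
#' template is the 137-bp sequencing amplicon, starting with the 21-mer
#' annealing part and ending with the reverse complement of the reverse
#' sequencing primer; the `detection` template extends it 5' so the
#' longest screening primer also fits.  The wild-type base at the variant
#' is T and the mutant base is A.  The short stretches between the oligo
#' landmarks are arbitrary synthetic spacers: the templates reproduce the
#' assay geometry, not the genomic sequence.
#'
#' @return A list with elements `detection` and `nanopore`, both
#'   [amplicon_template()] objects.
#' @export
#' @examples
#' tpls <- build_fixture_templates()
#' nchar(tpls$nanopore$wt_seq)  # 137
build_fixture_templates <- function() {
  s <- .fixture_segments
  core <- function(snv) paste0(s$anneal, s$gap1, s$pre_snv, snv, s$post_snv,
                               s$gap2, s$r5_rc, s$gap3, s$r68_rc)
  list(
    detection = amplicon_template("detection_synthetic",
                                  paste0(s$pre, core("T")),
                                  paste0(s$pre, core("A"))),
    nanopore = amplicon_template("nanopore_synthetic", core("T"), core("A"))
  )
}

#' Standard template samples
#'
#' Presets mimicking genomic DNA extracts built from cloned plasmid
#' standards: `Mu` and `WT` carry 1.8e4 plasmid copies/uL of the mutant or
#' wild-type amplicon in 50 ng/uL carrier DNA; `NC1` is carrier only and
#' `NC2` is water.
#'
#' @param label One of `"Mu"`, `"WT"`, `"NC1"`, `"NC2"`.
#' @return A list of class `"standard_sample"` with fields `label`,
#'   `mu_copies_per_uL`, `wt_copies_per_uL`, `carrier_ng_per_uL`.
#' @export
#' @examples
#' mix_standards(standard_sample("Mu"), standard_sample("WT"))$mu_copies_per_uL
standard_sample <- function(label = c("Mu", "WT", "NC1", "NC2")) {
  label <- match.arg(label)
  preset <- switch(label,
    Mu  = list(mu = 1.8e4, wt = 0,     carrier = 50),
    WT  = list(mu = 0,     wt = 1.8e4, carrier = 50),
    NC1 = list(mu = 0,     wt = 0,     carrier = 50),
    NC2 = list(mu = 0,     wt = 0,     carrier = 0))
  structure(list(label = label, mu_copies_per_uL = preset$mu,
                 wt_copies_per_uL = preset$wt,
                 carrier_ng_per_uL = preset$carrier),
            class = "standard_sample")
}

#' Mix two standard samples by volume
#'
#' Linear mixing of copy and carrier concentrations: `ratio` is the volume
#' fraction contributed by `a`.  Mixing the mutant and wild-type standards
#' in equal volumes halves both: 1.8e4 mutant copies/uL becomes 9000.
#'
#' @param a,b `"standard_sample"` objects.
#' @param ratio Volume fraction of `a`, in `[0, 1]` (default 0.5).
#' @return A `"standard_sample"`.
#' @export
mix_standards <- function(a, b, ratio = 0.5) {
  stopifnot(inherits(a, "standard_sample"), inherits(b, "standard_sample"))
  if (!is.finite(ratio) || ratio < 0 || ratio > 1) {
    stop("ratio must lie in [0, 1]", call. = FALSE)
  }
  label <- if (identical(a$label, b$label)) a$label
           else if (ratio == 1) a$label
           else if (ratio == 0) b$label
           else sprintf("mix(%s:%s)", a$label, b$label)
  structure(list(
    label = label,
    mu_copies_per_uL = ratio * a$mu_copies_per_uL + (1 - ratio) * b$mu_copies_per_uL,
    wt_copies_per_uL = ratio * a$wt_copies_per_uL + (1 - ratio) * b$wt_copies_per_uL,
    carrier_ng_per_uL = ratio * a$carrier_ng_per_uL + (1 - ratio) * b$carrier_ng_per_uL),
    class = "standard_sample")
}

#' Read-simulation configuration
#'
#' Parameters of the barcoded amplicon read simulator.  The default error
#' profile is indel-dominated and substitution-free: it models the
#' effective error process of reads that an exact-match counting procedure
#' accepts, where the observed false-detection floor of the assay (0.0%
#' mutant ratio over more than a thousand counted reads of true-negative
#' samples) bounds the effective substitution rate at the variant site to
#' essentially zero, while residual indels merely render a read
#' uncountable.  Set `sub_rate` explicitly to study raw-accuracy regimes.
#'
#' @param n_reads Number of reads to simulate.
#' @param true_mu_fraction Probability that a read derives from the mutant
#'   template.
#' @param sub_rate,ins_rate,del_rate Per-base substitution / insertion /
#'   deletion probabilities, each in `[0, 1)`.
#' @param p_forward Probability a read is reported in forward orientation
#'   (the complement is reverse-complemented).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list of class `"read_sim_config"`.
#' @export
read_sim_config <- function(n_reads, true_mu_fraction,
                            sub_rate = 0, ins_rate = 0.001, del_rate = 0.002,
                            p_forward = 0.5, seed = NULL) {
  n_reads <- as.integer(n_reads)
  if (n_reads < 0L) stop("n_reads must be >= 0", call. = FALSE)
  rates <- c(sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("error rates must lie in [0, 1)", call. = FALSE)
  }
  if (true_mu_fraction < 0 || true_mu_fraction > 1) {
    stop("true_mu_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (p_forward < 0 || p_forward > 1) {
    stop("p_forward must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_reads = n_reads, true_mu_fraction = true_mu_fraction,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, p_forward = p_forward,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "read_sim_config")
}

# apply per-base substitution / insertion / deletion errors to one read
.mutate_read <- function(chars, sub, ins, del) {
  n <- length(chars)
  if (sub > 0) {
    hit <- which(stats::runif(n) < sub)
    for (i in hit) {
      chars[i] <- sample(DNA_BASES[DNA_BASES != chars[i]], 1L)
    }
  }
  if (del > 0 || ins > 0) {
    keep <- if (del > 0) stats::runif(length(chars)) >= del
            else rep(TRUE, length(chars))
    ins_here <- if (ins > 0) stats::runif(length(chars)) < ins
                else rep(FALSE, length(chars))
    pieces <- character(0)
    for (i in seq_along(chars)) {
      if (keep[i]) pieces <- c(pieces, chars[i])
      if (ins_here[i]) pieces <- c(pieces, sample(DNA_BASES, 1L))
    }
    chars <- pieces
  }
  chars
}

#' Simulate barcoded amplicon reads
#'
#' Each read picks the mutant template with probability
#' `true_mu_fraction`, prepends the pad and barcode of the requested
#' barcoded primer (the template already starts with the annealing part),
#' applies per-base substitution/insertion/deletion errors, and is
#' reverse-complemented with probability `1 - p_forward`.  Quality strings
#' are constant placeholders; downstream counting is sequence-only.
#'
#' @param template An [amplicon_template()] whose sequence starts with the
#'   barcoded primer's annealing part (e.g. the `nanopore` fixture
#'   template).
#' @param barcode A barcode id (e.g. `"BC1"`) resolved against `panel`, or
#'   one row of a `"barcode_panel"`.
#' @param config A [read_sim_config()].
#' @param fastq Optional path; when given the reads are written there as
#'   FASTQ (4-line records, gzip if the path ends in `.gz`) and the path
#'   is returned invisibly.
#' @param panel Panel used to resolve a barcode id.
#' @return A [Biostrings::QualityScaledDNAStringSet] (or the `fastq` path).
#'   Read names record the barcode, true allele and orientation.
#' @export
#' @examples
#' tpl <- build_fixture_templates()$nanopore
#' cfg <- read_sim_config(n_reads = 5, true_mu_fraction = 0.5, seed = 7)
#' simulate_reads(tpl, "BC1", cfg)
simulate_reads <- function(template, barcode, config, fastq = NULL,
                           panel = default_barcode_panel()) {
  stopifnot(inherits(template, "amplicon_template"),
            inherits(config, "read_sim_config"))
  if (is.character(barcode)) {
    row <- match(barcode, panel$barcode_id)
    if (is.na(row)) stop("unknown barcode id: ", barcode, call. = FALSE)
    barcode <- panel[row, , drop = FALSE]
  }
  if (!startsWith(template$wt_seq, barcode$annealing_seq)) {
    warning("template does not start with the barcode's annealing part; ",
            "assembling pad + barcode + template anyway")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_reads
  prefix <- paste0(barcode$pad_seq, barcode$barcode_seq)
  body_wt <- paste0(prefix, template$wt_seq)
  body_mu <- paste0(prefix, template$mu_seq)
  is_mu <- stats::runif(n) < config$true_mu_fraction
  reads <- ifelse(is_mu, body_mu, body_wt)
  error_free <- config$sub_rate == 0 && config$ins_rate == 0 &&
    config$del_rate == 0
  if (!error_free && n > 0L) {
    chars <- strsplit(reads, "", fixed = TRUE)
    reads <- vapply(chars, function(ch) {
      paste(.mutate_read(ch, config$sub_rate, config$ins_rate,
                         config$del_rate), collapse = "")
    }, character(1))
  }
  is_fwd <- stats::runif(n) < config$p_forward
  if (any(!is_fwd)) reads[!is_fwd] <- revcomp(reads[!is_fwd])
  dss <- Biostrings::DNAStringSet(reads)
  names(dss) <- sprintf("read%06d bc=%s allele=%s strand=%s",
                        seq_len(n), barcode$barcode_id,
                        ifelse(is_mu, "mu", "wt"),
                        ifelse(is_fwd, "forward", "reverse"))
  quals <- Biostrings::PhredQuality(strrep("I", Biostrings::width(dss)))
  out <- Biostrings::QualityScaledDNAStringSet(dss, quals)
  if (!is.null(fastq)) {
    Biostrings::writeXStringSet(dss, fastq, format = "fastq",
                                qualities = Biostrings::BStringSet(quals),
                                compress = grepl("\\.gz$", fastq))
    return(invisible(fastq))
  }
  out
}

#' qPCR-simulation configuration
#'
#' Parameters of the qPCR trace simulator.  Mutant-bearing wells follow
#' `ct = intercept + slope * log10(copies)` with Gaussian cycle noise and a
#' melt peak concentrated inside the specific window; the default
#' intercept puts 9000 mutant copies at Ct about 30.  Wells without mutant
#' template normally stay flat, but with probability `wt_breakthrough_prob`
#' they produce a breakthrough event: a very late amplification
#' (Ct > 60) and/or a melt peak outside the specific window, the two
#' failure modes seen when blocking is imperfect or a non-specific product
#' forms.
#'
#' @param slope Cycles per log10 copies (default -3.32, perfect doubling).
#' @param intercept Cycles at 1 copy (default 43.1).
#' @param ct_noise_sd SD of the cycle noise (default 0.3).
#' @param wt_breakthrough_prob Probability of a breakthrough event in a
#'   well without mutant template (default 0.01).
#' @param specific_peak_mean,specific_peak_sd Melt-peak distribution of the
#'   specific product (defaults 80.5 and 0.15 deg C).
#' @param nonspecific_peak_low,nonspecific_peak_high Range from which
#'   non-specific melt peaks are drawn (the specific window is excluded).
#' @param max_cycles Cycles run (default 90, the screening regime).
#' @param blocker_uM Blocker concentration annotation (0.4 or 1.2).
#' @param seed Integer seed.
#' @return A list of class `"qpcr_sim_config"`.
#' @export
qpcr_sim_config <- function(slope = -3.32, intercept = 43.1,
                            ct_noise_sd = 0.3, wt_breakthrough_prob = 0.01,
                            specific_peak_mean = 80.5, specific_peak_sd = 0.15,
                            nonspecific_peak_low = 72,
                            nonspecific_peak_high = 88,
                            max_cycles = 90L, blocker_uM = 0.4, seed = NULL) {
  if (ct_noise_sd < 0 || specific_peak_sd < 0) {
    stop("noise SDs must be >= 0", call. = FALSE)
  }
  if (wt_breakthrough_prob < 0 || wt_breakthrough_prob > 1) {
    stop("wt_breakthrough_prob must lie in [0, 1]", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 ct_noise_sd = ct_noise_sd,
                 wt_breakthrough_prob = wt_breakthrough_prob,
                 specific_peak_mean = specific_peak_mean,
                 specific_peak_sd = specific_peak_sd,
                 nonspecific_peak_low = nonspecific_peak_low,
                 nonspecific_peak_high = nonspecific_peak_high,
                 max_cycles = as.integer(max_cycles),
                 blocker_uM = blocker_uM,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "qpcr_sim_config")
}

# draw a non-specific melt peak: uniform over the configured range minus
# the specific window
.nonspecific_peak <- function(cfg, window = melt_window()) {
  repeat {
    p <- stats::runif(1, cfg$nonspecific_peak_low, cfg$nonspecific_peak_high)
    if (p < window$low || p > window$high) return(p)
  }
}

#' Simulate qPCR wells
#'
#' Vectorised over `template_class` / `mutant_copies` (recycled to equal
#' length).  Wells of class `"Mu"` with `mutant_copies > 0` amplify on the
#' log-linear standard curve with a specific melt peak (events later than
#' `max_cycles` are recorded as no amplification); all other wells stay
#' flat except for occasional breakthrough events (see
#' [qpcr_sim_config()]).
#'
#' @param template_class Character vector of well classes
#'   (`"Mu"`, `"WT"`, `"NC1"`, `"NC2"`).
#' @param mutant_copies Mutant template copies per well.
#' @param config A [qpcr_sim_config()].
#' @param sample_id Optional sample ids (default auto-numbered).
#' @return A `"qpcr_records"` data frame with a `copies` column appended.
#' @export
#' @examples
#' simulate_qpcr("Mu", 9000, qpcr_sim_config(seed = 1))$ct  # about 30
simulate_qpcr <- function(template_class, mutant_copies,
                          config = qpcr_sim_config(), sample_id = NULL) {
  stopifnot(inherits(config, "qpcr_sim_config"))
  n <- max(length(template_class), length(mutant_copies))
  template_class <- rep_len(template_class, n)
  mutant_copies <- rep_len(mutant_copies, n)
  if (any(mutant_copies < 0)) stop("copies must be >= 0", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  ct <- rep(NA_real_, n)
  peak <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (template_class[i] == "Mu" && mutant_copies[i] > 0) {
      ct_i <- config$intercept + config$slope * log10(mutant_copies[i]) +
        stats::rnorm(1, 0, config$ct_noise_sd)
      if (ct_i > 0 && ct_i <= config$max_cycles) {
        ct[i] <- ct_i
        peak[i] <- stats::rnorm(1, config$specific_peak_mean,
                                config$specific_peak_sd)
      }
    } else if (stats::runif(1) < config$wt_breakthrough_prob) {
      ct_i <- stats::runif(1, 60, 85)    # breakthrough is always very late
      if (ct_i <= config$max_cycles) {
        ct[i] <- ct_i
        peak[i] <- if (stats::runif(1) < 0.5) {
          stats::runif(1, 80, 81)        # specific product, trace template
        } else {
          .nonspecific_peak(config)
        }
      }
    }
  }
  if (is.null(sample_id)) {
    sample_id <- sprintf("%s_%02d", template_class, seq_len(n))
  }
  out <- qpcr_records(sample_id, template_class, ct, peak, config$max_cycles)
  out$copies <- mutant_copies
  out
}

#' Simulate a three-fold (or other) serial-dilution sensitivity run
#'
#' Builds the copy-number series with [build_dilution_series()], simulates
#' `replicates` mutant wells per dilution point, and appends negative
#' control wells (`WT` and `NC1`, `replicates` each) when
#' `include_controls`.
#'
#' @param config A [qpcr_sim_config()].
#' @param start_copies,fold,steps Passed to [build_dilution_series()]
#'   (defaults: 9000 copies, three-fold, 6 points).
#' @param replicates Wells per dilution point (default 3).
#' @param include_controls Add negative-control wells (default `TRUE`).
#' @return A `"qpcr_records"` data frame with a `copies` column.
#' @export
simulate_dilution <- function(config = qpcr_sim_config(), start_copies = 9000,
                              fold = 3, steps = 6, replicates = 3,
                              include_controls = TRUE) {
  series <- build_dilution_series(start_copies, fold, steps)
  classes <- rep("Mu", length(series) * replicates)
  copies <- rep(series, each = replicates)
  if (include_controls) {
    classes <- c(classes, rep(c("WT", "NC1"), each = replicates))
    copies <- c(copies, rep(0, 2 * replicates))
  }
  ids <- sprintf("%s_%s_r%d", classes,
                 ifelse(copies > 0, format(copies, trim = TRUE, scientific = FALSE), "0"),
                 stats::ave(seq_along(classes),
                            paste(classes, copies), FUN = seq_along))
  simulate_qpcr(classes, copies, config, sample_id = ids)
}
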