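# qPCR outcome classification: melt-curve specificity filtering, sample
# calls, serial-dilution arithmetic and the Ct-vs-log10(copies) fit.

#' Melt-curve specificity window
#'
#' Amplification products whose melting-curve peak falls inside this closed
#' temperature window are treated as the specific amplicon; peaks outside
#' it are judged non-specific.  The default window of 80-81 deg C is the
#' observed melt range of the specific V595E amplicon.
#'
#' @param low,high Window bounds in deg C (`low < high`), both inclusive.
#' @return A list of class `"melt_window"`.
#' @export
melt_window <- function(low = 80, high = 81) {
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("melt window requires finite low < high", call. = FALSE)
  }
  structure(list(low = low, high = high), class = "melt_window")
}

#' Create a table of qPCR well records
#'
#' @param sample_id Sample identifiers.
#' @param template_class One of `"Mu"`, `"WT"`, `"NC1"`, `"NC2"`,
#'   `"unknown"` per well.
#' @param ct Threshold cycle; `NA` means no amplification within
#'   `max_cycles`.
#' @param melt_peak Melting-curve peak temperature (deg C); `NA` if absent.
#' @param max_cycles Number of thermal cycles run (e.g. 90 for screening,
#'   45 or 50 for verification).
#' @return A data frame of class `"qpcr_records"`.
#' @export
qpcr_records <- function(sample_id, template_class = "unknown", ct = NA_real_,
                         melt_peak = NA_real_, max_cycles = 45L) {
  n <- max(length(sample_id), length(ct), length(melt_peak))
  out <- data.frame(sample_id = rep_len(as.character(sample_id), n),
                    template_class = rep_len(as.character(template_class), n),
                    ct = rep_len(as.numeric(ct), n),
                    melt_peak = rep_len(as.numeric(melt_peak), n),
                    max_cycles = rep_len(as.integer(max_cycles), n),
                    stringsAsFactors = FALSE)
  bad <- which(!is.na(out$ct) & (out$ct <= 0 | out$ct > out$max_cycles))
  if (length(bad) > 0L) {
    stop(sprintf("ct must lie in (0, max_cycles]; offending row %d", bad[1]),
         call. = FALSE)
  }
  ok_class <- c("Mu", "WT", "NC1", "NC2", "unknown")
  if (!all(out$template_class %in% ok_class)) {
    stop("template_class must be one of ", paste(ok_class, collapse = ", "),
         call. = FALSE)
  }
  class(out) <- c("qpcr_records", "data.frame")
  out
}

#' Classify wells as specific or non-specific amplification
#'
#' A well is specific when it amplified (Ct present), produced a melt peak,
#' and that peak lies inside the closed melt window.  Wells with a Ct but
#' no recorded melt peak are non-specific: specificity cannot be
#' established.
#'
#' @param records A `"qpcr_records"` data frame.
#' @param window A [melt_window()].
#' @return Logical vector, one element per well.
#' @export
#' @examples
#' r <- qpcr_records("s", ct = c(32, 70, NA), melt_peak = c(80.5, 76, NA),
#'                   max_cycles = 90)
#' classify_specific(r)  # TRUE FALSE FALSE
classify_specific <- function(records, window = melt_window()) {
  stopifnot(is.data.frame(records), inherits(window, "melt_window"))
  !is.na(records$ct) & !is.na(records$melt_peak) &
    records$melt_peak >= window$low & records$melt_peak <= window$high
}

#' Call a sample positive or negative from its qPCR replicates
#'
#' A sample is called positive when at least one replicate shows specific
#' amplification (melt peak inside the window) at `ct <= ct_cutoff`.  A
#' single qualifying replicate suffices; any specific amplification counts
#' as detection.  By default the cutoff equals the run's cycle count, so
#' every specific amplification qualifies; long screening runs (90 cycles)
#' are normally re-called with a stricter cutoff since very late events can
#' arise from trace breakthrough.
#'
#' @param records A `"qpcr_records"` data frame (>= 1 row), the replicates
#'   of one sample.
#' @param window A [melt_window()].
#' @param ct_cutoff Maximum Ct accepted for a positive; defaults to the
#'   run's `max_cycles`.
#' @return A list of class `"discrimination_call"` with fields `call`
#'   (`"positive"`/`"negative"`), `n_specific_replicates` (replicates that
#'   were specific and within the cutoff) and `reason`.
#' @export
call_sample <- function(records, window = melt_window(), ct_cutoff = NULL) {
  stopifnot(is.data.frame(records))
  if (nrow(records) < 1L) {
    stop("call_sample() needs at least one replicate record", call. = FALSE)
  }
  if (is.null(ct_cutoff)) ct_cutoff <- max(records$max_cycles)
  specific <- classify_specific(records, window)
  qualifies <- specific & !is.na(records$ct) & records$ct <= ct_cutoff
  n <- sum(qualifies)
  call <- if (n >= 1L) "positive" else "negative"
  reason <- if (n >= 1L) {
    sprintf("specific amplification in replicate(s) %s (ct <= %.4g, melt peak in [%g, %g])",
            paste(which(qualifies), collapse = ","), ct_cutoff,
            window$low, window$high)
  } else if (any(specific)) {
    sprintf("specific amplification only beyond ct cutoff %.4g", ct_cutoff)
  } else if (any(!is.na(records$ct))) {
    "amplification present but melt peak outside the specific window"
  } else {
    sprintf("no amplification within %d cycles", max(records$max_cycles))
  }
  structure(list(call = call, n_specific_replicates = as.integer(n),
                 reason = reason),
            class = "discrimination_call")
}

#' @export
print.discrimination_call <- function(x, ...) {
  cat(sprintf("<call> %s (%d qualifying replicate%s): %s\n", x$call,
              x$n_specific_replicates,
              if (x$n_specific_replicates == 1L) "" else "s", x$reason))
  invisible(x)
}

#' Serial dilution copy-number series
#'
#' @param start_copies Copies in the first (undiluted) sample.
#' @param fold Dilution factor per step (> 1).
#' @param steps Number of samples including the undiluted one.
#' @return Integer vector of length `steps`; element `i` is
#'   `round(start_copies / fold^(i-1))`.
#' @export
#' @examples
#' build_dilution_series(9000, 3, 6)  # 9000 3000 1000 333 111 37
build_dilution_series <- function(start_copies, fold, steps) {
  if (start_copies < 1) stop("start_copies must be >= 1", call. = FALSE)
  if (fold <= 1) stop("fold must be > 1", call. = FALSE)
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1", call. = FALSE)
  round(start_copies / fold^(seq_len(steps) - 1L))
}

#' Fit Ct against log10 copy number
#'
#' Ordinary least squares of Ct on `log10(copies)` over the usable dilution
#' points: wells that amplified specifically.  Non-specific and
#' non-amplified wells are excluded before fitting.
#'
#' @param points Data frame with columns `copies`, `ct` and `specific`
#'   (logical), e.g. from [as_dilution_points()].
#' @return A list of class `"dilution_fit"` with `slope` (cycles per
#'   log10 copies), `intercept`, `r` (Pearson correlation) and `n_used`.
#' @export
fit_ct_vs_logcopies <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("copies", "ct", "specific") %in% names(points)))
  use <- points$specific & !is.na(points$ct) & points$copies > 0
  pts <- points[use, , drop = FALSE]
  if (nrow(pts) < 2L) {
    stop("need at least 2 specific, amplified dilution points to fit",
         call. = FALSE)
  }
  x <- log10(pts$copies)
  fit <- stats::lm(ct ~ x, data = data.frame(ct = pts$ct, x = x))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(x, pts$ct),
                 n_used = nrow(pts)),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("<dilution_fit> ct = %.2f * log10(copies) + %.2f  (r = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r, x$n_used))
  invisible(x)
}

#' Convert qPCR records of a dilution series into fit-ready points
#'
#' @param records A `"qpcr_records"` data frame with a `copies` column
#'   (e.g. from [simulate_dilution()]).
#' @param window A [melt_window()].
#' @return Data frame with columns `copies`, `ct`, `specific`.
#' @export
as_dilution_points <- function(records, window = melt_window()) {
  stopifnot("copies" %in% names(records))
  data.frame(copies = records$copies, ct = records$ct,
             specific = classify_specific(records, window))
}

#' Read / write qPCR record tables as CSV
#'
#' Columns: `sample_id`, `template_class`, `ct` (empty = no amplification),
#' `melt_peak`, `max_cycles`; extra columns (e.g. `copies`) are preserved.
#'
#' @param path File path.
#' @param records A `"qpcr_records"` data frame.
#' @return `read_qpcr_csv()` returns a `"qpcr_records"` data frame.
#' @export
read_qpcr_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "template_class", "ct", "melt_peak", "max_cycles")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("qPCR CSV ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- qpcr_records(raw$sample_id, raw$template_class,
                      as.numeric(raw$ct), as.numeric(raw$melt_peak),
                      raw$max_cycles)
  extra <- setdiff(names(raw), need)
  for (col in extra) out[[col]] <- raw[[col]]
  out
}

#' @rdname read_qpcr_csv
#' @export
write_qpcr_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
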