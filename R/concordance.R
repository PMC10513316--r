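# Cross-method concordance: compare Sanger calls with the
# blocker-assay calls sample by sample and summarise agreement, plus the
# sequencing ratio extrema by agreement class.

#' Build a sample call table
#'
#' @param sample_id Unique sample identifiers (en dashes are normalised to
#'   hyphens).
#' @param sanger,new_method Calls per method; accepted spellings are
#'   `"+"`, `"positive"`, `"pos"` and `"-"` (hyphen or minus sign),
#'   `"negative"`, `"neg"`.
#' @param ratio_percent Sequencing mutation ratio (percent) or `NA` when
#'   not tested.
#' @return Data frame of class `"sample_records"` with columns
#'   `sample_id`, `sanger`, `new_method`, `ratio_percent`.
#' @export
sample_records <- function(sample_id, sanger, new_method,
                           ratio_percent = NA_real_) {
  norm_call <- function(x, col) {
    x <- tolower(trimws(as.character(x)))
    out <- ifelse(x %in% c("+", "positive", "pos"), "positive",
           ifelse(x %in% c("-", "−", "–", "negative", "neg"),
                  "negative", NA_character_))
    if (anyNA(out)) {
      stop(sprintf("unrecognised %s call '%s'", col, x[which(is.na(out))[1]]),
           call. = FALSE)
    }
    out
  }
  id <- gsub("–", "-", as.character(sample_id))  # en dash -> hyphen
  if (anyDuplicated(id)) {
    stop("duplicate sample_id: ", id[anyDuplicated(id)], call. = FALSE)
  }
  n <- length(id)
  out <- data.frame(sample_id = id,
                    sanger = norm_call(rep_len(sanger, n), "sanger"),
                    new_method = norm_call(rep_len(new_method, n), "new_method"),
                    ratio_percent = rep_len(as.numeric(ratio_percent), n),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_records", "data.frame")
  out
}

#' Read a sample call table from CSV
#'
#' Expected columns: `sample_id`, `sanger`, `new_method`, `ratio_percent`.
#' The ratio column accepts numbers, empty cells, or `"n.t."` (not
#' tested); the latter two are read as missing, never as zero.
#'
#' @param path CSV path.
#' @return A `"sample_records"` data frame.
#' @export
#' @examples
#' path <- system.file("extdata", "first_verification.csv",
#'                     package = "blockerpcr")
#' summarize_concordance(read_sample_table(path))
read_sample_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "sanger", "new_method", "ratio_percent")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("sample table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  ratio <- trimws(raw$ratio_percent)
  ratio[ratio %in% c("", "n.t.", "n.t", "NA")] <- NA
  sample_records(raw$sample_id, raw$sanger, raw$new_method,
                 suppressWarnings(as.numeric(ratio)))
}

#' Summarise concordance between the two methods
#'
#' Counts agreement and disagreement between the Sanger and blocker-assay
#' calls and reports sequencing-ratio extrema: over the Sanger-positive
#' samples with a measured ratio, and over the discordant samples.
#'
#' @param records A `"sample_records"` data frame (may be empty or a list
#'   of several tables, which are then combined).
#' @return A list of class `"concordance_summary"`: `n_total`, `n_match`,
#'   `n_discordant`, `n_sanger_pos`, `n_sanger_neg`, `n_new_pos`,
#'   `n_new_neg`, `discordant_ids`, `ratio_min_sanger_pos`,
#'   `ratio_max_sanger_pos`, `ratio_range_discordant` (length-2 vector or
#'   `NA` when no ratios are available).
#' @export
summarize_concordance <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- combine_sample_tables(records)
  }
  stopifnot(is.data.frame(records))
  match_ <- records$sanger == records$new_method
  ratio_of <- function(sel, fun) {
    v <- records$ratio_percent[sel & !is.na(records$ratio_percent)]
    if (length(v) == 0L) NA_real_ else fun(v)
  }
  disc <- !match_
  structure(list(
    n_total = nrow(records),
    n_match = sum(match_),
    n_discordant = sum(disc),
    n_sanger_pos = sum(records$sanger == "positive"),
    n_sanger_neg = sum(records$sanger == "negative"),
    n_new_pos = sum(records$new_method == "positive"),
    n_new_neg = sum(records$new_method == "negative"),
    discordant_ids = records$sample_id[disc],
    ratio_min_sanger_pos = ratio_of(records$sanger == "positive", min),
    ratio_max_sanger_pos = ratio_of(records$sanger == "positive", max),
    ratio_range_discordant = c(ratio_of(disc, min), ratio_of(disc, max))),
    class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("<concordance> %d samples: %d concordant, %d discordant\n",
              x$n_total, x$n_match, x$n_discordant))
  cat(sprintf("  Sanger: %d positive / %d negative; blocker assay: %d / %d\n",
              x$n_sanger_pos, x$n_sanger_neg, x$n_new_pos, x$n_new_neg))
  if (x$n_discordant > 0L) {
    cat("  discordant:", paste(x$discordant_ids, collapse = ", "), "\n")
  }
  if (!is.na(x$ratio_min_sanger_pos)) {
    cat(sprintf("  sequencing ratio among Sanger positives: %.1f-%.1f%%\n",
                x$ratio_min_sanger_pos, x$ratio_max_sanger_pos))
  }
  invisible(x)
}

#' Cross-tabulate calls of the two methods
#'
#' @param records A `"sample_records"` data frame.
#' @return A 2x2 contingency table (rows: Sanger, columns: blocker assay,
#'   levels positive/negative).
#' @export
discordance_pattern <- function(records) {
  stopifnot(is.data.frame(records))
  lv <- c("positive", "negative")
  table(sanger = factor(records$sanger, levels = lv),
        new_method = factor(records$new_method, levels = lv))
}

#' Combine several sample tables into one
#'
#' @param tables List of `"sample_records"` data frames.
#' @return A single `"sample_records"` data frame; duplicate ids across
#'   tables are rejected.
#' @export
combine_sample_tables <- function(tables) {
  out <- do.call(rbind, lapply(tables, as.data.frame))
  sample_records(out$sample_id, out$sanger, out$new_method, out$ratio_percent)
}
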