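# Oligonucleotide records and panel input/output.

OLIGO_ROLES <- c("allele_primer", "opposite_primer", "blocker", "barcoded_primer")

#' Create an oligonucleotide record
#'
#' An oligo is a short single-stranded DNA sequence written 5'-to-3' with a
#' functional role in the assay.  Blockers are 3'-phosphorylated so that the
#' polymerase cannot extend them; the constructor enforces this.
#'
#' @param name Oligo name.
#' @param bases DNA sequence, 5'-to-3', alphabet A/C/G/T.
#' @param role One of `"allele_primer"`, `"opposite_primer"`, `"blocker"`,
#'   `"barcoded_primer"`.
#' @param three_prime_phosphate Logical; `TRUE` for extension-blocked oligos.
#'   Must be `TRUE` when `role = "blocker"`.
#' @param five_prime_phosphate Logical; 5'-phosphate modification (used on
#'   barcoded sequencing primers to direct adapter ligation).
#' @return An object of class `"oligo"`: a list with the fields above.
#' @export
#' @examples
#' oligo("BF1", "CTAGCCACAGTGAAATCTCGA", "blocker", three_prime_phosphate = TRUE)
oligo <- function(name, bases, role = "opposite_primer",
                  three_prime_phosphate = FALSE,
                  five_prime_phosphate = FALSE) {
  role <- match.arg(role, OLIGO_ROLES)
  assert_bases(bases, min_len = 1L, what = sprintf("oligo '%s'", name))
  if (role == "blocker" && !isTRUE(three_prime_phosphate)) {
    stop("a blocker must carry a 3'-phosphate (three_prime_phosphate = TRUE)",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), bases = toupper(bases), role = role,
         three_prime_phosphate = isTRUE(three_prime_phosphate),
         five_prime_phosphate = isTRUE(five_prime_phosphate)),
    class = "oligo")
}

#' @export
print.oligo <- function(x, ...) {
  mods <- c(if (x$five_prime_phosphate) "5'P", if (x$three_prime_phosphate) "3'P")
  cat(sprintf("<oligo> %s [%s] %d nt%s\n  5'-%s-3'\n", x$name, x$role,
              nchar(x$bases),
              if (length(mods)) paste0(" (", paste(mods, collapse = ", "), ")") else "",
              x$bases))
  invisible(x)
}

#' Assemble a panel data frame from oligo records
#'
#' @param ... Objects of class `"oligo"`, or a single list of them.
#' @return A data frame with one row per oligo (class `"oligo_panel"`),
#'   columns `name`, `bases`, `size`, `role`, `three_prime_phosphate`,
#'   `five_prime_phosphate`.
#' @export
oligo_panel <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "oligo")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "oligo")))
  out <- data.frame(
    name = vapply(xs, `[[`, character(1), "name"),
    bases = vapply(xs, `[[`, character(1), "bases"),
    size = vapply(xs, function(o) nchar(o$bases), integer(1)),
    role = vapply(xs, `[[`, character(1), "role"),
    three_prime_phosphate = vapply(xs, `[[`, logical(1), "three_prime_phosphate"),
    five_prime_phosphate = vapply(xs, `[[`, logical(1), "five_prime_phosphate"),
    stringsAsFactors = FALSE)
  class(out) <- c("oligo_panel", "data.frame")
  out
}

# Parse one printed oligo sequence.  Conventions of the shipped panel table:
#   "&"  alignment padding (stripped),
#   "-P" suffix = 3'-phosphate, "P-" prefix = 5'-phosphate,
#   remaining "-" separate the pad / barcode / annealing parts of the
#   three-part barcoded sequencing primers.
parse_oligo_seq <- function(s) {
  s <- gsub("&", "", s, fixed = TRUE)
  p3 <- grepl("-P$", s)
  if (p3) s <- sub("-P$", "", s)
  p5 <- grepl("^P-", s)
  if (p5) s <- sub("^P-", "", s)
  parts <- strsplit(s, "-", fixed = TRUE)[[1]]
  list(bases = paste(parts, collapse = ""), parts = parts,
       three_prime_phosphate = p3, five_prime_phosphate = p5)
}

#' Read an oligo panel from a tab-separated table
#'
#' The table mirrors the layout of a published oligo panel: columns `name`,
#' `size`, `group`, `role`, `sequence`.  Alignment padding characters (`&`)
#' are stripped, a trailing `-P` marks a 3'-phosphate, a leading `P-` marks a
#' 5'-phosphate, and internal dashes separate the pad / barcode / annealing
#' parts of barcoded sequencing primers.
#'
#' @param path Path to the TSV file.
#' @return An `"oligo_panel"` data frame with additional columns `group`,
#'   and (for barcoded primers) `pad_seq`, `barcode_seq`, `annealing_seq`.
#' @seealso [braf_panel()] for the built-in canine BRAF V595E panel.
#' @export
read_oligo_panel <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("name", "size", "group", "role", "sequence")
  if (!all(need %in% names(raw))) {
    stop("oligo panel table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  parsed <- lapply(raw$sequence, parse_oligo_seq)
  bases <- vapply(parsed, `[[`, character(1), "bases")
  for (i in seq_along(bases)) {
    assert_bases(bases[i], what = sprintf("oligo '%s'", raw$name[i]))
  }
  out <- data.frame(
    name = raw$name, bases = bases, size = nchar(bases),
    role = raw$role, group = raw$group,
    three_prime_phosphate = vapply(parsed, `[[`, logical(1), "three_prime_phosphate"),
    five_prime_phosphate = vapply(parsed, `[[`, logical(1), "five_prime_phosphate"),
    stringsAsFactors = FALSE)
  bad_size <- which(out$size != raw$size)
  if (length(bad_size) > 0L) {
    stop(sprintf("declared size disagrees with sequence length for oligo '%s'",
                 out$name[bad_size[1]]), call. = FALSE)
  }
  nparts <- vapply(parsed, function(p) length(p$parts), integer(1))
  out$pad_seq <- out$barcode_seq <- out$annealing_seq <- NA_character_
  three <- nparts == 3L
  out$pad_seq[three] <- vapply(parsed[three], function(p) p$parts[1], character(1))
  out$barcode_seq[three] <- vapply(parsed[three], function(p) p$parts[2], character(1))
  out$annealing_seq[three] <- vapply(parsed[three], function(p) p$parts[3], character(1))
  if (any(out$role == "blocker" & !out$three_prime_phosphate)) {
    stop("blocker rows must carry the '-P' (3'-phosphate) suffix", call. = FALSE)
  }
  class(out) <- c("oligo_panel", "data.frame")
  out
}

#' Built-in canine BRAF V595E oligo panel
#'
#' Loads the oligo panel shipped with the package: the candidate allele
#' primers, opposite primers and blockers used to develop the V595E
#' detection assay, the TA-cloning and standard-construction primers, and
#' the six three-part barcoded sequencing primers.
#'
#' @return An `"oligo_panel"` data frame; see [read_oligo_panel()].
#' @export
#' @examples
#' panel <- braf_panel()
#' subset(panel, role == "blocker")$name
braf_panel <- function() {
  read_oligo_panel(system.file("extdata", "braf_oligos.tsv",
                               package = "blockerpcr", mustWork = TRUE))
}

#' Read / write oligo panels as FASTA
#'
#' FASTA descriptions carry the role and phosphate flags as `key=value`
#' tokens (`role=`, `p3=`, `p5=`), so a panel round-trips losslessly.
#'
#' @param path File path.
#' @param panel An `"oligo_panel"` data frame.
#' @return `read_oligo_fasta()` returns an `"oligo_panel"` data frame;
#'   `write_oligo_fasta()` returns `path` invisibly.
#' @export
read_oligo_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  hdr <- names(ss)
  tok1 <- vapply(strsplit(hdr, "\\s+"), `[[`, character(1), 1)
  getkv <- function(key, default) {
    m <- regmatches(hdr, regexpr(paste0(key, "=\\S+"), hdr))
    vapply(seq_along(hdr), function(i) {
      v <- regmatches(hdr[i], regexpr(paste0(key, "=\\S+"), hdr[i]))
      if (length(v)) sub(paste0(key, "="), "", v) else default
    }, character(1))
  }
  xs <- lapply(seq_along(ss), function(i) {
    oligo(tok1[i], as.character(ss[[i]]),
          role = getkv("role", "opposite_primer")[i],
          three_prime_phosphate = getkv("p3", "false")[i] == "true",
          five_prime_phosphate = getkv("p5", "false")[i] == "true")
  })
  oligo_panel(xs)
}

#' @rdname read_oligo_fasta
#' @export
write_oligo_fasta <- function(panel, path) {
  ss <- Biostrings::DNAStringSet(panel$bases)
  names(ss) <- sprintf("%s role=%s p3=%s p5=%s", panel$name, panel$role,
                       tolower(panel$three_prime_phosphate),
                       tolower(panel$five_prime_phosphate))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
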