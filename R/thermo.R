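# Nearest-neighbor duplex thermodynamics and melting temperature for short
# oligos, using the Breslauer et al. (1986) dinucleotide parameters with the
# classic Schildkraut-Lifson salt correction as applied by the Primer3
# lineage when the Breslauer table is selected.

# Breslauer 1986 nearest-neighbor parameters, indexed by the 5'->3'
# dinucleotide of one strand.  dh in kcal/mol, ds in cal/(mol*K), both as
# positive magnitudes of the helix-formation terms.
.breslauer <- local({
  dinuc <- c("AA", "AC", "AG", "AT", "CA", "CC", "CG", "CT",
             "GA", "GC", "GG", "GT", "TA", "TC", "TG", "TT")
  dh <- c(9.1, 6.5, 7.8, 8.6, 5.8, 11.0, 11.9, 7.8,
          5.6, 11.1, 11.0, 6.5, 6.0, 5.6, 5.8, 9.1)
  ds <- c(24.0, 17.3, 20.8, 23.9, 12.9, 26.6, 27.8, 20.8,
          13.5, 26.7, 26.6, 17.3, 16.9, 13.5, 12.9, 24.0)
  list(dh = stats::setNames(dh, dinuc), ds = stats::setNames(ds, dinuc),
       init_ds = 10.8)  # helix initiation entropy, cal/(mol*K)
})

GAS_CONSTANT <- 1.987  # cal/(mol*K)

#' Reaction-buffer context for melting-temperature calculations
#'
#' Holds the ionic and oligo concentrations that enter the salt and
#' concentration corrections.  The defaults are the assay buffer: 50 mM
#' monovalent cations (K+ and Na+ combined), 2 mM Mg2+, 0.2 mM dNTPs and
#' 0.4 uM of each oligo.
#'
#' @param monovalent_mM Monovalent cation concentration (mM).
#' @param divalent_mM Divalent (Mg2+) concentration (mM).
#' @param dntp_mM Total dNTP concentration (mM); dNTPs chelate Mg2+ and are
#'   subtracted before the divalent-to-monovalent conversion.
#' @param oligo_uM Oligo concentration (uM), used in the C/4 term.
#' @return A list of class `"thermo_context"`.
#' @export
#' @examples
#' ctx <- thermo_context()
#' monovalent_equivalent(ctx)  # about 211 mM
thermo_context <- function(monovalent_mM = 50, divalent_mM = 2,
                           dntp_mM = 0.2, oligo_uM = 0.4) {
  vals <- c(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
            dntp_mM = dntp_mM, oligo_uM = oligo_uM)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all concentrations must be finite and >= 0", call. = FALSE)
  }
  if (oligo_uM <= 0) stop("oligo_uM must be > 0", call. = FALSE)
  structure(as.list(vals), class = "thermo_context")
}

#' Monovalent-equivalent salt concentration
#'
#' Converts the divalent cation concentration (after subtracting chelating
#' dNTPs) into an equivalent monovalent concentration with the
#' von Ahsen/Owczarzy rule `monovalent + 120 * sqrt(max(divalent - dNTP, 0))`,
#' the conversion used by the Primer3 lineage of Tm calculators.
#'
#' @param context A [thermo_context()].
#' @return Monovalent-equivalent concentration in mM.
#' @export
monovalent_equivalent <- function(context = thermo_context()) {
  stopifnot(inherits(context, "thermo_context"))
  context$monovalent_mM +
    120 * sqrt(max(context$divalent_mM - context$dntp_mM, 0))
}

#' Duplex thermodynamics and melting temperature of an oligo
#'
#' Sums the Breslauer nearest-neighbor dinucleotide enthalpies and entropies
#' over the oligo (plus the helix-initiation entropy) and converts them to a
#' melting temperature with
#' `Tm = dH / (dS + R * ln(C/4)) - 273.15 + 16.6 * log10([Na+ equiv] / 1000)`,
#' where `C` is the oligo concentration.  The `C/4` term is the standard
#' choice for a non-self-complementary primer in excess over template.
#'
#' @param oligo An [oligo()] object or a plain DNA sequence (A/C/G/T,
#'   length >= 2).
#' @param context A [thermo_context()].
#' @return A list of class `"duplex_thermo"` with fields `delta_H`
#'   (kcal/mol, negative for a stable duplex), `delta_S` (cal/(mol*K)) and
#'   `tm_celsius`.
#' @export
#' @examples
#' duplex_thermo("TCCTTTACTTACTACACCTC")$tm_celsius
duplex_thermo <- function(oligo, context = thermo_context()) {
  bases <- if (inherits(oligo, "oligo")) oligo$bases else oligo
  assert_bases(bases, min_len = 2L, what = "oligo sequence")
  n <- nchar(bases)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  stacks <- paste0(chars[-n], chars[-1])
  dh <- -sum(.breslauer$dh[stacks])                      # kcal/mol
  ds <- -(sum(.breslauer$ds[stacks]) + .breslauer$init_ds)  # cal/(mol*K)
  conc <- context$oligo_uM * 1e-6                        # mol/L
  tm_k <- (dh * 1000) / (ds + GAS_CONSTANT * log(conc / 4))
  salt <- 16.6 * log10(monovalent_equivalent(context) / 1000)
  structure(list(delta_H = dh, delta_S = ds,
                 tm_celsius = tm_k - 273.15 + salt),
            class = "duplex_thermo")
}

#' @export
print.duplex_thermo <- function(x, ...) {
  cat(sprintf("<duplex_thermo> dH = %.1f kcal/mol, dS = %.1f cal/(mol K), Tm = %.1f C\n",
              x$delta_H, x$delta_S, x$tm_celsius))
  invisible(x)
}

#' Melting temperature of one or more sequences
#'
#' Vectorised convenience wrapper around [duplex_thermo()].
#'
#' @param bases Character vector of DNA sequences.
#' @param context A [thermo_context()].
#' @return Numeric vector of melting temperatures (deg C).
#' @export
oligo_tm <- function(bases, context = thermo_context()) {
  vapply(bases, function(b) duplex_thermo(b, context)$tm_celsius,
         numeric(1), USE.NAMES = FALSE)
}

#' Rank oligos by melting temperature
#'
#' Orders a set of candidate oligos by descending Tm; ties keep input order
#' (stable sort), so equal-Tm candidates are reported in the order designed.
#'
#' @param oligos An `"oligo_panel"` data frame, a list of [oligo()] objects,
#'   or a character vector of sequences.
#' @param context A [thermo_context()].
#' @return A data frame with columns `name`, `bases`, `tm_celsius` (rounded
#'   to 0.1 C) sorted by decreasing Tm.
#' @export
rank_by_tm <- function(oligos, context = thermo_context()) {
  if (inherits(oligos, "oligo_panel") || is.data.frame(oligos)) {
    nm <- oligos$name; seqs <- oligos$bases
  } else if (is.character(oligos)) {
    nm <- names(oligos) %||% oligos; seqs <- unname(oligos)
  } else {
    stopifnot(all(vapply(oligos, inherits, logical(1), "oligo")))
    nm <- vapply(oligos, `[[`, character(1), "name")
    seqs <- vapply(oligos, `[[`, character(1), "bases")
  }
  if (length(seqs) == 0L) {
    return(data.frame(name = character(0), bases = character(0),
                      tm_celsius = numeric(0)))
  }
  tm <- oligo_tm(seqs, context)
  ord <- order(-tm)  # base order() is stable: ties keep input order
  data.frame(name = nm[ord], bases = seqs[ord],
             tm_celsius = round(tm[ord], 1), stringsAsFactors = FALSE)
}
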