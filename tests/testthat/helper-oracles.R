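# Independent oracles used to cross-check the implementation.  These share
# no code with the package internals: the thermodynamic table is a separate
# transcription indexed as a matrix, sequence handling uses chartr, and the
# tally oracle is a plain double loop over reads and patterns.

# string reverse complement without Biostrings
oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# brute-force nearest-neighbor summation over an independently transcribed
# Breslauer (1986) parameter matrix, with the Primer3-style salt handling
oracle_thermo <- function(seq, mono = 50, div = 2, dntp = 0.2, conc_uM = 0.4) {
  b <- c("A", "C", "G", "T")
  dH <- matrix(c(9.1,  6.5,  7.8,  8.6,
                 5.8, 11.0, 11.9,  7.8,
                 5.6, 11.1, 11.0,  6.5,
                 6.0,  5.6,  5.8,  9.1), 4, 4, byrow = TRUE,
               dimnames = list(b, b))
  dS <- matrix(c(24.0, 17.3, 20.8, 23.9,
                 12.9, 26.6, 27.8, 20.8,
                 13.5, 26.7, 26.6, 17.3,
                 16.9, 13.5, 12.9, 24.0), 4, 4, byrow = TRUE,
               dimnames = list(b, b))
  ch <- strsplit(seq, "")[[1]]
  h <- 0; s <- 0
  for (i in seq_len(length(ch) - 1L)) {
    h <- h + dH[ch[i], ch[i + 1]]
    s <- s + dS[ch[i], ch[i + 1]]
  }
  h <- -h
  s <- -(s + 10.8)
  na_eq <- mono + 120 * sqrt(max(div - dntp, 0))
  tm_k <- h * 1000 / (s + 1.987 * log(conc_uM * 1e-6 / 4))
  list(dH = h, dS = s, tm = tm_k - 273.15 + 16.6 * log10(na_eq / 1000))
}

# count occurrences of a fixed pattern in a string (no regex machinery)
oracle_count <- function(pattern, s) {
  hits <- gregexpr(pattern, s, fixed = TRUE)[[1]]
  sum(hits > 0)
}

# brute-force per-barcode tally: every read checked against every barcode
# and both allele signatures on both strands, bucket rules applied inline
oracle_tally <- function(reads, barcode_ids, barcode_seqs, wt_sig, mu_sig) {
  out <- data.frame(barcode_id = barcode_ids, n_wt = 0L, n_mu = 0L,
                    n_ambiguous = 0L, n_barcode_only = 0L,
                    stringsAsFactors = FALSE)
  n_unassigned <- 0L
  for (r in reads) {
    both <- c(r, oracle_revcomp(r))
    bc_hits <- vapply(barcode_seqs, function(b) {
      sum(vapply(both, oracle_count, integer(1), pattern = b)) > 0
    }, logical(1))
    wt_hit <- sum(vapply(both, oracle_count, integer(1), pattern = wt_sig)) > 0
    mu_hit <- sum(vapply(both, oracle_count, integer(1), pattern = mu_sig)) > 0
    if (sum(bc_hits) != 1L) {
      n_unassigned <- n_unassigned + 1L
      next
    }
    j <- which(bc_hits)
    if (wt_hit && mu_hit) out$n_ambiguous[j] <- out$n_ambiguous[j] + 1L
    else if (wt_hit) out$n_wt[j] <- out$n_wt[j] + 1L
    else if (mu_hit) out$n_mu[j] <- out$n_mu[j] + 1L
    else out$n_barcode_only[j] <- out$n_barcode_only[j] + 1L
  }
  attr(out, "n_unassigned") <- n_unassigned
  out
}

random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len[i], replace = TRUE), collapse = "")
  }, character(1))
}

fixture_sig <- function() allele_signature(build_fixture_templates()$nanopore)
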