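---
title: "Methods: blocker-mediated allele-specific PCR, from thermodynamics to allele ratios"
author: "blockerpcr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: blocker-mediated allele-specific PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockerpcr)
```

# The assay model

A blocker-mediated allele-specific PCR discriminates a single-nucleotide
substitution by combining two oligos on the same strand:

* an **allele-specific primer** whose 3′ terminal base sits exactly on the
  variant and carries the mutant base — a 3′ mismatch on wild-type
  template stalls extension;
* a **blocker**, fully complementary to the wild-type sequence with the
  variant at its centre and a 3′-phosphate so it cannot prime.  On
  wild-type template it outcompetes the primer (perfect match vs 3′
  mismatch); on mutant template the roles reverse (central mismatch vs
  perfect-match primer).

Discrimination is therefore a competition of duplex stabilities, which is
why the melting temperatures of the primer and blocker — and the *gap*
between them — are the central design quantities.  Detection is read out
by qPCR (Ct plus a melting-curve peak) and, orthogonally, by counting
barcoded amplicon sequencing reads.

# Melting temperatures

`duplex_thermo()` implements the classic nearest-neighbor computation:
the duplex enthalpy and entropy are sums of the Breslauer (1986)
dinucleotide parameters plus a helix-initiation entropy of
−10.8 cal/(mol·K), and

$$T_m = \frac{\Delta H}{\Delta S + R\,\ln(C/4)} - 273.15
      + 16.6\,\log_{10}[\mathrm{Na^+_{eq}}]$$

with $C$ the oligo concentration (the $C/4$ form assumes a
non-self-complementary oligo in excess over template, the standard PCR
situation) and the Schildkraut–Lifson salt term evaluated at the
monovalent-equivalent concentration

$$[\mathrm{Na^+_{eq}}] = [\mathrm{mono}] +
  120\sqrt{\max([\mathrm{Mg^{2+}}] - [\mathrm{dNTP}],\,0)} \;\;
  \mathrm{(mM)},$$

the divalent conversion used by the Primer3 lineage of calculators (dNTPs
chelate magnesium, hence the subtraction; the clamp at zero handles dNTP
excess).  Defaults (`thermo_context()`): 50 mM monovalent cations, 2 mM
Mg²⁺, 0.2 mM dNTPs, 0.4 µM oligo — the assay buffer.  Temperatures are
reported to 0.1 °C, matching the precision at which melt windows are
specified; the Breslauer table is internally reverse-complement symmetric,
so `Tm(s) == Tm(revcomp(s))` holds to machine precision (tested on random
oligos).

The choice of the Breslauer table (rather than the later unified
parameters) is deliberate: it is the parameter set under which this
assay's oligo families were designed, and only *relative* orderings and
gaps within the panel matter downstream.  Absolute Tm accuracy is not a
goal; no dangling-end, mismatch or secondary-structure terms are included.

# Design geometry and scoring

`make_allele_primer()` anchors the primer 3′ end on the variant
(forward strand for a "downstream" assay, reverse strand for "upstream");
`make_blocker()` centres the variant at position `ceiling(L/2)` of the
blocker's own strand — exact centre for odd lengths, one base 5′ of centre
for even lengths, the convention consistent with the shipped panel's
even-length blocker.  `enumerate_candidates()` forms the full Cartesian
product of allele primers × blockers × opposite primers and scores each
combination:

```
score = 10 − |Tm_blocker − Tm_allele − Δ*| − 2·[allele is family max] − 2·[blocker is family max]
```

The score encodes two empirical failure modes: a blocker far hotter than
its primer suppresses mutant amplification too, and the hottest member of
either family is the one that loses specificity (the hottest allele primer
amplifies wild type; the hottest blocker slows everything).  The target
gap Δ* defaults to **+5 °C** (blocker hotter than primer).  No
quantitative ideal gap is established anywhere we know of, so Δ* is an
exposed, documented guess; the score is a pre-ranking aid to shrink the
screening matrix, never a claim about which combination a screen would
pick.  With the shipped panel it does place the 18-mer primer + 21-mer
blocker pairing (gap 5.2 °C) first and the 25-mer blocker last, which the
test suite keeps as a regression check of the heuristic, not as ground
truth.

# qPCR call logic

`classify_specific()` deems a well specific iff it amplified (Ct present)
**and** its melt peak lies inside the closed window [80, 81] °C
(`melt_window()`); "outside the range 80–81 °C" defines non-specific, so
the boundary itself is acceptable.  A recorded Ct without a melt peak is
non-specific — specificity cannot be established.  `call_sample()` calls
a sample positive when **any** replicate is specific with
`ct ≤ ct_cutoff`; a single specific replicate suffices (any specific
amplification is detection; a majority rule would trade sensitivity for
nothing in this assay, though the cutoff is configurable).  The default
cutoff equals the run's cycle count: 45- and 50-cycle verification runs
accept all specific events, while 90-cycle screening runs — which exist
precisely to surface very late breakthrough — are normally re-called with
`ct_cutoff = 45`, so a specific event at Ct ≈ 75 from trace template
counts as a screening observation, not a positive.

`build_dilution_series()` is exact integer arithmetic
(`round(start/fold^i)`), and `fit_ct_vs_logcopies()` is ordinary least
squares of Ct on log₁₀(copies) over the specific, amplified wells only,
reporting the Pearson r.

# Read counting

A read is assigned to a sample when exactly one panel barcode (24-mer)
occurs in it, and to an allele when exactly one of the two signature
k-mers occurs; both searches run on the read and its reverse complement.
`max_mismatch = 0` (the default) makes this an exact fixed-string search;
`max_mismatch > 0` switches to Biostrings approximate matching for
realistic raw nanopore reads.  Bucket rules: ≥ 2 different barcodes →
presumed chimera, unassigned; both signatures → ambiguous; barcode
without signature → counted for depth accounting only.  These buckets
partition every read, a conservation law the suite checks against a
brute-force oracle.

The signature defaults to **k = 11**, centred on the variant: long enough
to be unique within the 137-bp amplicon and not to arise by chance in
junk reads (4¹¹ ≈ 4×10⁶), short enough to survive errors at a usable
rate, and positioned clear of the annealing parts.  The ratio is
`100·n_mu/(n_wt+n_mu)` rounded **half-up** to one decimal (the precision
of reported mutation ratios; round-half-even would bias boundary cases
down).  `sufficient_depth` requires ≥ 1000 allele-informative reads
before a ratio is reportable, and `call_from_ratio()` uses a positive
threshold of 0%: any mutant reads call positive.  Observed positives in
our reference tables sit at ≥ 0.1% and negatives at exactly 0.0%, so 0 is
the maximally sensitive threshold consistent with that separation; it is
a parameter, not a law.

# What the simulators emulate — and what they do not

`build_fixture_templates()` stitches the two amplicon templates from the
shipped oligo panel so that every primer, blocker and annealing part
occurs character-exact on its proper strand and allele (wild-type base T,
mutant base A at the variant).  The stretches between those landmarks are
**fixed arbitrary spacers**: the real intervening sequence is not
printed anywhere machine-readable, so the templates are labelled
synthetic and reproduce the assay's geometry — including the 137-bp
sequencing amplicon and 176-base barcoded read body — not the genome.
Tests verify the spacers collide with no oligo, barcode or signature.

`simulate_reads()` draws each read's allele from a Bernoulli with the
true mutant fraction, prepends pad + barcode, applies i.i.d. per-base
substitution/insertion/deletion errors, and reverse-complements with
probability `1 − p_forward` (default 0.5, matching a library readable
from both ends).  Qualities are constant placeholders — counting is
sequence-only by design.

The **default error profile is indel-dominated and substitution-free**
(`sub_rate = 0`, `ins_rate = 0.001`, `del_rate = 0.002`).  This is a
considered choice, not an oversight.  Under exact-match counting, an
i.i.d. substitution rate $s$ converts wild-type reads into perfect
mutant-signature matches at rate $\approx s/3$ per read (one specific
base change at the variant site, remaining signature intact), imposing a
floor of $\approx 100·(s/3)/(1-s)$ % on every measured ratio: ~1% floor
at a "raw nanopore" $s = 0.03$, which would make true-negative samples
indistinguishable from the ~1% true positives this assay exists to
detect.  The assay's observed behaviour — 0.0% ratios over > 10³ counted
reads in negative samples, and a measured 0.1% true positive — shows the
*effective* substitution floor of exact-match counting on demultiplexable
reads is far below one part in 10³: real errors are correlated within
reads, so reads whose 24-mer barcode and 10 other signature bases are
perfect are strongly enriched for being error-free at the variant site
too, a selection an i.i.d. model cannot express.  The default therefore
models the effective post-filter error process: indels (which provably
cannot fabricate the exact mutant k-mer — they only drop reads from the
count, a property the suite tests) carry the residual error, and
`sub_rate` remains available for studying raw-accuracy regimes, where
users should expect exactly the ratio floor described above.

`simulate_qpcr()` gives mutant-bearing wells
`ct = intercept + slope·log₁₀(copies) + N(0, σ)` with defaults
slope −3.32 (perfect doubling), intercept 43.1 (placing 9000 copies at
Ct ≈ 30, the observed anchor), σ = 0.3 cycles, and a specific melt peak
N(80.5, 0.15) concentrated inside the window.  Wells without mutant
template stay flat except for rare breakthrough events
(`wt_breakthrough_prob`, default 0.01): always very late
(Ct ~ U(60, 85)), with the melt peak specific or non-specific with equal
probability — reproducing both observed failure modes (a late specific
trace event, and non-specific products).  Breakthroughs are *always*
late; the simulator does not model a systematically leaky blocker, which
in reality would produce earlier wild-type amplification (that regime can
be explored by raising `wt_breakthrough_prob` and lowering the cutoff,
but no parameter makes breakthrough early).  Consequently, the
zero-false-positive property of the call logic at `ct_cutoff = 45` is a
structural fact of the simulator — the tests document that the *pipeline*
never converts a late/non-specific event into a positive, not that the
wet assay cannot produce a false positive.

Passing tests on these simulators show the computational pipeline is
correct and well-calibrated under its stated assumptions; they cannot
show that real urine-sediment DNA, real polymerase kinetics or real
nanopore error structure satisfy those assumptions.

# Numerical choices and degenerate inputs

* Ratio rounding half-up to 1 decimal; extrema over empty ratio sets are
  `NA`, and "n.t." parses as missing, never zero.
* `rank_by_tm()` and candidate ranking use stable orderings: ties keep
  input (design) order.
* Tm requires length ≥ 2 and a strict A/C/G/T alphabet; violations are
  rejected naming the offending position.
* Empty candidate lists enumerate to empty tables; an empty sample table
  summarises to zeros; a tally with no informative reads has an undefined
  (`NA`) ratio and is `insufficient`, not negative.
* Sample ids normalise en dashes to hyphens on input; duplicates are
  rejected rather than silently collapsed.
* All simulators take an explicit integer seed; identical seeds give
  byte-identical output (tested down to the FASTQ text).

# Problem sizes

The shipped suite exercises: 10⁵-read tallies for ratio recovery at the
studied fractions (1.4% and 0%), 20 random fractions in [0.001, 0.5] at
10⁴ reads each for binomial-recovery calibration, 10³-read brute-force
oracle comparisons, 10³ random oligos for thermodynamic symmetry and salt
monotonicity, and 10³ seeded qPCR screens for the zero-false-positive
property.  These sizes make the statistical assertions sharp (binomial SE
of the ratio at 10⁵ reads is 0.04 percentage points) while the whole
suite completes in well under a minute on a laptop core.

# Known limitations

* Tm values are panel-relative (Breslauer parameters, no mismatch
  thermodynamics); do not compare them with calculators using the unified
  parameter set.
* The candidate score is a documented heuristic with a guessed Δ*; it
  pre-ranks, it does not predict screens.
* The fixture templates are synthetic between oligo landmarks; counting
  results transfer to real amplicons only insofar as the signatures
  remain allele-exclusive there.
* The i.i.d. error model cannot represent quality-correlated nanopore
  errors; see the error-profile discussion above.
* No raw fluorescence or melt-curve processing: Ct and peak temperatures
  enter as given scalars.  No genome-wide primer uniqueness or
  hairpin/dimer screening.
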