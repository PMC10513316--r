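# blockerpcr

Design and analysis of **blocker-mediated allele-specific PCR assays** for
detecting a single-nucleotide substitution at low allele fraction — the
motivating case being the canine *BRAF* V595E mutation (a T→A substitution
homologous to human V600E) in urine-sediment DNA, where carcinoma cells may
contribute only a small fraction of the template.

The assay couples an **allele-specific primer**, whose 3′ terminal base sits
on the variant and matches only the mutant allele, with a
**3′-phosphorylated blocker** that is fully complementary to the wild-type
sequence across the variant and competitively prevents the primer from
extending on wild-type template. Because the blocker carries the variant at
its centre, it binds wild-type template more tightly than the one-mismatch
mutant template, so amplification proceeds essentially only from the mutant
allele. Positive/negative discrimination then comes from qPCR: a well is
called positive when it amplifies within a Ct cutoff **and** its
melting-curve peak falls inside the specific product's melt window
(80–81 °C by default). Orthogonal quantification uses barcoded amplicon
sequencing: reads in which a sample barcode and an allele-discriminating
k-mer co-occur are counted, and the mutant allele ratio for barcode *b* is

    ratio_b = 100 × n_mu / (n_wt + n_mu)  [%]

The package is aimed at assay developers and bioinformaticians who want a
tested, reproducible implementation of this workflow: every wet-lab input
is replaced by a synthetic generator, so the full pipeline runs and is
validated entirely in silico.

## What's inside

| Module | Functions |
|---|---|
| Thermodynamics | `duplex_thermo()`, `oligo_tm()`, `rank_by_tm()` — Breslauer nearest-neighbor ΔH/ΔS with `Tm = ΔH/(ΔS + R ln(C/4)) − 273.15 + 16.6 log₁₀[Na⁺eq]`, divalent ions converted by `monovalent + 120·√(Mg²⁺ − dNTP)` |
| Design | `snv_locus()`, `make_allele_primer()`, `make_blocker()`, `enumerate_candidates()`, `score_candidate()` |
| qPCR calls | `classify_specific()`, `call_sample()`, `build_dilution_series()`, `fit_ct_vs_logcopies()` |
| Read counting | `allele_signature()`, `classify_reads()`, `tally_reads()`, `call_from_ratio()` |
| Concordance | `read_sample_table()`, `summarize_concordance()`, `discordance_pattern()` |
| Simulators | `build_fixture_templates()`, `simulate_reads()`, `simulate_qpcr()`, `simulate_dilution()`, `mix_standards()` |
| CLI | `run_cli()` / installed `exec/blockerpcr` script |

The built-in oligo panel (`braf_panel()`) ships the assay's 14 candidate
primers, 6 blockers and 6 three-part barcoded sequencing primers; the
fixture amplicon templates are stitched from those oligos with synthetic
spacers (they reproduce the assay geometry, not the genomic sequence).

## Worked example

```r
library(blockerpcr)

## 1. rank primer/blocker combinations around the variant
locus <- locus_from_template(build_fixture_templates()$detection)
opp   <- subset(braf_panel(), name %in% c("R4","R5","R6","R7","R8"))
cand  <- enumerate_candidates(locus, allele_lengths = 18:20,
                              blocker_lengths = c(21, 23, 25),
                              opposite_primers = opp)
head(cand[order(cand$rank), c("allele_name","blocker_name","tm_allele",
                              "tm_blocker","score","rank")], 3)
#>             allele_name          blocker_name tm_allele tm_blocker score rank
#> 1  allele_downstream_18 blocker_downstream_21      66.7       71.9   9.8    1
#> 10 allele_downstream_18 blocker_downstream_21      66.7       71.9   9.8    2
#> 19 allele_downstream_18 blocker_downstream_21      66.7       71.9   9.8    3
```

The 18-mer allele primer with the 21-mer blocker (the F4/BF1 pairing of the
shipped panel, Tm gap 5.2 °C) ranks first; the hottest 25-mer blocker is
penalised and ranks last.

```r
## 2. count barcoded reads at a true mutant fraction of 1.4%
tpl <- build_fixture_templates()$nanopore
sig <- allele_signature(tpl)                    # CACAGTGAAAT vs CACAGAGAAAT
cfg <- read_sim_config(n_reads = 20000, true_mu_fraction = 0.014,
                       sub_rate = 0, ins_rate = 0, del_rate = 0, seed = 42)
tally <- tally_reads(simulate_reads(tpl, "BC1", cfg), sig = sig)
tally[1, ]
#>   barcode_id  n_wt n_mu n_ambiguous n_barcode_only ratio_percent sufficient_depth
#> 1        BC1 19714  286           0              0           1.4             TRUE
call_from_ratio(tally)[1]
#> [1] "positive"

## 3. dilution-series sensitivity: Ct is log-linear in copy number
fit_ct_vs_logcopies(as_dilution_points(simulate_dilution(qpcr_sim_config(seed = 1))))
#> <dilution_fit> ct = -3.33 * log10(copies) + 43.19  (r = -0.996, n = 18)

## 4. concordance of the assay against Sanger calls on the shipped tables
first  <- read_sample_table(system.file("extdata", "first_verification.csv",
                                        package = "blockerpcr"))
second <- read_sample_table(system.file("extdata", "second_verification.csv",
                                        package = "blockerpcr"))
summarize_concordance(list(first, second))
#> <concordance> 38 samples: 34 concordant, 4 discordant
#>   Sanger: 16 positive / 22 negative; blocker assay: 20 / 18
#>   discordant: 1-4, 1-6, 1-20, 2-11
#>   sequencing ratio among Sanger positives: 14.3-49.6%
```

The 286/20000 mutant reads give a ratio of 1.4%, matching the injected
fraction; the dilution fit recovers the simulator's slope of −3.32
cycles/log₁₀(copies) within noise; and all four discordant samples sit in
the Sanger-negative / assay-positive cell, each with a sequencing ratio
(0.1–1.4%) far below the ~15% detection floor of chromatogram-based
calling.

## Command line

```sh
blockerpcr dilution --start 9000 --fold 3 --steps 6
blockerpcr count --fastq reads.fastq --min-reads 1000 --out tally.tsv
blockerpcr concord --calls inst/extdata/first_verification.csv
blockerpcr simulate reads --n 10000 --mu-fraction 0.014 --seed 1 --out reads.fastq
```

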