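# ribocomp

Mechanistic modelling of how transcripts compete for a limited pool of free
ribosomes, and of what happens to that competition when translation
elongation is crippled — for example by depleting elongation factor 2
(eEF2), the enzyme that catalyses ribosome translocation. The package is
aimed at people studying translational control with polysome profiles and
paired Ribo-seq/mRNA-seq data who want a quantitative, testable account of
*mTOR-independent* preferential translation of high-initiation (5'-TOP /
ribosomal-protein) transcripts.

## The model

A transcript with initiation rate constant *k<sub>i</sub>*, elongation rate
*k<sub>e</sub>* (codons/time), mRNA level *m* and ribosome footprint *L*
codons produces protein at the steady-state rate

    Q = m R k_i [ 1 − L / (k_e/(k_i R) + L − 1) ]

where *R* is the free-ribosome level and the bracket is the probability
that the initiation region is unobstructed. The model is valid for
*k<sub>e</sub>/(k<sub>i</sub>R) ≥ 1*; at equality the entry jams and *Q* = 0.

Around this core the package provides:

* **Whole-cell closure** — solve for the free pool under total-ribosome
  conservation (`solve_free_ribosomes`), predict sucrose-gradient class
  fractions (`polysome_fractions`), and run knockdown scenarios
  (`simulate_knockdown`). Two scenario modes exist: a uniform
  *k<sub>e</sub>* scaling (which, as the vignette derives, almost exactly
  cancels out of relative yields) and the default eEF2 mode, in which each
  codon's dwell is recruitment (∝ eEF2 availability) followed by
  translocation slowed by positively charged nascent residues — so
  depletion differentially *relieves* charge-rich transcripts such as
  ribosomal proteins.
* **A stochastic lattice simulator** (`simulate_transcript`, Gillespie
  exclusion process with extended particles and the two-phase dwell) used
  as brute-force oracle for the closed form, plus `charge_penalty` to
  quantify the relief mechanism.
* **A synthetic-omics generator** (`generate_transcriptome`,
  `generate_counts`) producing paired mRNA-seq/Ribo-seq negative-binomial
  count matrices for control vs knockdown with a TOP-like gene class and a
  full truth table.
* **Self-contained TE statistics** (`size_factors`,
  `translation_efficiency`, `differential_te`, `class_enrichment`) —
  median-of-ratios normalisation, paired label-permutation tests with
  exhaustive enumeration when feasible, BH correction, rank-based class
  enrichment.
* **A pipeline runner** (`run_pipeline`) writing all artifacts with a
  checksummed manifest for byte-level reproducibility.

## Worked example

```r
library(ribocomp)

tx <- generate_transcriptome(n_genes = 200, top_fraction = 0.1, seed = 1)
kd <- simulate_knockdown(tx, calibrate_r_total(tx), knockdown_scenario(0.05))
kd
#> knockdown_result (mode eEF2, f = 0.05)
#>   baseline : pool_state: R_total = 21.1878, R_free = 1.1825 (5.58%), E = 1, residual = 6.89e-12
#>   knockdown: pool_state: R_total = 21.1878, R_free = 0.223919 (1.06%), E = 0.05, residual = 1.50e-09
#>   median relative log2 yield change by class:
#>     other  -0.141
#>     TOP    +0.967
```

A 95% factor knockdown (`f = 0.05`) depletes the free ribosome pool about
five-fold (5.6% → 1.1% of total), shifts polysome signal into the heavy
fraction, and redistributes synthesis: the median TOP-class gene gains
almost one log2 unit of *relative* protein output while the background
class loses. Feeding the same transcriptome through the synthetic
sequencing experiment and the statistics:

```r
exp <- generate_counts(tx, seed = 2)
res <- differential_te(exp, n_perm = 1000, seed = 3)
class_enrichment(res, n_perm = 10000, seed = 4)
#> class_enrichment: z = +4.602, p = 9.999e-05 (greater; 20 vs 180 genes, 10000 permutations)
```

The TOP class is detected as shifted upward with p ≈ 1e-4 from three
replicates per condition — class-level inference is the reliable readout at
this design size, while per-gene ranks remain noise-limited (see the
vignette's discussion of the 3-replicate permutation floor and the
occupancy-versus-flux caveat).

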