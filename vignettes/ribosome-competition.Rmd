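---
title: "Modelling transcript competition for ribosomes under elongation-factor depletion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcript competition for ribosomes under elongation-factor depletion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribocomp)
```

## The problem

When translation elongation is impaired -- for instance by depleting
eukaryotic elongation factor 2 (eEF2), the factor that catalyses ribosome
translocation -- ribosomes dwell longer on mRNA. Three things are then
observed in tissue: the free ribosomal subunit pool shrinks, polysomes shift
from light to heavy fractions, and transcripts with high initiation rates
(classically the 5'-TOP mRNAs encoding ribosomal proteins) are
translationally favoured relative to everything else, without any mTOR
signalling involvement. `ribocomp` packages a mechanistic account of these
observations: a closed-form steady-state competition model, a whole-cell
ribosome-conservation closure, a stochastic lattice simulator that serves as
the model's oracle, and a synthetic Ribo-seq/mRNA-seq pipeline that lets the
statistical machinery be tested against known ground truth.

## The closed-form yield model

For a transcript with initiation rate constant $k_i$, elongation rate $k_e$
(codons per time unit), mRNA abundance $m$ and ribosome footprint $L$
(codons), competing for free ribosomes at level $R$, the steady-state protein
production rate is

$$Q = m R k_i \left[ 1 - \frac{L}{k_e/(k_i R) + L - 1} \right],$$

where the bracket is the probability that the initiation region is not
occluded by an elongating ribosome. Writing $u = k_e/(k_i R)$, the bracket
equals $(u-1)/(u+L-1)$: it is 1 when elongation is fast relative to
initiation pressure ($u \to \infty$) and reaches 0 exactly at the jamming
boundary $u = 1$, where the model's validity ends. `ribocomp` treats $u < 1$
as a hard error rather than clamping -- silent clamping would let a
mis-configured solver pass unnoticed.

All units are dimensionless model units; only ratios and the combination
$x = k_i R / k_e = 1/u$ carry meaning.

Per mRNA copy, the expected number of elongating ribosomes follows from
Little's law: the initiation flux $Q/m$ times the transit time
$n_{\mathrm{codons}}/k_e$, giving
$N = n\,p(u)/u$ -- a function of $u$ alone. $N$ is maximal at an
intermediate $u^\ast(L)$ (about 4.1 for $L = 10$): below it, additional
initiation pressure *reduces* the carried load because the entry region
clogs. This matters twice below.

## Whole-cell closure and its surprise

`solve_free_ribosomes()` closes the model over a transcriptome with total
ribosome conservation, $R_{\mathrm{free}} + \sum_g m_g N_g(R_{\mathrm{free}})
= R_{\mathrm{total}}$, by Brent root finding on a bracket capped below the
jam boundary of the most jam-prone gene. Uniqueness is guaranteed where all
genes sit on the increasing branch of $N$ ($u > u^\ast$); the default
transcriptome places its TOP class slightly beyond the peak (they are both
high-initiation and slow-elongating), but the aggregate bound curve remains
monotone because TOP genes carry a small share of total mRNA.

A knockdown scenario that scales every gene's $k_e$ by the residual factor
$f$ turns out to be *almost inert* for relative yields, a result we believe
is worth stating prominently. Because $N$ depends on $u$ only, conservation
forces the solved free pool to drop nearly in proportion to $k_e$: the
freed ribosomes ($R_{\mathrm{free}}$ is a small fraction of
$R_{\mathrm{total}}$) are absorbed by a slight *decrease* of every gene's
$u$. Relative yields therefore move only through the second-order spread of
$\mathrm{d}\log p / \mathrm{d}\log u$ -- and in the direction that slightly
*disfavours* high-$k_i$ genes. The intuitive argument "free ribosomes fall,
therefore high-initiation transcripts win" silently holds $k_e$ fixed; when
elongation itself is the perturbed quantity, the two effects cancel almost
exactly. The `ke_uniform` scenario mode exposes this cancellation and the
test suite pins its magnitude (below 0.01 log2 units for a twenty-fold
knockdown in a two-gene system).

## The charge-relief mechanism, and why it is the default

What breaks the cancellation is the second mechanism: elongation is a
two-phase dwell per codon,

* factor recruitment at rate $k_{\mathrm{bind}} \cdot E$, sequence
  independent, where $E$ is eEF2 availability;
* translocation at rate $k_{\mathrm{trans0}} \cdot e^{-\beta q}$, where $q$
  counts positively charged residues (K/R) among the $W$ residues of nascent
  peptide preceding the codon -- the electrostatic drag of the exit tunnel.

The effective elongation rate is the harmonic combination
$k_e(E) = [1/(k_{\mathrm{bind}}E) + \overline{e^{\beta q}}/k_{\mathrm{trans0}}]^{-1}$.
At full availability the translocation term dominates and charge-rich
transcripts elongate measurably slower; as $E \to 0$ the recruitment wait
dominates *identically for every transcript*, so the relative charge penalty
melts away. Ribosomal-protein mRNAs are exactly the charge-rich,
high-initiation class, so depletion hands them a differential elongation
relief on top of their initiation advantage. The default `"eEF2"` scenario
mode implements this: baseline rates are computed at $E = 1$ and knockdown
rates at $E = f$, per gene, from charge content. With it, the package
reproduces all the qualitative signatures simultaneously: free-pool
depletion, light-to-heavy polysome shift, and a positive median relative
yield change of the TOP class with a negative median for the rest.

```{r knockdown}
tx <- generate_transcriptome(n_genes = 200, top_fraction = 0.1, seed = 1)
kd <- simulate_knockdown(tx, calibrate_r_total(tx), knockdown_scenario(0.05))
kd
```

## Parameter defaults and their rationale

| parameter | default | meaning and basis |
|---|---|---|
| `depletion_factor` | 0.05 | residual eEF2, a ~95% knockdown |
| `k_bind`, `k_trans0` | 20, 10 | recruitment faster than translocation at $E=1$, so the charge penalty is expressed at baseline and relieved under depletion |
| `beta` (generator) | 0.5 per residue | sized so the charge effect rivals the initiation-constant effect, as the biology suggests |
| `beta`, `W` (simulator default) | 0.15, 10 | deliberately conservative defaults for free exploration; every study-level run passes its own charge model |
| TOP $k_i$ | log-normal, median 1, sdlog 0.2 | ten-fold initiation advantage over background (median 0.1, sdlog 0.4) |
| charge fraction | TOP $\mathcal N(0.25, 0.05)$, other $\mathcal N(0.10, 0.05)$, clipped to $[0.02, 0.45]$ | K/R-rich ribosomal proteins versus proteome background |
| coding length | TOP 80--250, other 150--600 codons | ribosomal proteins are short |
| congestion target | median TOP gene at $u = 1.8$ | TOP transcripts partly elongation-limited at baseline, per their slow measured elongation |
| NB dispersion | log-normal, median 0.01, sdlog 0.4 | deep bulk libraries from inbred animals |
| design | 3 vs 3, paired assays, library sizes $\pm 20\%$ | three animals per group; normalisation must do real work |

`calibrate_r_total()` converts the congestion target into a total ribosome
level; the resulting baseline free pool is a few percent of the total, and a
95% knockdown shrinks it several-fold while heavy polysomes grow -- the
directions seen in sucrose gradients. The baseline here is polysome-dense
(monosome-to-polysome ratios are small); the model reproduces the
*directions* of gradient changes, not absolute peak shapes.

## The lattice simulator as oracle

`simulate_transcript()` runs a continuous-time Markov (Gillespie direct)
simulation of ribosomes as extended particles (footprint $L$) with the
two-phase dwell, steric exclusion, initiation only into a vacant entry
region, and termination at the last codon. It is the brute-force check on
the closed form: in the initiation-limited regime ($x \le 0.1$, uncharged
sequence) the simulated production rate agrees with $Q/m$ (using the
harmonic $k_e$) within about 5--10%, which is the accuracy class of the
closed form itself -- the bracket term is a mean-field approximation, not an
exact exclusion-process result. The simulator also validates the
polysome-profile assumption: at low density the lattice behaves like an
infinite-server queue, so ribosomes-per-mRNA is near-Poisson; the
total-variation distance of the empirical load histogram from a truncated
Poisson with matched mean is a few percent. This is exactly the law
`polysome_fractions()` assumes, truncated at the steric capacity
$\lfloor n/L \rfloor$.

Standard errors of production rates come from splitting the measurement
window into 20 blocks, which absorbs temporal correlation of the completion
stream. Two runs with the same seed are bit-identical; the R RNG drives the
C++ core.

`charge_penalty()` quantifies the relief mechanism directly: the
uncharged-over-charged production ratio $P(E)$ falls from clearly above 1 at
$E = 1$ towards 1 under depletion, with an analytic transit-time limit
(`charge_penalty_analytic()`) confirming $P \to 1$ as $E \to 0$.

## What the synthetic experiment does and does not emulate

`generate_counts()` produces paired mRNA-seq and Ribo-seq count matrices.
Expected mRNA counts are proportional to transcript abundance; expected
footprint counts are proportional to abundance times ribosomes-per-mRNA at
the solved pool -- footprints sample *occupancy*, so stalled ribosomes raise
footprint signal. Each sample is depth-normalised to a nominal library size
(so global occupancy shifts are not directly observable, as in real
sequencing), with per-sample library factors and per-gene NB dispersions.

It does not emulate: UTRs or positional read structure, transcriptional
responses, isoforms, time-course dynamics, batch effects, or proteomics.
Passing tests therefore demonstrate that the statistics recover the model's
occupancy-driven truth under calibrated noise -- not that they would survive
every artefact of real libraries.

One substantive consequence of the occupancy convention deserves emphasis.
Whether a transcript's footprint-density TE moves with or against its
synthesis flux depends on which side of the load peak $u^\ast$ it sits.
On the uncongested branch ($u > u^\ast$), charge relief would raise TOP
yield share while *lowering* their relative occupancy -- flux and TE
diverging across classes, a caveat familiar from Ribo-seq under elongation
inhibitors. Because the default transcriptome places TOP genes on the
congested branch (slow elongation plus high initiation), relief of their
entry congestion raises initiation success and occupancy together: the TOP
class gains both yield share and relative TE, which is the direction real
footprint data show. The per-gene tables report both quantities
(`rel_log2_change` and `dte_log2`) so the distinction stays visible, and
the branch dependence is a genuine, testable prediction of the model.

## Statistics

* **Size factors**: median-of-ratios against a per-gene geometric-mean
  reference over all-positive genes, rescaled to geometric mean 1. With a
  pseudocount of 0 the difference statistic is exactly invariant to
  rescaling any single sample; the default pseudocount (0.5) bounds the
  distortion by roughly pseudocount/count.
* **Differential TE**: per-gene difference of condition means of per-sample
  log2 TE; the null permutes condition labels of whole samples, jointly
  across assays, preserving the paired structure. All
  $\binom{n}{n_{kd}}$ assignments are enumerated when there are at most
  10,000 (p-values then live on the grid $k/n_{\mathrm{assign}}$ and are
  never 0 because the observed labelling is included); otherwise sampled
  permutations use the add-one estimator. BH q-values are computed over
  genes passing the count filter (default: at least 10 summed counts in
  each assay).
* **Discreteness floor**: a 3v3 design has 20 label assignments whose
  statistics come in sign-symmetric pairs, so the smallest attainable
  two-sided p is 0.1. Calibration is therefore meaningful at level 0.1
  (where the test is exact), while rejection at nominal 0.05 is
  structurally impossible at this replication -- a property of any paired
  permutation test at $n = 3$, worth knowing before planning analyses.
* **Class enrichment**: standardised rank sum of the focal class's TE
  changes, one-sided by default, with a label-permutation p-value.

On default synthetic data the TOP class is detected as shifted (one-sided
p well below 0.01) even though per-gene rank recovery is noise-limited:
with three replicates and realistic dispersion the per-gene standard error
of the TE change (~0.15 log2 units) is comparable to most true effect
sizes, bounding the Spearman correlation between truth and estimate at
roughly 0.7. Class-level inference is the reliable readout at this design
size; per-gene rankings are not.

## Numerical choices

Root finding uses `stats::uniroot` on
$[10^{-12} R_{\mathrm{total}},\ \min(R_{\mathrm{total}},
(1-10^{-9})\min_g k_e/k_i)]$ with a residual tolerance of
$10^{-8}R_{\mathrm{total}}$ (polished by bisection if needed); an
infeasible bracket raises a jamming error naming the binding gene. The
jamming boundary itself is treated as valid with $Q = 0$ (closed set).
Polysome class signal is scaled so the bound classes account for exactly
$1 - R_{\mathrm{free}}/R_{\mathrm{total}}$ (the truncation mass of the
Poisson law is absorbed by the scaling); an empty polysome compartment is
flagged and the monosome-to-polysome ratio reported as infinite.
Permutation comparisons use a $10^{-12}$ slack so ties are counted as hits.
Stage seeds in the pipeline derive from the master seed by fixed offsets,
so one stage's draw count cannot perturb another's stream.

Test and acceptance workloads use 200-gene transcriptomes, lattice runs of
order $10^4$ time units, 1,000 sampled permutations (or exhaustive
enumeration when smaller), and 10,000 enrichment permutations -- sizes at
which every stochastic check has comfortable Monte-Carlo margin.

## Known limitations

* The closed form is mean-field; near the jamming boundary and at high
  density only the lattice simulator is trustworthy.
* $R_{\mathrm{total}}$ is an input per scenario; ribosome biogenesis
  feedback over days is out of scope.
* The truncated-Poisson polysome law is justified at low-to-moderate
  density and checked against the simulator there; strongly congested
  transcripts will be over-dispersed relative to it.
* The charge model uses a single exponential penalty with a fixed trailing
  window; no codon-specific decoding rates, drop-off, or collision-coupled
  quality control.
* Charge relief plus entry saturation imply opposite-sign class effects for
  flux and occupancy; resolving which dominates in any real data set
  requires measurements outside this package's scope.
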