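---
title: "Scoring the promoter G-quadruplex landscape: methods and design notes"
author: "promG4 maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the promoter G-quadruplex landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promG4)
```

# Scope and data model

`promG4` quantifies the G-quadruplex (G4) burden of gene regulatory
regions and fits the biophysical models used to characterise individual
promoter G4s in solution. The genomic half of the package works on a
fixed window per transcript, the transcription-regulatory region (TRR):
2000 nt upstream through 1000 nt downstream of the TSS, always
re-oriented so the stored string reads 5′→3′ on the coding (sense)
strand, with the TSS base at 0-based index 2000. Three sub-regions tile
the window exactly: distal promoter (offsets −2000..−501), proximal
promoter (−500..−1) and downstream (0..+999), with lengths 1500 / 500 /
1000 nt. This tiling is the only reading under which the three region
lengths partition the 3000-nt window, and it is used both for region
counting and for the length-normalised region breakdown.

Two deliberate boundary rules follow from the fixed window length `T`:

* A TRR that would overhang its contig is **excluded, never truncated**.
  Truncation would silently change the denominator of the abundance
  score; exclusions are instead counted and reported
  (`trrExcluded()`).
* Minus-strand genes are reverse-complemented at extraction, so
  "coding strand" always means the sense strand. Strand-resolved results
  (coding vs template G4s) are meaningless without this normalisation.

# The PQS grammar and the matching policy

Putative quadruplex sequences are matched by the canonical grammar
`G≥3(N1–7G≥3)≥3`: at least four tracts of three or more consecutive
guanines, with loops of one to seven arbitrary nucleotides between
consecutive tracts. Three conventions make the match set well defined
where the grammar alone is ambiguous:

* **Tracts are maximal G-runs, consumed whole.** A run of, say, fifteen
  G's is one tract; it is never split to manufacture four tracts out of
  a single run. Ambiguity base N may appear in loops but never inside a
  tract.
* **Greedy leftmost matching with maximal tract extension.** A match
  starts at the leftmost usable run, chains through as many qualifying
  tracts as the loop bounds allow before closing, and scanning resumes
  after its end. Matches are therefore non-overlapping, and the motif
  count *n* per window is unambiguous. This is the convention of the
  widely used PQS scanners; at very dense loci other conventions could
  count differently.
* **Zero-length loops are rejected** (they would merge two runs into one
  anyway under the maximal-run rule).

Both strands are scanned: the template ("C4") calls come from scanning
the reverse complement and mirroring coordinates back onto the
coding-strand axis (`[s, e)` ↦ `[3000−e, 3000−s)`). The test suite pins
this policy to an independent brute-force oracle that enumerates every
run-delimited substring and applies the grammar directly; the two agree
exactly on 1000 random 200-nt sequences of 40–60% G content per run of
the suite.

# Scores

With coverage indicator $\alpha_{j,k}$ (1 when position $k$ of TRR $j$
lies under at least one motif on the strand considered — a nucleotide in
two motifs counts once):

* **F score** (abundance): $F = 100 \sum_k \alpha_{j,k} / T$, per strand,
  with $F_o = F_{cd} + F_{ncd}$; $F = 0$ exactly when the strand has no
  motif.
* **Positional profile**: $W_k = \frac{1}{m}\sum_j \alpha_{j,k}$,
  computed per strand from whichever transcript collection is supplied.
  The default is the full redundant transcript set, reused unchanged
  across transcript-pick iterations, so percentile ranks across
  iterations share one profile.
* **Q score** (location significance):
  $Q = \sum_k \alpha_{j,k} W_k$, with $Q_o = Q_{cd} + Q_{ncd}$. Only the
  functional form above uses exactly the quantities introduced with the
  profile, is additive across strands, and its rank order — the only
  thing the downstream percentile uses — is insensitive to monotone
  rescaling.
* **CF / CQ**: cumulative-frequency percentiles of F and Q. Transcripts
  with a zero score are excluded from the reference distribution and
  carry no percentile (`NA`); nonzero scores map to
  $100\cdot\#\{s' \le s\}/\#\{s' \ne 0\}$. The inclusive-rank convention
  is a choice — the maximum always maps to 100, ties share a value — and
  any monotone convention preserves the >50% classification boundary up
  to ties.
* **Classification**: both percentiles above 50 → *G4-important*; both
  below → *G4-less-important*; mixed, exactly 50, or undefined →
  *intermediate*.

Transcript redundancy is handled the way the scores were designed to be
used: `pickTranscripts()` draws one transcript per gene uniformly at
random, several iterations (default 10) are scored, and downstream
statistics are reported as mean ± sample SD across iterations with a
one-way ANOVA p-value checking that the picks did not drive the result.

For the region breakdown, a motif is assigned to the region containing
its **start** position; a motif spanning a boundary counts once. Counts
are divided by region length and rescaled to percentages summing to 100,
so uniform density reads 33.3% everywhere.

# Tissue and pathway aggregation

"Genes active in a tissue" is an input gene list (GMT); the package
deliberately implements no expression thresholding, since activity
calling is upstream of its scope. Tissue enrichment is the percentage of
active genes with at least one PQS overlapping the requested region,
averaged over pick iterations.

Pathways with **more than 50** member genes present in the annotation
(strictly greater; configurable) are summarised per iteration by the
percentage of analyzable member genes that are G4-important, where
"analyzable" excludes genes with both $F_o$ and $Q_o$ zero. Member
CF$_o$ and CQ$_o$ distributions are compared to the same iteration's
genome-wide background by a two-sided Wilcoxon rank-sum test; the
reported $P_{max}$ is the worst (largest) p-value over iterations, a
conservative summary. Sidedness is a design choice (the direction is
visible from the medians); the iteration ANOVA groups are the per-gene
scores per iteration. No multiple-testing correction is applied across
pathways by default, matching how such tables are conventionally
reported; `stats::p.adjust` can be applied downstream.

# Biophysical models

**Two-state melting.** CD melting curves are fit to
$\theta(T) = \frac{(b_{f0}+b_{f1}T) + (b_{u0}+b_{u1}T)K(T)}{1+K(T)}$
with $K(T)=\exp[(\Delta H/R)(1/T_m - 1/T)]$ — a folded/unfolded
equilibrium with linear baselines. The model pins $\Delta G(T_m)=0$, so
$\Delta S = \Delta H/T_m$ is derived, not fit, and
$\Delta G(T) = \Delta H - T\Delta S$ is reported from the unrounded fit
parameters (reporting it from rounded table values of ΔH and ΔS can
differ by a few percent). Temperatures are accepted in °C (instrument
convention) and converted internally to K. The fit is multi-start over a
deterministic ΔH grid with $T_m$ bounded inside the data range; a
transition at the edge of the range raises a warning.

**Unfolding kinetics.** FRET traces are fit to
$A_1 e^{-k_1 t} + A_2 e^{-k_2 t} + C$ (multi-start over log-spaced rate
pairs, rates bounded in $[10^{-8}, 10^{2}]\,s^{-1}$), with $k_1 \ge k_2$
enforced by relabelling. A single-exponential is reported instead when
corrected AIC prefers it or when the two rates fall within a 3× ratio —
below that separation the two components are not identifiable in
practice. In the trap assay (excess complementary C-rich strand), the
fast phase reflects hybridisation of unfolded/partially folded
molecules and the slow phase G4 opening; `pseudoFirstOrder()` divides an
observed rate by the trap concentration to give the second-order
constant. `fitArrhenius()` regresses $\ln k$ on $1/T$
($E_a = -\mathrm{slope}\cdot R$); `eyringParams()` regresses $\ln(k/T)$
on $1/T$ for $\Delta H^\ddagger$ and $\Delta S^\ddagger$, or applies the
shortcut $\Delta H^\ddagger = E_a - RT_{ref}$ with
$T_{ref} = 298.15\,K$ by default. The two routes agree to within 2% when
$T_{ref}$ is near the mean experimental temperature.

**FID and dose-response.** Emission spectra are integrated by the
trapezium rule over 510–750 nm (linear interpolation at the window
edges; exact for piecewise-linear spectra), displacement is
$100 - 100\cdot A_{sample}/A_{standard}$, and DC50/EC50 midpoints come
from a four-parameter logistic on log-concentration with the Hill slope
bounded in [0.2, 5]. The 4PL fit is preferred over raw interpolation
because it uses every point and gives standard errors; when the fitted
midpoint is not bracketed by the sampled concentrations the function
falls back to monotone linear interpolation at the 50% level and flags
the result. Negative displacement (sample brighter than standard) is
reported with a warning rather than clipped.

# The synthetic-data generator

`simulateGenome()` is the package's ground-truth instrument, not a
fixture: it emits a contig, annotation, planted-motif truth table and
per-gene class labels, all reproducible from one seed. Its defaults are
the conditions the package's claims are validated under:

* 200 genes, 1–3 transcripts per gene with TSSs staggered by 40 nt;
* 30% of genes planted *G4-important*: Poisson(6) motifs per TRR placed
  by a Gaussian at offset −50 ± 150 (weight 0.9, the remainder uniform),
  mirroring the empirically observed upstream concentration of promoter
  PQS; background genes receive Poisson(1) uniformly placed motifs;
* motif templates drawn from the scanner grammar itself (four tracts of
  3–5 G's, loops of 1–7 nt from {A,C,T});
* i.i.d. background nucleotides at 42% GC.

Planted motifs get 8-nt A/T flanks — wider than the longest legal loop —
so no background G-run can merge with or chain into a planted motif:
every planted motif is recovered by the scanner at exactly its truth
interval at any background composition, which the suite checks across 20
seeds. Spurious background PQS are permitted and are what make the
synthetic landscape non-trivial.

What the generator does **not** emulate: repeat families and
minisatellite structure, regional GC heterogeneity, CpG islands, or any
coupling between G4 density and expression. Passing tests therefore
demonstrate correctness of the scoring machinery and statistical
calibration under a known model — not that real promoters behave like
the simulator.

Curve simulators (`simulateMeltingCurve`, `simulateKineticTrace`,
`simulateRates`, `simulateEmissionSpectrum`, `simulateDoseResponse`) are
the forward models of the fitting functions with Gaussian (or lognormal,
for rates) noise and a recorded truth attribute. Their default truth
parameters — $T_m = 71.4$ °C, ΔH = 170 kJ mol⁻¹, rates $10^{-2}$ and
$3\times10^{-4}$ s⁻¹, $E_a = 22.1$ kJ mol⁻¹, DC50 = 0.31 µM — are the
magnitudes typical of stable promoter G4s, so parameter-recovery tests
run in the physically relevant regime.

# Numerical choices and degenerate inputs

* Nonlinear fits use `minpack.lm::nlsLM` with deterministic multi-starts
  (8 by default); failure of every start is an error, not a silent NA.
* `cumulativeFrequency` errors on all-zero input (the reference
  distribution would be empty), as do `pearsonR` on constant vectors,
  `regionBreakdown` on an empty class, and the pathway percentage when
  every member gene has both scores zero.
* Identical ANOVA groups return p = 1 (F = 0) rather than NaN.
* `fitMidpoint` rejects responses that are non-monotone beyond a noise
  tolerance (20% of the response range) — a non-monotone "dose-response"
  is a data problem the fit should not paper over.
* Ties in CF/CQ share a percentile (inclusive rank); the argmax of a
  finite-sample $W_k$ profile jitters by a few tens of nt around the
  planted peak, which is why positional claims are stated as intervals
  (peak within −200..0) rather than a point.

# Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to make the statistical checks sharp but quick:
genomes of 25–150 genes (TRRs are 3 kb, so a 150-gene genome is ≈ 0.8 Mb
of sequence), 1000 oracle sequences of 200 nt, 100 Monte-Carlo
replicates for melting/kinetic/Arrhenius bias, 50 for DC50, and 20
replicate genomes for class-recovery rates. A full-genome run
(~50,000 transcripts) uses the same code path; only the inputs grow.

# Known limitations

* The scanner targets the three-tetrad grammar; two-tetrad (G≥2) G4s,
  RNA G4s and i-motif annotation are out of scope (a template-strand G4
  call already captures the C-rich readout of the sense strand).
* Thermodynamic plausibility scoring of PQS (G4Hunter-style) is not
  implemented; every grammar match counts equally.
* The melting model assumes a single two-state transition; multiphasic
  melts (mixtures of intra- and intermolecular species) must be
  decomposed upstream or fit piecewise.
* Pathway statistics inherit whatever gene-identifier universe the
  annotation uses; no identifier mapping is attempted.
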