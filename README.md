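# promG4

Promoter G-quadruplex (G4) landscape scoring and biophysics for R.

G-rich DNA can fold into four-stranded G-quadruplexes, and putative
quadruplex sequences (PQS) cluster in gene promoters, where they can act
as *cis*-regulatory elements. `promG4` is for genomicists and nucleic-acid
biophysicists who want to (i) quantify how G4-laden the regulatory region
of every transcript in a genome is, (ii) rank genes, tissues and pathways
by that burden, and (iii) fit the solution-biophysics curves (CD melting,
FRET unfolding kinetics, fluorescent-intercalator displacement, reporter
dose-response) used to characterise individual promoter G4s.

## The model

For every transcript, the **transcription-regulatory region** (TRR) is
the window −2000..+1000 nt around the TSS, read 5′→3′ on the coding
strand (minus-strand genes are reoriented at extraction). PQS are matched
by the canonical grammar

```
G≥3 (N1–7 G≥3)≥3
```

i.e. at least four maximal G-tracts of ≥3 guanines separated by loops of
1–7 nt, matched greedily leftmost with maximal tract extension, so motif
calls are non-overlapping. Per strand *s* ∈ {cd, ncd} and transcript *j*
with coverage indicator α<sub>j,k</sub> (position *k* under ≥1 motif):

* **Abundance** F<sub>s</sub> = 100 · Σ<sub>k</sub> α<sub>j,k</sub> / T with
  T = 3000, and F<sub>o</sub> = F<sub>cd</sub> + F<sub>ncd</sub>;
* **Positional profile** W<sub>k</sub> = (1/m) Σ<sub>j</sub> α<sub>j,k</sub>,
  the genome-wide probability that position *k* relative to the TSS is
  covered (empirically peaked a few tens of nt upstream of the TSS);
* **Location significance** Q<sub>s</sub> = Σ<sub>k</sub> α<sub>j,k</sub> W<sub>k</sub>,
  and Q<sub>o</sub> = Q<sub>cd</sub> + Q<sub>ncd</sub>;
* **CF / CQ**: cumulative-frequency percentiles of F and Q over the
  transcript universe (zero scores excluded); a gene with CF<sub>o</sub> > 50
  and CQ<sub>o</sub> > 50 is **G4-important**, with both < 50
  **G4-less-important**.

Pathways (GMT gene sets with > 50 members) are called G4-important when
more than half of their analyzable genes are; member score distributions
are compared against the genome background by two-sided Wilcoxon rank-sum
tests (worst-iteration P<sub>max</sub> reported), with one-way ANOVA
checking that random one-transcript-per-gene picks do not drive the
result. Biophysics: two-state van't Hoff melting with linear baselines
(ΔS = ΔH/T<sub>m</sub>, ΔG(T) = ΔH − TΔS), double-exponential unfolding
kinetics with AICc model selection and pseudo-first-order normalisation,
Arrhenius (E<sub>a</sub> = −slope·R) and Eyring (ΔH‡, ΔS‡) analysis, and
four-parameter-logistic DC50/EC50 fits.

## Worked example

```r
library(promG4)

sim  <- simulateGenome(nGenes = 100, maxTranscripts = 2, seed = 42)
trr  <- extractTRR(sim$genome, sim$transcripts)
scan <- scanTRR(trr)
scan
#> PQSScan: 362 motif(s) over 151 TRR(s) (coding 242, template 120)

sc <- scoreTranscripts(scan)
head(sc[, c("transcript_id","F_cd","F_ncd","F_o","Q_o","CF_o","CQ_o","class")], 5)
#>   transcript_id F_cd F_ncd  F_o    Q_o CF_o  CQ_o        class
#> 1      G0001.T1 0.00  0.00 0.00  0.000   NA    NA intermediate
#> 2      G0002.T1 2.07  0.00 2.07  0.596 52.4  32.4 intermediate
#> 3      G0003.T1 6.67  1.47 8.13 12.623 96.2 100.0    important
#> 4      G0003.T2 6.67  1.47 8.13 10.874 96.2  98.1    important
#> 5      G0004.T1 0.00  0.00 0.00  0.000   NA    NA intermediate

cls <- merge(sc, sim$geneClasses, by = "gene_id")
mean(cls$important[cls$class.y == "important"])   # planted-class recovery
#> 0.977
```

`G0003` was planted as a G4-important gene: 8.13% of its TRR nucleotides
sit under PQS (F<sub>o</sub>), its motifs fall where the genome-wide
profile W<sub>k</sub> concentrates (Q<sub>o</sub> = 12.6), and both
percentiles exceed 50, so it is classified `important`; 97.7% of planted
genes are recovered that way. The same session fits a melting curve
simulated at the parameters typical of a stable promoter G4:

```r
cv <- simulateMeltingCurve(tm = 71.4, dH = 170, noise = 0.01, seed = 1)
fitMeltingTwoState(cv$temperature_C, cv$signal)
#> Two-state melting fit: Tm = 72.48 C, dH = 166.3 kJ/mol, dS = 481.0 J/mol/K
#>   dG(310 K) = 17.14 kJ/mol
```

i.e. a T<sub>m</sub> near 71–72 °C and ~17 kJ mol⁻¹ of unfolding free
energy at body temperature.

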