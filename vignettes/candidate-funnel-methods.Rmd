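---
title: "Methods: the ice-nucleation candidate-gene funnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ice-nucleation candidate-gene funnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linafunnel)
```

## The problem

Some bacteria catalyze the freezing of supercooled water at temperatures far
above the homogeneous nucleation point. For *Lysinibacillus parviboronicapiens*
(*Lp*) this activity travels with a secreted, non-proteinaceous particle, so
the classical *ina*-gene paradigm does not apply and the responsible genes
have to be found by elimination. `linafunnel` implements that elimination
chain as a reusable, tested pipeline:

1. quantify ice nucleation activity (INA) per strain from droplet-freezing
   dilution assays;
2. keep the genes present in all INA-positive (target) genomes and absent
   from all INA-negative ones;
3. of those, keep the genes expressed under the assay growth conditions;
4. of those, keep the biosynthetic core genes (PKS/NRPS signature domains);
5. confirm candidates by independent mutation recurrence in a UV screen.

Every input can also be simulated by the package's seeded generator, so the
full funnel runs and is validated end to end without any external data.

## Freezing spectra

A droplet-freezing assay cools `N0` droplets per dilution along a ramp (the
default grid is −2 °C to −12 °C in 1 °C steps, matching the standard
protocol of six tenfold dilutions from 10⁸ CFU/ml, thirty 20-µl droplets,
three replicates). With `N(Θ)` droplets still unfrozen at temperature `Θ`
and `A` CFU per droplet, the cumulative ice-nucleating-particle (INP)
concentration per CFU is the classical cumulative estimator

    K(Θ) = [ln N0 − ln N(Θ)] / A .

Numerical choices, in decreasing order of consequence:

* **Censoring.** When every droplet froze, `ln N(Θ)` is undefined. We
  substitute `N(Θ) = 0.5` and flag the value `censored = TRUE`: the point is
  a lower bound, kept so spectra remain plottable, never silently dropped.
* **Combining dilutions.** `K` is defined per dilution; combining the six
  dilutions into one spectrum is under-determined by the protocol. The
  default pools replicates of each dilution by count summation (droplets are
  exchangeable), keeps the *informative* dilutions (some but not all pooled
  droplets frozen), and averages their `K` weighted by pooled droplet
  number. `combine = "most_dilute"` instead keeps the single most dilute
  informative dilution, which stitches rather than averages; both modes are
  exposed because either reading is defensible.
* **Monotonicity.** Per dilution, `K` is monotone because frozen counts are
  cumulative (a frozen droplet stays frozen). The weighted average can still
  dip when the informative set changes between adjacent temperatures, so the
  finished spectrum is passed through a running maximum. The correction is
  within sampling noise; the invariant it restores is physical.
* **Detection.** The decision rule behind a `+`/`−` INA call is not part of
  the estimator; we use a one-sided exact test (Fisher) of the pooled
  frozen/unfrozen table against a water control at `alpha = 0.05`
  (configurable). The same rule scores density-gradient fractions against a
  blank in `fraction_profile()`.

## The genomic funnel

**Clade uniqueness.** From a Roary-style presence/absence matrix
(genes × genomes, cells carrying locus tags), `unique_to_clade()` keeps the
clusters present in *every* target genome and absent from *every* other
genome. "Present in only one target" is a weaker reading of clade
uniqueness; it is available as `mode = "any"` but is not the default, since
a gene missing from one INA-positive strain cannot be required for INA.
Results are reported as locus tags of the reference target genome, which is
the namespace the expression table and gene models share.

**Expression.** TPM normalization (`tpm_i = 10⁶·(c_i/l_i)/Σ(c_j/l_j)`) with
annotated CDS length as the effective length — fragment-length correction
would require the read data, which is out of scope. "Expressed" defaults to
`TPM > 0`, i.e. any mapped read; the threshold is a parameter because zero
is a convention, not an estimate.

**Biosynthetic core genes.** A full cluster scan (antiSMASH-style HMMs) is
deliberately out of scope; `call_bgc_core()` applies a transparent
signature-domain rule instead. A gene is core when it carries a ketosynthase
(KS) domain, a complete condensation + adenylation (C + A) didomain, a
thioesterase (TE) immediately adjacent to a core gene, or an accessory
domain (4′-phosphopantetheinyl transferase; NAD-dependent
epimerase/dehydratase) within the merge window (default 10 kb) of a core
gene. Core genes with pairwise gaps ≤ the window merge into regions. The
signature table is an argument, so the rule can be tightened or extended
without touching the pipeline.

## The UV screen

`annotate_effect()` classifies each variant against the gene models:
strand-aware codon lookup with the bacterial genetic code for SNPs
(synonymous / nonsynonymous / nonsense), length mod 3 for indels
(frameshift / in-frame), intergenic otherwise. The start codon is treated
like any other codon: a mutation that turns ATG into an alternative
initiator is still a coding change. Coordinates are 1-based inclusive;
insertions are anchored at the base before the event (VCF convention).

`filter_artifacts()` removes a variant only when the *identical* substitution
recurs in ≥ 2 strains *and* lies in an insertion-sequence or
short-hypothetical gene ("short" defaults to CDS < 300 nt with a
"hypothetical" product — the length threshold is a judgment call and is
configurable). Recurrence alone never removes a variant under the default
AND semantics; an OR mode exists for sensitivity analysis. The removal log
is attached to the result, because silently dropped variants are the classic
failure mode of such filters.

`recurrently_hit_genes()` counts, per gene, the *distinct* complete-loss
strains carrying ≥ 1 candidate-effect variant (nonsynonymous, nonsense,
frameshift, in-frame indel — synonymous and intergenic changes do not
count), and ranks genes by that count, ties broken by gene id. Mutants with
reduced (not abolished) activity are excluded by default and can be included
with a flag.

## The synthetic-data generator

The generator exists so the funnel's logic can be validated against planted
truth. Its defaults are the study conditions: 19 genomes with 2 targets;
six tenfold dilutions from 10⁸ CFU/ml, 30 droplets, 3 replicates; mean UV
mutation load λ = 4; 7 complete-loss mutants split 5/2 across the planted
T1-PKS and NRPS genes plus 2 reduced mutants. Models, and what they do and
do not emulate:

* **Freezing.** Each droplet at dilution `d` holds `A(d)` CFU; the number of
  INPs active at or above `Θ` is Poisson(`K(Θ)·A`), the minimal stochastic
  nucleation model consistent with the cumulative estimator. One exponential
  deviate per droplet, thresholded against the cumulative `K(Θ)·A` curve,
  couples the draws across temperatures and makes frozen counts cumulative
  by construction. The true spectrum is log-linear below an onset
  temperature (defaults: onset −4 °C, slope 0.7 log₁₀ units per °C,
  `K` = 10⁻⁷ per CFU at onset — magnitudes typical of highly active
  bacterial ice nucleators). Not emulated: temperature-ramp kinetics,
  droplet-volume variation, CFU counting error in `A`.
* **Pan-genome.** Planted clade-unique clusters among four distractor
  classes: core (all genomes), shell (random subsets, never a subset of the
  targets), target-partial (one target only), near-unique (targets plus
  exactly one outgroup genome). The distractor counts (1200/600/25/25 in the
  replay fixture) are desk-scale stand-ins — a real 19-genome matrix is an
  order of magnitude larger — chosen to exercise every occupancy pattern the
  filter must reject. Not emulated: annotation noise, paralog splitting,
  fragmented assemblies.
* **Expression.** Negative-binomial counts (defaults mean 200, size 5 —
  moderately expressed bacterial genes with typical overdispersion; at these
  values the NB mass at zero is ~10⁻⁸, so sampled zeros effectively never
  contaminate the planted-zero count). The configured number of
  zero-expression genes is forced by setting counts to zero, drawn from the
  clade-unique set minus the biosynthetic core genes, which the study found
  expressed. Lengths are uniform 300–6000 nt.
* **Genome.** One contig; clean ORFs (ATG ... non-stop codons ... TAA) laid
  out with 80–220 nt intergenic gaps; the five-gene template (PPTASE,
  EPIM_DH, an intergenic gap, T1-PKS with KS-AT-DH-KR-ACP, NRPS with two
  C-A-PCP modules, TE) flanked by hypothetical genes, with insertion-sequence
  elements and housekeeping genes elsewhere. The replay fixture plants one
  additional five-core-gene cluster behind a 12 kb spacer so the genome
  carries ten core genes in total, matching the published count, which was
  taken over all clusters in the genome, not only the focal one. Not
  emulated: codon usage, GC skew, multi-contig assemblies (the readers
  accept them; the generator does not produce them).
* **Mutants.** Background load per strain is Poisson(λ); the distribution is
  an assumption (the study reports only the mean) and is flagged as such in
  the bundle manifest. Background variants are missense SNPs and 1-nt
  indels at random CDS positions, never in the causal genes and never in IS
  elements (causal hits and artifacts are planted separately). Within the
  complete-loss strains, background genes are drawn from disjoint per-strain
  pools: at desk scale (~80 genes instead of ~4500) unconstrained placement
  would produce chance two-strain recurrences that a real genome's gene
  count dilutes away, and the replay is meant to reproduce the published
  outcome in which only the two causal genes recur. The flag
  `background_disjoint = FALSE` removes the constraint. Artifacts are
  identical substitutions planted in IS genes across ≥ 2 strains.

All randomness flows from the single config seed through per-component
offsets, so each component is reproducible in isolation and the whole bundle
is byte-identical across runs (verified by checksum in the tests).

## What the tests do and do not show

The suite validates the *logic* under the generator's assumptions: exact
planted-truth recovery for every filter, estimator recovery within binomial
sampling error (3×300-droplet assays), annotation agreement with a
full-CDS-translation oracle, invariants (monotone spectra, TPM conservation
to 10⁶ ± 10⁻⁶ relative, funnel nesting, artifact filter never touching
strain-unique variants) on randomized inputs, and the replay fixture's stage
counts. Passing says nothing about ortholog-clustering quality, read
alignment, or variant calling — those live upstream of this package's
inputs. Problem sizes (a ~4800-cluster matrix, ~80-gene genome, 1000-strain
calibration runs) are the package's chosen desk-scale study conditions.

## Worked example

```{r example, eval = FALSE}
cfg <- in_paper_config(seed = 1)
bundle <- gen_funnel_fixture(cfg)

ann  <- annotate_effect(bundle$variants, bundle$genes, bundle$genome)
kept <- filter_artifacts(ann, bundle$genes)
hits <- recurrently_hit_genes(kept, bundle$phenotypes, min_strains = 2)

report <- run_funnel(bundle$pa, cfg$target_ids, bundle$expression,
                     bundle$genes, screen_hits = hits$gene_id)
print(report)
#> Candidate-gene funnel
#>   unique                     2993 genes
#>   unique_expressed           2986 genes
#>   unique_expressed_core        10 genes
#>   screen_supported              2 genes
```

## Known limitations

* The BGC rule is a deliberately simple stand-in: it will miss clusters
  whose annotations lack the signature domains and cannot subdivide hybrid
  clusters.
* Effect annotation handles one variant at a time; compound effects of
  multiple variants in one codon are not modeled.
* The detection test conditions on the pooled table; it does not model
  between-replicate overdispersion.
* `K(Θ)` carries no confidence interval — the exact test against the control
  is the only inferential statement the package makes about spectra.
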