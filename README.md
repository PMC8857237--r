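# linafunnel

Forward-genetics tooling for finding the genes behind bacterial ice
nucleation activity (INA). Some bacteria nucleate the freezing of
supercooled water at temperatures as warm as a few degrees below zero; in
*Lysinibacillus parviboronicapiens* the activity travels with a secreted,
non-proteinaceous particle, so the responsible genes cannot be found by
homology to the classical *ina* genes. `linafunnel` implements the
elimination chain that narrows a pan-genome to a candidate biosynthetic gene
cluster, for microbiologists running comparative-genomics screens and for
anyone who needs a tested, reproducible implementation of the underlying
estimators.

## What it computes

**Freezing spectra.** From droplet-freezing dilution assays (N₀ droplets per
dilution cooled along a ramp, N(Θ) unfrozen at temperature Θ, A CFU per
droplet), the cumulative ice-nucleating-particle concentration per CFU:

    K(Θ) = [ln N₀ − ln N(Θ)] / A

with flagged lower bounds when all droplets froze, replicate pooling,
droplet-number-weighted combination across dilutions, and a one-sided exact
test against a water control for ±INA calls (`spectrum_from_assay()`,
`ina_detectable()`, `fraction_profile()`).

**The candidate funnel.** Genes present in every target genome and absent
from every other genome of a Roary-style presence/absence matrix
(`unique_to_clade()`); of those, the genes expressed at TPM > 0
(`tpm()`, `expressed_genes()`); of those, the biosynthetic core genes by a
transparent signature-domain rule — ketosynthase, condensation + adenylation
didomain, thioesterase adjacent to a core gene, accessory transferases
within a 10 kb window (`call_bgc_core()`); composed by `run_funnel()`.

**The UV mutant screen.** Strand-aware coding-effect annotation of
per-strain variants against the genome and gene models
(`annotate_effect()`), removal of identical substitutions recurring across
strains inside insertion sequences or short hypothetical genes
(`filter_artifacts()`), and ranking of genes by the number of distinct
complete-loss mutants carrying candidate-effect variants
(`recurrently_hit_genes()`).

**Synthetic data.** A seeded generator (`gen_funnel_fixture()` and friends)
produces every input — pan-genome matrix, negative-binomial expression
table, an annotated genome with a planted PKS-NRPS cluster, UV-mutant VCFs
with Poisson mutation load and planted artifacts, stochastic droplet
assays — with the planted truth recorded, so the whole pipeline runs and is
validated without any download.

## Worked example

The shipped replay configuration encodes the published funnel's stage
structure as generator parameters; one seed reproduces the whole analysis:

```r
library(linafunnel)

cfg    <- in_paper_config(seed = 1)
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

hits[, c("gene_id", "n_strains")]
#>        gene_id n_strains
#> 1 VT1065_00150         5
#> 2 VT1065_00155         2
```

Reading the numbers: 2993 gene clusters are present in both INA-positive
genomes and absent from the 17 INA-negative ones; 7 of them have zero mapped
reads, leaving 2986; 10 of those carry biosynthetic signature domains; and
the mutant screen's recurrence ranking lands on exactly two adjacent
genes — the planted T1-PKS (hit in 5 complete-loss mutants) and NRPS (hit in
2) — which are the funnel's final candidates.

The assay side of the same bundle:

```r
spectrum_from_assay(bundle$assays$wild_type)
#> Freezing spectrum for wild_type -- 11 temperatures, 0 censored
#>       strain temperature_c    k_per_cfu censored n_series_used
#> 1  wild_type            -2 0.000000e+00    FALSE             0
#> 2  wild_type            -3 0.000000e+00    FALSE             0
#> 3  wild_type            -4 7.155042e-08    FALSE             1
#> ...
#> 11 wild_type           -12 4.311118e-02    FALSE             1

ina_detectable(bundle$assays$wild_type, bundle$control)
#> [1] TRUE
```

The estimated K(Θ) rises from ~10⁻⁷ INPs per CFU at the −4 °C onset to
~4×10⁻² at −12 °C, tracking the generating spectrum; the wild type is
detectable against the water control while complete-loss mutants are not.

File-based workflows use the same functions behind `run_all()`, which takes
a YAML/list config of input paths (presence/absence CSV, expression TSV,
GFF3, FASTA, VCFs, phenotype TSV, assay CSV) and returns one report;
`write_bundle()` materialises a generated bundle in those formats.

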