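# biofilmarch

Quantitative characterization of phototrophic biofilm architecture on stone
substrata, from confocal Z-stacks and substrate photographs to a per-strain
**colonization index**.

Pioneer cyanobacteria and microalgae colonize calcareous stone in two
recognizable styles: **compact** mats (dense, few empty spaces) and
**porous** networks (reticulate filaments, many voids). The style is largely
intrinsic to the strain and shapes how the biofilm weathers the stone. This
package implements the full measurement chain that turns image stacks into
that characterization, for researchers in stone biodeterioration,
conservation science and biofilm ecology.

## The method

Each strain is imaged as Z-stacks at three sampling points. After slice-count
harmonization, 8-bit conversion and thresholding (Otsu over the 256-bin
histogram, foreground = intensity ≥ threshold), every slice *j* of strain *i*
yields three dimensionless quantities in [0, 1]:

- substratum coverage 𝒜ᵢⱼ = Aᵢⱼ / aᵢ (microbial area over slice area),
- linear-measure ratio ℒᵢⱼ = (Aᵢⱼ/Pᵢⱼ) / (√aᵢ/4) (pattern's area/perimeter
  over the characteristic linear measure of the slice; ≈1 for compact mats,
  ≈0 for filament networks),
- normalized fractal dimension 𝒟ᵢⱼ = D_B(Fᵢⱼ) / 2 (box-counting dimension
  from the slope of ln N_δ vs −ln δ, with R² reported).

Per-slice series are aggregated along depth with three operators — maximum,
arithmetic mean, and a Gaussian-weighted mean whose weights peak at ordinal
position λ(1+N) (default λ = 0.5, the middle of the biofilm) — then rescaled
across strains so each quantity/operator column maps its best strain to 1.
The colonization index I_C of a strain under a fixed operator is the mean of
its three rescaled quantities, and classifies the strain as

| I_C | label |
|---|---|
| < 0.5 | porous colonizer |
| 0.5 – 0.7 | intermediate |
| ≥ 0.7 | compact colonizer |

A seeded synthetic-data module generates image stacks (compact and porous
regimes with Gaussian depth-coverage profiles), pale-gray tessera
photographs with blue-green colonized patches, and correlated roughness
profiles — all with ground truth, so every stage is testable without real
micrographs. Supporting statistics cover pairwise Mann–Whitney U matrices,
Pearson correlation between substrate- and projection-scale coverage,
five-number summaries and ISO 4287-style roughness parameters (Ra, Rq, Rz,
Rt).

## Worked example

Run the full pipeline on a four-strain synthetic suite and classify the
published index table:

```r
library(biofilmarch)

cfg <- pipeline_config(n_strains = 4,
                       labels = c("compact", "compact", "porous", "porous"),
                       seed = 11)
report <- run_pipeline(cfg)
print(report)
#> Colonization report: 4 strain(s)
#>     strain    ic_max ic_average ic_weighted   label
#>  strain_01 0.9773325  0.9865704   0.9821137 compact
#>  strain_02 1.0000000  1.0000000   1.0000000 compact
#>  strain_03 0.3781954  0.4357911   0.4144438  porous
#>  strain_04 0.4227083  0.4689260   0.4458195  porous
#> Tessera vs MIP coverage: Pearson r = 0.999

res <- classify_from_fixture("table5")
print(res$labels[, c("strain", "label", "unanimous")], row.names = FALSE)
#>                  strain        label unanimous
#>   Calothrix membranacea       porous      TRUE
#>  Coelastrella rubescens intermediate      TRUE
#>     Fischerella ambigua       porous      TRUE
#>          Nostoc commune      compact      TRUE
#>          Plectonema sp.      compact      TRUE
```

The report's `ic_*` columns are the colonization indices per aggregation
operator; both compact strains sit at the top of the 0.7–1 band, both porous
strains below 0.5, and the label column recovers the generator's ground
truth. The Pearson r near 1 reflects that a strain's substrate-scale
coverage mirrors its projection-scale (MIP) coverage. The fixture
classification reproduces the published porous / intermediate / compact
grouping of the five selected strains.

A thin command-line wrapper for the same operations ships at
`inst/scripts/biofilmarch-cli.R` (subcommands `synth`, `run`, `fixtures`,
`stats`).

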