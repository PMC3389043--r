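# planktondiv

Microplankton community diversity across a *Phaeocystis*-type spring
bloom, from tagged 18S rDNA pyrosequencing reads and microscopy counts.

Coastal bloom surveys typically combine two views of the same water:
high-throughput sequencing of the hypervariable V2–V3 region of the 18S
rRNA gene (tagged 454-style amplicons), and inverted-microscope counts
with cell measurements. `planktondiv` implements the full computational
chain between raw inputs and the survey's headline numbers, for
ecologists and bioinformaticians who want each step reusable, seeded and
tested:

* **Read pre-processing** — demultiplexing by 10-nt sample tag + `TCAG`
  key + forward primer, primer stripping, and length QC (fractions of
  reads above 200/400 bp).
* **Taxonomic binning** — BLAST-tabular hits (built-in seed-and-extend
  aligner included) filtered at E ≤ 10⁻⁵, min-score 5 and top-percent 1,
  lowest-common-ancestor assignment over a ranked lineage table,
  min-support pruning, and group proportion tables.
* **OTU diversity** — greedy centroid clustering at 97% identity, taxon
  validation at ≥ 3 reads, rarefaction (analytic hypergeometric and
  Monte Carlo), and the four indices
  - Chao1: `S_chao1 = S + n₁²/(2 n₂)`
  - Shannon: `H' = −Σ pᵢ ln pᵢ`
  - Margalef: `d = (S−1)/ln N`
  - Simpson: `Δ = 1 − Σ pᵢ²`
* **Between-date change** — the normalized relative change
  `R = (n_iB/N_B)/(n_iA/N_A)`, which compares a taxon's read share
  across samples of unequal depth.
* **Phylogenetics of the focal group** — progressive alignment of OTU
  representatives, Kimura two-parameter distances
  `d = −½ ln(1−2P−Q) − ¼ ln(1−2Q)`, neighbor-joining, 1000 seeded
  bootstrap replicates, Newick output.
* **Carbon biomass** — geometric biovolumes and group-specific carbon
  allometries (190 fg C µm⁻³ for ciliates, `0.760·V^0.819` pg C for
  dinoflagellates, size-dependent `a·V^b` power laws for phytoplankton),
  stock series in µg C L⁻¹ and survey fold changes.
* **Synthetic data** — a seeded generator for reference databases,
  bloom-structured communities, error-laden tagged reads (with 454-like
  length attrition) and microscopy tables, so the whole pipeline runs
  and is tested without any download.

## Worked example

The normalized relative change, applied to a bloom group counted at 660
reads out of 18,280 on the first date and 5,435 out of 41,057 on the
second:

```r
library(planktondiv)
r <- relative_change(660, 5435, 18280, 41057)
round(as.numeric(r), 2)
#> [1] 3.67        # i.e. a 3.7-fold enrichment
```

Diversity indices on a small abundance vector:

```r
chao1(c(1, 1, 2, 3))          # S=4, n1=2, n2=2 -> 5
#> [1] 5
shannon_index(rep(3, 4))      # uniform over 4 OTUs
#> [1] 1.386294
```

Fold changes from a two-date stock table:

```r
stocks <- data.frame(group = "phytoplankton", date = c("mar", "apr"),
                     stock_ugC_per_L = c(42.6, 1439.1))
fold_change_summary(stocks)
#>           group  min    max    ratio rounded_ratio
#> 1 phytoplankton 42.6 1439.1 33.78169            34
```

And the full simulated survey in one call:

```r
report <- run_pipeline(default_config(seed = 1))
report$diversity
#>   sample reads otus    chao1 margalef   shannon   simpson
#> 1    apr   410   26 46.25000 4.155477 0.7895702 0.2569780
#> 2    mar   180   25 33.90909 4.621644 2.2801924 0.8458642
```

— the bloom date (`apr`) keeps its OTU richness while evenness (Shannon,
Simpson) collapses under the dominant taxon, the signature this kind of
survey looks for. `report$compare` holds the per-OTU `R` values
(`R = 9.33` for the constructed bloom OTU at these settings), and
`report$fold_changes` the biomass fold changes of the simulated
microscopy scenario.

## The analysis workflow

The `analysis/` directory walks the same pipeline step by step as
numbered scripts, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # reference DB, reads, microscopy
Rscript analysis/02_demux_qc.R        # demultiplex + length QC
Rscript analysis/03_assign_taxonomy.R # aligner + LCA + group tables
Rscript analysis/04_otu_diversity.R   # OTUs, indices, rarefaction, R
Rscript analysis/05_phylogeny.R       # NJ/K2P tree with bootstraps
Rscript analysis/06_biomass.R         # stocks and fold changes
```

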