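---
title: "Methods: a bloom-survey amplicon and biomass pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a bloom-survey amplicon and biomass pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`planktondiv` re-implements, as tested and reusable code, the computational
chain of a coastal microplankton bloom survey that pairs tag pyrosequencing
of the 18S rDNA V2--V3 region with inverted-microscopy counts: read
pre-processing, taxonomic binning, OTU-based diversity statistics, distance
phylogenetics of a focal group, and biovolume-based carbon biomass. This
vignette explains the models and procedures stage by stage, the parameters
that matter, what the synthetic-data generator does and does not emulate,
and the numerical and design choices made where the methodology left room.

## The survey design being modelled

The scenario is a two-date contrast: a pre-bloom sample and a sample taken
at the peak of a *Phaeocystis globosa*-type bloom, during which one taxon
comes to dominate the community while many low-abundance relatives persist.
Amplicons carry a per-sample 10-nt tag, the fixed 4-nt instrument key
`TCAG`, and the universal eukaryote forward primer 18S-82F
(`GAAACTGCGAATGGCTC`); the reverse primer is Ek-516r (`ACCAGACTTGCCCTCC`).
The amplified insert spans roughly 470--500 nt of the V2--V3 region.

## Synthetic data generator

Because raw pyrosequencing runs and Silva-scale references are neither
needed nor desirable for testing, every input is generated:

* **Reference database** (`generate_reference_db()`): an ancestral ~500-nt
  sequence is mutated down a family → genus → species tree with
  per-branch substitution rates chosen so expected pairwise divergence is
  ~2% within a genus, ~8% within a family and ~15% between families. The
  ordering is the property that matters: it makes a 97% clustering
  threshold species-like and gives the LCA assignment meaningful rank
  structure. A lineage table (`family:...;genus:...;species:...`) is
  emitted alongside.
* **Communities** (`generate_community()`): geometric rank-abundance
  series, the standard simple model for plankton assemblages; optionally
  one taxon is promoted to a bloom fraction (0.9 by default in the
  pipeline's bloom-date sample, mirroring the >90% dominance the focal
  bloom former reaches). The bloom-date community reuses the pre-bloom
  taxon set so between-date comparisons are meaningful.
* **Reads** (`generate_reads()`): multinomial sampling of taxa, point
  substitutions at an `error_rate` per base (1% default), and a two-part
  length-attrition model: a fraction `p_full = 0.30` of reads keep the
  full insert; the rest are truncated to `min_len = 150` nt plus a
  geometric excess with mean 130 nt. At these defaults ~75% of cleaned
  reads exceed 200 bp and ~40% exceed 400 bp, the attrition observed in
  454 titanium runs of this amplicon. A truth table (read → source
  reference) always accompanies the reads so recovery can be scored.
* **Microscopy tables** (`generate_microscopy_table()`): one row per
  taxon and date with cell abundance and lognormally jittered linear
  dimensions. The jitter is mean-preserving, so zero-SD specs reproduce
  their means exactly. The default two-date scenario is calibrated, at
  the dimension means, to phytoplankton stocks running from ~43 to
  ~1440 µg C L⁻¹ (~34-fold) and microzooplankton stocks from ~6.3 to
  ~26.4 µg C L⁻¹ (~4-fold), the magnitudes of an eastern English Channel
  spring bloom.

What the generator does **not** emulate: chimeras, homopolymer indel
errors (the dominant 454 artifact class; point substitutions suffice to
exercise clustering and binning), quality scores, and reverse-complement
reads (off by default, as the tagged-end protocol reads forward; a flag
enables them). Tests passing on this generator therefore demonstrate
algorithmic correctness and end-to-end consistency, not robustness to
every real-world artifact.

## Read pre-processing

`demultiplex()` assigns a read iff positions 1--10 exactly match a sample
tag, positions 11--14 equal `TCAG`, and the forward primer follows within
a configurable substitution budget (default 1). Tag matching is exact:
10-nt tags with exact matching is the conservative standard, and the
protocol gives no tag-error tolerance. Everything else goes to an
unassigned bin, so the output partitions the input — the invariant behind
the pipeline's read-count ledger. Cleaned reads have tag, key and primer
removed; an exact reverse-primer match near the 3' end is trimmed, and
reads without it are kept, since truncated 454 reads are expected.
`length_stats()` reports threshold exceedance fractions (defaults 200 and
400 bp) and reports an empty read set as undefined rather than zero.

## Taxonomic binning

Reads are compared to the reference database by `align_reads()`, a
seed-and-extend local aligner provided so the stage runs without external
BLAST: exact 11-mer seeds select candidate references (at most 10), which
are then aligned with affine-gap Smith--Waterman (+2/−3, gap open 5,
extend 2) via Biostrings; a bit score and Karlin--Altschul-style E-value
are computed from the raw score, read length and database length, and
hits are emitted in BLAST outfmt-6 layout. `method = "full"` disables the
seed screen and is the exhaustive reference mode. External BLAST tabular
files can be substituted at any point via `read_hit_table()`.

`filter_hits()` applies the three standard MEGAN thresholds with the
conventional values for this amplicon: E-value ≤ 1e-5, bit score ≥ 5,
and top-percent 1 — a hit is retained only if its score reaches 99% of
the best retained score for that read. Top-percent is interpreted as
MEGAN documents it (a band below the best hit passing the other two
filters); ties for the best score are all retained. The min-score of 5
bits is far below typical BLAST practice but is kept as the stage's
default because it is the convention for these short, noisy reads; it is
configurable, and the filter audit records how many hits each step
removed.

`assign_lca()` places each read on the deepest node lying on every
retained hit's lineage (the naive LCA; no weighted or long-read variant).
Reads with no retained hits are binned "No hits"; reads whose retained
hits only reference lineage-less entries are "Not assigned"; disjoint
lineages collapse to the root. `apply_min_support()` re-assigns reads on
nodes with fewer than `min_support` direct reads to the nearest ancestor
whose subtree count reaches the threshold; with the default
`min_support = 1` it is the identity, and read totals are conserved for
any setting. `summarize_groups()` turns the counted tree into
group/percentage tables and refuses overlapping (ancestor/descendant)
grouping nodes, which would double-count.

## OTU clustering and diversity

`pairwise_identity()` is the primitive under the 97% threshold: the
shorter sequence is aligned end-to-end against the best region of the
longer (semi-global, affine gaps, +2/−3/5/2), and identity is matches
over alignment columns. Truncated reads are thus compared over their
overlap instead of being penalized for missing 3' sequence. The dynamic
program is compiled (Rcpp) and is verified in the tests against an
independent Biostrings alignment of the same model.

`cluster_greedy()` is Uclust-style greedy centroid clustering: reads are
processed by decreasing length (ties by id — a deterministic stand-in for
the tool's unspecified ordering); each read joins the first centroid, in
founding order, reaching the identity threshold, else founds a new
centroid. A shared-word screen (11-mers, ≥25% shared) skips alignments
against centroids far below the threshold; under point-substitution
noise a pair at 97% identity shares ~70% of its words, so the screen is
effectively lossless (tests compare it against the exhaustive path), and
`screen_frac = 0` disables it. Taxon validation keeps clusters of at
least three member reads — "three identical reads" is read as three reads
in the same 97% cluster, since literal identity is not implied by a
clustering threshold — and the representative is the longest member
above 400 nt.

The per-sample indices are the survey's four:

* **Chao1** `S + n1²/(2 n2)`, with `n1` the singleton count and — as this
  survey defines it — `n2` the number of OTUs with **two reads or more**.
  The textbook doubleton definition is available via `classic = TRUE`.
  When `n2 = 0` the bias-corrected degenerate form `S + n1(n1−1)/2` is
  returned and flagged.
* **Shannon** `H' = −Σ p_i ln p_i`, natural log by default (consistent
  with the magnitudes such surveys report); the base is configurable.
* **Margalef** `d = (S−1)/ln N`, defined as 0 at `N = 1`.
* **Simpson** defaults to the Gini--Simpson complement `1 − Σ p_i²`;
  the dominance form `Σ p_i²` and the unbiased finite-sample complement
  are selectable, since which variant a given survey printed is usually
  ambiguous. Neither is asserted as "the" published value.

`rarefaction_curve()` computes the analytic hypergeometric expectation
`E[S_n] = Σ_i (1 − C(N−n_i, n)/C(N, n))` (evaluated with log-binomial
coefficients for stability) and offers a seeded Monte Carlo mode
(subsampling without replacement) that the tests require to agree within
three standard errors. Whether a given published curve was analytic or
resampled is generally unstated; the analytic mode is the default
because it is exact and deterministic.

`relative_change()` is the normalized between-date statistic
`R = (n_B/N_B)/(n_A/N_A)`; taxa absent on the first date are flagged
"new" and on the second "lost" (R = 0). At the original survey's scale,
counts 660 → 5435 against totals 18 280 / 41 057 give R = 3.67, the
3.7-fold enrichment of the bloom group.

## Phylogenetics of the focal group

Validated OTU representatives, plus the reference sequences of the bloom
taxon's family, are aligned by `align_representatives()`: a deterministic
progressive aligner (average-linkage guide tree on pairwise identities,
affine-gap profile--profile merges, compiled). A production MSA tool is
deliberately not re-implemented; the testable core of the stage is
distances and tree building, and the progressive aligner is sufficient
for the handful of representative sequences involved.

`k2p_distance()` excludes columns with a gap or ambiguity in either row
(pairwise deletion; complete deletion is not used) and evaluates
`d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` from the transition and
transversion proportions. Saturated pairs (non-positive log arguments)
are reported as a flagged maximum (default 10) rather than NaN, so
downstream tree building stays defined. `nj_tree()` performs classical
Saitou--Nei neighbor joining (exact on additive matrices — a test
oracle); negative branch lengths, an occasional NJ artifact, are clamped
to zero with the deficit moved to a sister branch, the common convention.
`bootstrap_support()` resamples alignment columns with replacement,
deriving replicate `r`'s seed from `(seed, r)` so replicates are
reproducible and order-independent, and scores each internal bipartition
of the full-data tree by its replicate frequency (1000 replicates by
convention). Newick output quotes labels containing structural
characters; round trips preserve topology, branch lengths (≤1e-9) and
supports. Interpretive clade names of published figures are not
reproduced; the artifact reports clades and their per-sample read
tallies.

## Carbon biomass

`biovolume()` applies the nearest-geometric-solid formulas (sphere,
prolate spheroid, cylinder, cone, cylinder with half-sphere caps).
Carbon conversions are per group: ciliates use the constant
190 fg C µm⁻³; dinoflagellates the power law 0.760 V^0.819 pg C;
phytoplankton groups use configurable `a V^b` allometries defaulting to
the standard size-dependent coefficients (diatoms a = 0.288, b = 0.811;
non-diatom protists a = 0.216, b = 0.939 — values from the literature
the method conventionally cites, not fitted here). Colony carbon for the
bloom former is pluggable and defaults to the generic non-diatom law;
heterotrophic nanoflagellates likewise. Biomass is exactly
`abundance × cell carbon × 10⁻⁶` µg C L⁻¹, group stocks sum exactly to
the grand total, and `fold_change_summary()` reports max/min stock
ratios with the integer rounding used in survey prose ("34-fold",
"a factor of four"). The often-quoted predator-to-prey biomass
percentage is computable from the stock series but needs the full
time series to match any published average, so it is not asserted.

## Orchestration, determinism and problem sizes

`run_pipeline()` chains the stages under a flat key-value configuration
whose defaults are the conventional analysis parameters (E-value 1e-5,
min-score 5, top-percent 1, min-support 1, identity 0.97, validation at
3 reads, representative floor 400 nt, 1000 bootstrap replicates). All
randomness derives from the single config seed through named per-stage
sub-streams (`derive_seed()`), so reruns are byte-identical — the
pipeline tests compare whole output directories. A read-count ledger
records inputs, outputs and itemized drops at every stage.

The bundled analysis scripts and the test suite run the simulation at
desk scale: a 27-reference database (3 families × 3 genera × 3 species),
two samples of 180 and 410 reads (preserving the original ~1:2.2
read-depth ratio), and a 10-taxon community with the bloom taxon at 90%
on the second date. These sizes were chosen so every stage's behavior is
exercised — truncation, misassignment pressure from congeneric
references, singleton OTUs — while the full workflow remains a
minutes-scale run on a laptop.

## Known limitations

* The built-in aligner's E-values use fixed ungapped Karlin--Altschul
  parameters for the +2/−3 scheme; they are calibrated for filtering,
  not for BLAST-identical statistics.
* The greedy clustering order and the shared-word screen are a
  deterministic stand-in for a specific external tool's unspecified
  heuristics; cluster boundaries for borderline pairs may differ from
  any particular Uclust build.
* The progressive aligner is adequate for tens of sequences; it is not a
  general MSA replacement.
* Published figure-level values that depend on the real reads and the
  full Silva reference (per-group read percentages, per-OTU tallies,
  index values for the real samples) are out of reach by construction;
  the tests instead pin the statistics' defining properties and the
  worked examples computable from printed counts.
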