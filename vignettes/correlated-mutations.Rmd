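---
title: "Correlated mutations in families of interacting proteins: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated mutations in families of interacting proteins: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corrmut)
library(dplyr)
```

## The problem

When a deleterious substitution at one protein site is compensated by a
substitution at another site, the two sites accumulate correlated mutations:
their variation across a family of homologous sequences is statistically
coupled. Within one protein, such couplings tend to connect residues that are
close in the folded structure; between two interacting proteins — under the
interolog assumption that orthologs of interacting proteins also interact —
they point at interface residues. `corrmut` implements a complete pipeline
for this analysis on a family of interacting proteins, such as the plant
MIKC-type MADS-domain transcription factors that motivate its design: a
DNA-binding (MADS) domain with solved homologous structures, an intervening
(I) domain, and a keratin-like (K) domain predicted to form coiled-coil
helices.

Working with a whole family, rather than a single protein pair, buys two
things. First, the same homologous position pair can be examined in many
family members, so a detection can be scored as *conserved* (seen in more
than one member) — recurrence is evidence that the signal is not noise.
Second, pairs of family members known *not* to interact provide a matched
negative control for the intermolecular analysis: every validation statistic
can be compared between interacting and non-interacting sets.

## The coevolution statistic

For an alignment column $k$, every pair of sequences $(i, j)$ with residues
at $k$ contributes the substitution-matrix score of its residue pair,

$$\theta_k(i,j) = B\!\left(a_{ik},\, a_{jk}\right),$$

with $B$ a BLOSUM matrix (BLOSUM62 by default; configurable). Scores are
centred per column over the defined sequence pairs — the entry measures
variability *relative to the mean variability of the site* — giving a site
variability vector $D_k$ with one entry per sequence pair. The coevolution
score of two columns is the Pearson correlation of their variability vectors
over the sequence pairs defined in both, and a pair of columns is reported
when $r \ge 0.4$, a conservative threshold in line with earlier
correlated-mutation work. Reported pairs are grouped into *correlated
groups*, the connected components of the graph whose edges are the reported
pairs; all threshold-passing pairs are kept and annotated with their group
(an option restricts output to multi-pair groups).

Sequence pairs that diverged longer ago have had more time to accumulate
coincidental double substitutions. The optional (and default) *time
correction* divides each centred entry by the pair's Poisson-corrected
amino-acid distance $t_{ij} = -\ln(1 - p_{ij})$, where $p_{ij}$ is the
fraction of differing residues over shared non-gap columns; the vector is
then re-centred. Centring *before* the normalisation keeps constant columns
at an exact all-zero vector, so two invariant sites can never appear
correlated merely because both score vectors are proportional to $1/t$.
Identical sequence pairs ($t = 0$) are dropped from time-corrected vectors
rather than floored, and $p = 1$ is outside the model's domain. For paired
alignments, one joint divergence per ortholog-pair row pair is computed on
the concatenation of the two rows.

Numerical guard rails, chosen where the method description is silent:

* an entry is undefined when either residue is a gap; correlations use the
  intersection of defined pairs;
* columns with gap fraction above 0.1 are skipped (configurable);
* a correlation requires at least `max(10, n_pairs / 2)` common defined
  pairs — small overlaps produce spuriously extreme $r$;
* a column pair with a constant restriction has no defined correlation and
  is skipped, not reported;
* the cutoff applies to signed $r$; an option thresholds $|r|$ instead.

Intramolecular mode scans all column pairs of one family alignment;
intermolecular mode scans only A-columns against B-columns of a paired
alignment, and positions are reported as (molecule, column) plus reference
residue coordinates.

## Dataset assembly

The ortholog-set construction mirrors how such a family dataset is built
from heterogeneous sources (domain-database membership, similarity search,
and fully sequenced genomes):

* **Best-hit assignment**: each candidate goes to the reference protein with
  the highest pairwise identity, computed with gaps counting as
  non-identical (gap–gap columns excluded from the denominator;
  configurable). For genome-derived candidates — where the sequence
  complement is complete — the criterion is bidirectional: the candidate
  must in turn be its reference's best hit within its species-and-source
  pool. Identity ties break towards the lexicographically smaller reference
  id, with a warning.
* **Within-species redundancy removal** at 95% identity. The published
  workflow used a standalone clustering tool whose exact behaviour is
  unspecified; `corrmut` uses a documented greedy centroid rule (members in
  input order join the first cluster whose founding member is within the
  cutoff) that preserves the intent — collapsing near-identical
  within-species sequences while keeping the reference proteins apart.
* **Representative selection** by source priority genome > interpro >
  blast, random (seeded) among ties.
* **Filters**: at least 25% identity to the assigned reference (inclusive),
  and at least 30 rows per family or 30 ortholog pairs per interaction set
  (inclusive) — below that, correlation estimates are unreliable.
* **Co-ortholog pairing**: per species, the full Cartesian product of
  A-orthologs and B-orthologs (2 co-orthologs each side give $2 \times 2 =
  4$ ortholog pairs). Clustering is applied before pairing.

## Validation against independent data

**Structure distances.** `min_heavy_atom_distances()` reads a PDB file and
returns, for every residue pair within and across chains, the minimum
distance over heavy atoms (hydrogens ignored, first altloc kept,
insertion-coded residues skipped with a warning). Correlated pairs are
compared against these distances at 15 Å and 10 Å: the fraction of detected
pairs within the threshold is set against the background fraction over all
residue pairs, with a resampling p-value from 1000 random background subsets
of the same size. Pairs outside the structure-mapped range are excluded (the
mapping from structure numbering to reference coordinates is supplied
explicitly, since only part of a reference protein is typically covered by a
homologous structure).

**Interaction motifs.** Overlap with externally predicted interaction-motif
pairs is scored at single-residue resolution in reference coordinates:
coverage of motif positions by correlated positions, coverage of correlated
positions by motifs, and their harmonic mean (F-score). *Consistent* overlap
additionally demands molecule matching — the two positions of a correlated
pair falling inside the two member motifs of one complementary motif pair,
respectively — counted per motif pair over interaction pairs.

**SNPs.** A SNP overlaps when its residue position is a correlated position
of the same protein in the analysis set under consideration; matching is
exact-position (no window). Counts and fractions are reported per class
(synonymous / non-synonymous) and per analysis set. Functionally important
interface positions are expected to show *fewer* non-synonymous SNPs at the
short within-species timescale even though they are variable across species.

## Randomization tests

All four significance procedures use the add-one convention
$p = (1 + \#\{\text{null} \ge \text{observed}\}) / (1 + \text{reps})$, which
never returns zero and is conservative (super-uniform) under the null:

1. **Random background subsets** for distance enrichment (above).
2. **Pairing shuffle**: rows of molecule B are permuted against molecule A
   and the full intermolecular detection re-run per replicate — genuine
   intermolecular coevolution cannot survive the shuffle. Because each
   replicate re-runs the engine, the default is 100 replicates (overridable
   to 1000).
3. **Position randomisation** for the motif F-score: each distinct
   correlated position is replaced by a random position of its protein, the
   same replacement applied to every pair sharing the position (a
   per-protein injection per replicate).
4. **Random stretches** for helix periodicity: stretches with the number and
   lengths of the called helices are re-placed uniformly at random, without
   overlap, in the analyzed region, and the periodicity statistic
   recomputed.

The calibration suite verifies on null-simulated data that the empirical
frequency of $p \le 0.05$ stays at or below 0.07 for tests 1, 3 and 4 over
hundreds of trials; test 2, whose per-trial cost is a full engine run, is
verified on planted data (shuffling destroys the planted signal; the
identity permutation reproduces the observed statistic exactly).

## Conservation across family members and entropy

Homologous positions of different family members are defined through a
user-supplied master alignment of the reference proteins
(`build_homology_map()`): an explicit, auditable mapping rather than an
implicit one. A correlated pair of protein X is *conserved* in protein Y
when both positions map (no gap in Y) and the mapped pair is itself a
correlated pair of Y; positions hitting a gap are *unmappable* and excluded
from the conserved-in-at-least-one fraction.

Why is a pair not conserved in some member? Either the homologous positions
do not vary there (consistent with functional importance), or they vary
without correlation. The two cases are separated with column entropy
$S_k = -\sum_{j=1}^{20} P_{jk} \ln P_{jk}$ (natural log, so values lie in
$[0, \ln 20 \approx 3.0]$), computed over the 20 amino acids with gaps
excluded and frequencies renormalised. For every correlated position and
every other protein whose homologous position carries no correlated
mutation, the entropy of the correlated column is compared with the entropy
of the homologous column; the strict-inequality fraction ("how often is the
correlated site more variable than its silent homolog") is reported
separately for positions of conserved and of never-conserved pairs. Ties
count as not-higher.

For the intermolecular analysis, recurrence is counted at the level of
*conserved groups*: mapped position pairs observed in more than one
interaction pair, tallied separately for interacting and non-interacting
sets and normalised by each set's total pair count.

## Helix topology

Coiled-coil probability tracks are inputs (any per-residue predictor will
do; re-implementing a specific predictor's scoring is out of scope — the
bespoke statistic downstream is the point). `call_helices()` turns a track
into maximal runs with probability at least 0.5 and length at least 4.
Within-helix correlated pairs are binned by sequence separation
$d = |i - j|$ in reference residue coordinates; on a helix, one turn is
~3.6 residues, so contacts on the same face prefer $d = 4$ (and 3, 7) while
$d = 2$ points to the opposite face. The periodicity statistic is
$\Delta = \mathrm{pct}(d{=}4) - \mathrm{pct}(d{=}2)$ in percentage points,
tested against the random-stretch null. Whether histogram percentages are
pooled across proteins or averaged per protein is a free choice; pooling is
implemented (per-protein histograms are available by filtering the input).
Helix-to-helix and helix-to-domain contact tabulation uses declared interval
bins; the default domain intervals (MADS 1–58, I 59–89) are configurable
because domain boundaries vary between proteins.

## The synthetic-data generator

No deposited processed dataset exists for this kind of analysis, so the
package ships a generator that produces every input the pipeline consumes,
with the statistical structure the analysis assumes:

* **Star phylogeny**: each sequence descends independently from a random
  ancestor. This deliberately removes shared-ancestry correlation — the
  main confounder of correlated-mutation analysis — so that planted
  compensation is the only coevolution source and recovery can be measured
  cleanly. Background sites substitute uniformly over the 20 amino acids at
  a per-leaf probability solved so the expected pairwise Poisson distance
  matches the configured depth (default 0.7 substitutions per site, a
  plausible cross-species divergence for a plant gene family; the realised
  mean tracks the target within a few percent at 60 sequences).
* **Planted pairs** evolve over a two-state compatible-state system (a
  charge-pair metaphor: K↔D at one position matched with E↔R at the other).
  When the first position toggles, the partner adopts the compatible state
  with probability $q$ (compensation strength) and evolves independently
  otherwise. The per-leaf toggle probability defaults to
  $\min(0.5,\, 1 - e^{-\text{depth}})$, matching background substitution
  pressure while keeping both states common.
* **Default sizes** — 60 sequences, 100 columns, $q = 0.9$ — are the
  conditions of the recovery suite: comfortably above the 30-row minimum
  the analysis itself enforces, with column counts that keep a full
  detection run fast. Interaction sets default to 34 interacting and 34
  non-interacting pairs, the scale of the reference interaction screen;
  the test and acceptance ensembles simulate one of each per seed across
  20 seeds instead, which measures the same discrimination at desk scale.
* **Toy structures** lay residues along an extended, jittered chain (4 Å
  spacing; two well-separated chains for intermolecular fixtures) and
  relocate each planted pair's second residue to within the contact
  distance (default 8 Å), so planted pairs are in contact and typical
  other pairs are beyond 15 Å. CA and CB pseudo-atoms are emitted as
  minimal single-model PDB, exercising the real structure reader.
* **Annotations**: motif pairs centred on planted positions with
  probability `fidelity` (else random), non-synonymous SNPs avoiding
  planted positions with probability `fidelity`, and coil tracks marking
  declared helix regions.

What passing on synthetic data does *not* show: robustness to phylogenetic
structure (a two-clade variant of the generator would be needed; real
families share ancestry), to alignment error, to indels (not simulated), or
to the weaker, heterogeneous compensation of real proteins. The planted
two-state signal is idealised; recovery there is a correctness check of the
machinery, not an accuracy claim for real alignments.

## A worked run

```{r pipeline}
planted <- tibble::tibble(pos_1 = c(10, 30, 50), pos_2 = c(20, 40, 60))
fam <- simulate_family(n_seq = 60, n_col = 80, planted = planted,
                       q = 0.9, seed = 7)
pairs <- detect_correlated_pairs(fam, cutoff = 0.4)
pairs
```

```{r structure}
ts <- make_toy_structure(n_res = 80, planted_pairs = planted, seed = 8)
distance_enrichment(pairs, ts$distances, thresholds = c(15, 10),
                    reps = 200, seed = 9)
```

```{r plot, fig.width = 5, fig.height = 3}
sets <- simulate_interaction_set(n_interacting = 1, n_noninteracting = 1,
                                 n_seq = 60, seed = 10)
null <- shuffle_pairing_null(sets$interacting[[1]], reps = 50, seed = 11)
glance(null)
autoplot(null)
```

## Reproducibility notes

Every stochastic function takes an explicit seed (or runs inside the
caller's seeded RNG scope) and is byte-reproducible. The acceptance script
(`scripts/acceptance.R`) re-runs the recovery, discrimination, conservation
and periodicity analyses from scratch at the default study conditions
(20-seed ensembles, 100–1000 resampling replicates) and writes the resulting
quantities as JSON; the test suite additionally verifies the engine against
a brute-force oracle to $10^{-12}$, the structure reader against an
all-atom scan, and the three cheap randomization tests against their null
calibration.
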