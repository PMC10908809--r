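---
title: "Inferring mother-infant virome strain transmission with virotrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mother-infant virome strain transmission with virotrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`virotrace` implements the computational chain of a longitudinal mother-infant
gut virome study as reusable, tested functions: curation of assembled viral
scaffolds from precomputed annotation features, construction of
breadth-filtered RPKM abundance profiles, longitudinal community summaries,
strain-level Kimura 2-parameter (K2P) distances, inference of mother-to-infant
strain transmission, and phage-host co-transmission linkage. Upstream
bioinformatics (assembly, viral detection, clustering, host prediction,
consensus calling, multiple alignment) is out of scope; its outputs arrive as
plain tables and aligned FASTA. A synthetic cohort generator with planted
ground truth exercises every stage end to end.

## Viral scaffold curation

Scaffolds of at least 1 kbp are putatively viral if they satisfy at least one
of six criteria: (1) a RefSeq-viral BLAST hit, (2) at least three pVOG HMM
hits with at least two hits per 10 kb, (3) a VirSorter-positive call (any
category, including suggestive), (4) a circular assembly, (5) a hit to a
Crassvirales reference set, or (6) length above 3 kbp with no nt-database hit.
Scaffolds co-clustering with negative-control assemblies are removed first.
Genus-level viral clusters (VCs) are then condemned when any member carries an
rRNA gene, more than three ribosomal protein genes, or at least one ribosomal
protein gene with fewer than three pVOGs per 10 kb while VirSorter-negative
and non-circular; members of condemned VCs survive individually when circular
with at least one pVOG, circular and VirSorter-positive, or VirSorter-positive
without ribosomal protein genes. Rescue deliberately takes precedence over
condemnation for the individual member — the rescue rules describe stronger,
member-level evidence of a viral genome than the cluster-level contamination
signal. Boundary conventions are explicit: "at least three pVOG hits" is
`>= 3`, "longer than 3 kbp" is strictly `> 3000`, and the pVOG density is
`pvog_hits / (length_bp / 1e4)` compared with `>= 2` for inclusion and `< 3`
for condemnation.

Temperate phages are called from gene content: an integrase gene, or a
recombinase gene together with a CI-repressor-like gene; everything else is
treated as virulent.

## Abundance profiles

Read counts whose breadth of coverage (fraction of scaffold positions covered)
is below 75% are set to zero; records exactly at the threshold are retained,
since the rule is "less than". The filtered counts become RPKM values,
`count / (length/1000) / (library/1e6)`, where the library size is the
per-sample mapped-read total supplied with the metadata (configurable — the
choice between total quality-trimmed and virome-mapped reads is left to the
data producer). Host-level profiles sum vOTU rows sharing a predicted host,
keeping the single highest-confidence host when several are predicted and
collecting unmapped vOTUs under `unassigned`, so column totals are conserved.

## Longitudinal dynamics

Diversity uses the natural-log Shannon index and Bray-Curtis dissimilarity
(both via vegan, the standard implementations). Retention of an early
community in a later sample reports the retained entity count, its share of
the later sample's richness, and its share of the later sample's abundance.
The persistent/transient partition assigns an entity to an individual's
persistent personal virome when present in at least 75% of that individual's
samples (boundary inclusive, minimum three samples). Confidence intervals use
a percentile bootstrap on replicate means (1000 resamples, type-7 quantiles at
0.025/0.975).

## Strain distances

Per-entity consensus alignments are trimmed by 100 bp at both ends (global
alignment flanks are gap-enriched), and all pairwise K2P distances are
computed: with transition proportion P (A&harr;G, C&harr;T) and transversion
proportion Q over comparable columns,
`d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`.
Columns carrying a gap or ambiguity code are deleted per pair rather than
across the whole alignment — per-pair deletion wastes less signal when
different samples have different missing regions; global deletion remains
available by pre-masking. Pairs whose log argument is non-positive are
saturated and propagate as `NaN`, excluded downstream with a warning.
Distances are median-normalized per entity; the default normalizer is the
median of within-individual longitudinal distances (falling back to all finite
distances when an entity has none), which expresses every distance in units of
typical within-host strain drift.

## Transmission inference

For each entity, the test asks whether strain distances between related
individuals (a mother and her own infant) are smaller than between unrelated
individuals. The statistic is the rank-based AUC of the related-vs-unrelated
comparison (equivalent in ordering to the one-sided Wilcoxon rank sum).
Because every pair that shares an individual also shares that individual's
base strain, pair distances are strongly dependent; permuting relation labels
freely over pairs is anticonservative under this dependence (empirically, a
~22% rejection rate at the 5% level on null cohorts). The default null
therefore permutes family/role assignments over *individuals*, inducing a
pair-label permutation that preserves the dependence structure; this scheme is
exactly valid when individuals are exchangeable and also accommodates the
highly unequal sizes of the two groups. The pair-level scheme, including an
exhaustive enumeration mode used as a small-sample oracle, remains available
in `related_unrelated_permutation_test()`. P-values are
`(1 + #(stat_perm <= stat_obs)) / (n_valid + 1)` with 1000 iterations by
default, BH-adjusted across entities.

Entities with significantly closer related strains (FDR < 0.05) proceed to
sharing calls. The strain-identity cutpoint compares within-individual
normalized distances (positives) against unrelated-pair normalized distances
(negatives): Gaussian kernel density estimates of both groups (Silverman
bandwidth) are evaluated on a 512-point grid spanning the pooled range, and
the threshold maximizes the kernel-smoothed Youden index
`J(t) = TPR(t) + TNR(t) - 1`. Two numerical choices matter here. First, when
the groups are well separated, J is numerically flat over a wide interval; the
threshold is the midpoint of that optimal plateau — the maximal-margin
separator — rather than its first grid point, which would hug the
within-individual distribution and misclassify genuinely transmitted strains
lying slightly above the within-host drift scale. Second, when the Youden
threshold would admit more than 5% of unrelated pairs, the empirical-FDR
fallback replaces it with the 5th percentile (type-7) of the unrelated
distances, capping the unrelated admission rate at 5%. A zero-variance group
degrades the KDE; the cutpoint then falls back to the midpoint between the
group extremes, with a warning.

A pair of samples shares a strain when its normalized distance is strictly
below the threshold; ties at the threshold are called "different" (the
source rules define both strict sides and leave equality open, and the
conservative reading avoids inflating sharing). Sharing enrichment in related
over unrelated pairs uses a one-sided Fisher's exact test, and the
pre-/post-birth comparison contrasts sharing with maternal samples collected
before birth (gestational timepoints and birth) versus after (months 1-3),
again one-sided. Pairs sharing a sample are treated as independent in these
Fisher tests — a simplification inherited from the underlying study design
and flagged here as a statistical caveat; the permutation test above, not the
Fisher test, carries the main inferential weight.

## Co-transmission linkage

For each virus and its predicted host with strain data, the concurrent subset
collects individual-timepoints where both strains were reconstructed,
preferring VLP-derived strains over total-metagenome (MGS) strains for the
virus when both exist. Normalized distances are binarized against each
entity's threshold (0 = shared, 1 = different), and a control matrix marks
same-individual sample pairs (a mother and her infant count as different
individuals). The partial Mantel statistic correlates the vectorized upper
triangles of the two sharing matrices, partialling out the control matrix by
the standard residual formula; significance comes from 999 simultaneous
row/column permutations of the virus matrix (one-sided, positive
association). Constant sharing matrices cannot be tested; a constant control
matrix downgrades to the simple Mantel test; a sharing matrix collinear with
the control matrix makes controlling impossible and the pair is skipped.

Non-random linkage is `delta = f_obs - f_exp` over unordered concurrent
sample pairs, where `f_obs` is the joint sharing frequency and `f_exp` the
product of the marginal sharing frequencies; "proportion of concurrent
samples" is interpreted at the level of sample *pairs*, the objects on which
distances are defined. Significance uses a chi-squared test of independence
on the 2x2 sharing table without continuity correction (expected counts below
5 warn rather than switch methods). Degenerate margins return p = 1 with a
warning. A pair is flagged co-transmitted when its BH-adjusted Mantel p-value
is below 0.05 with positive correlation, and host-linked pairs are compared
against random virus-bacterium pairs with a one-sided Fisher's exact test.

## The synthetic cohort generator

The generator emulates the sampling design of a mother-infant cohort:
families of one mother (timepoints P3, P7, B, M1, M2, M3 — gestational weeks
approximately 12 and 28, birth, and months 1-3) and one or two infants
(months 1, 2, 3, 6, 9, 12), with VLP and total-metagenome samples per
individual-timepoint and uniform dropout (each individual always retains at
least two timepoints so longitudinal distances exist).

Strain sequences evolve under the continuous-time K80 model with analytic
transition probabilities, so the expected re-estimated K2P distance equals the
requested branch length exactly — for branch length d and
transition/transversion ratio kappa, the per-site transition probability is
`1/4 + 1/4 exp(-4bt) - 1/2 exp(-2(at+bt))` and the total transversion
probability `1/2 - 1/2 exp(-4bt)` with `bt = d/(kappa+2)`, `at = kappa bt`.
The genealogy is star-like: per entity, each family's maternal base strain
sits `d_unrelated/2` from the entity ancestor (unrelated pairs ~`d_unrelated`
apart); a transmitted infant base evolves `d_transmit` from the maternal base,
a non-transmitted infant independently `d_unrelated/2` from the ancestor; each
sample drifts `d_within/2` from its individual's base, so longitudinal pairs
sit ~`d_within` apart and related transmitted pairs
~`d_transmit + d_within`. When a phage is coupled to its predicted host
(probability `coupling_rate` given transmission), the host is forced
transmitted in the same family and the phage strain is present exactly in the
individual-timepoints where the host strain is present.

Defaults were chosen once for a plausible desk-scale cohort: 8 families, one
infant each, `transmission_rate` 0.5, `coupling_rate` 0.5, `d_within` 0.002,
`d_transmit` 0.005, `d_unrelated` 0.1 substitutions/site, kappa 2 (the
textbook transition bias), 5 kb sequences, 85% per-timepoint presence, 10%
dropout, 50% temperate probability, and lognormal abundances with per-vOTU
infant shifts so mother and infant viromes differ in composition, not just
depth. No distributional parameters for within- versus between-individual
strain distances are available from data at desk scale; these values are
chosen for testability — clear but not degenerate separation — rather than
claimed realism.

What the generator does *not* emulate: read-level noise, assembly and
alignment errors, recombination, indels (alignments are gap-free by
construction except where tests plant gaps), coverage-dependent consensus
quality, prophage coordinates, and realistic phage abundance kinetics.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery on its stated model, not performance on real
metaviromes.

## Reproducibility and problem sizes

Every stochastic step takes an explicit seed; one master seed fans out to
per-entity child seeds through a counter, so results are identical across
runs and robust to evaluation order. The test suite validates the type-I
error of the transmission test on 500 null entities (10 cohorts of 50 vOTUs,
1 kb sequences, 1000 permutation iterations) and parameter recovery on a
cohort of 40 vOTUs and 25 bacteria at 20 kb with `transmission_rate` 0.5 and
`coupling_rate` 1 — sizes chosen to give stable rates while keeping a full
run on a single CPU within minutes. Pairwise distance matrices are computed
with BLAS cross-products over per-base indicator matrices, which keeps the
20 kb cohort tractable.

## Known limitations

- Transmission direction is assumed mother-to-infant; the test is symmetric
  in the pair and directionality is not inferred.
- The Fisher enrichment and pre/post-birth tests ignore dependence among
  pairs sharing a sample.
- The empirical-FDR fallback conditions on the observed unrelated
  distribution; with few unrelated pairs the 5th percentile is noisy.
- Saturated (NaN) distances are excluded rather than imputed; entities whose
  normalization median is zero or undefined are excluded from sharing calls
  with a warning.
- Configuration validation is explicit field/range checking of the YAML
  contents rather than schema-based.
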