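---
title: "Methods: core drought-responsive microbiome inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: core drought-responsive microbiome inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, how they were resolved, and what a passing
test suite does and does not establish.

## The inference chain

The package targets replicated multi-genotype amplicon designs: a panel of
plant ecotypes grown under control and drought watering, with an ASV count
table, per-sample design factors (ecotype, treatment, tolerance class,
replicate), a taxonomy table, and optionally isolate 16S sequences and
screening phenotypes. The chain is:

1. filtering (taxa observed in ≤ 1 sample are removed) and conversion to
   relative abundances;
2. community structure: Shannon/richness, Bray–Curtis, PCoA, PERMANOVA;
3. per-ecotype differential abundance (DA) of taxa above an abundance
   floor, by exact two-sided Wilcoxon rank-sum tests;
4. cross-ecotype consensus: core-responsive taxa, and the tolerant vs
   sensitive fold contrast used to prioritise strains;
5. per-(ecotype × treatment) Spearman co-occurrence networks with
   topology, modularity, and cohesion;
6. control-vs-drought network comparison: neighbor-shift (NESH) scores,
   per-ecotype driver taxa, cross-ecotype core driver genera;
7. isolate dereplication, greedy 97 % OTU clustering, and matching of
   core ASVs to cluster representatives;
8. phenotype arithmetic: wilting-based tolerance index, relative fresh
   weight, microbiome-mediated protection effect.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `abundance_min` | 0.001 | mean relative-abundance floor before DA testing (0.1 %) |
| `alpha` | 0.05 | per-ecotype DA threshold, *unadjusted* by default |
| `k_core` | 5 | minimum ecotypes supporting a core call |
| `f_min` | 1.2 | enrichment fold floor (depletion symmetric at 1/`f_min`) |
| `eps` | 1e-6 | pseudocount on relative abundances in fold ratios |
| `net_abund_min` | 0.002 | network candidate floor (0.2 % within context) |
| `net_min_prev` | 2 | minimum samples with nonzero abundance |
| `rho_min`, `q_max` | 0.9, 0.05 | \|Spearman ρ\| and BH-q edge retention |
| `cohesion_n_null` | 200 | taxon-shuffled tables for the cohesion null |
| `driver_min_ecotypes` | 4 | ecotypes required for a core driver genus |
| `id_min` | 0.97 | OTU clustering / ASV-isolate match identity |
| `n_perm` | 999 | PERMANOVA permutations |

No multiplicity correction is applied in per-ecotype DA by default because
the screening criterion being reproduced is a raw p < 0.05 cutoff; the
`adjust = "BH"` flag exposes the stricter variant. The depletion fold
threshold is taken symmetric (1/`f_min`) since the stated criterion only
quantifies enrichment.

## Numerical and procedural choices

**Exact Wilcoxon.** Up to 12 pooled observations the rank-sum null is
enumerated over all C(n₁+n₂, n₁) assignments of the observed (possibly
tied) mid-ranks, so ties are exact too; beyond that a tie-corrected normal
approximation with continuity correction is used. With 4 vs 4 replicates
the smallest achievable two-sided p is 2/70 ≈ 0.029: significance at
α = 0.05 requires complete separation, and the realised type-I rate of the
screening procedure is 0.029, not 0.05. This discreteness is a property of
the design being reproduced; the calibration test therefore uses 6 vs 6
groups, where the achievable rejection rate (≈ 0.041) can sit inside the
[0.03, 0.07] band.

**PERMANOVA.** One-factor mode uses the group-pair sum-of-squares
identities; the sequential two-factor mode uses McArdle–Anderson hat-matrix
partitioning on the Gower-centred matrix (terms added in order, the
classical adonis default) and is what the pipeline reports for
ecotype + treatment. Permutations are free (unrestricted); p-values use
(1 + b)/(1 + m) so they are never zero. Pairwise mode BH-adjusts across
group pairs.

**Spearman edge p-values** use the t approximation
t = ρ√((n−2)/(1−ρ²)), as common co-occurrence tooling does. This is a
deliberate deviation from exactness: with 4 replicate samples per network
the exact two-sided p of even a *perfect* rank correlation is 2/24 ≈ 0.083,
so an exact-test reading of "|ρ| ≥ 0.9 and FDR-adjusted p < 0.05" returns
empty networks for every ecotype at this design size. Under the t form,
|ρ| = 1 gives p = 0 and the published filter behaves as described.

**Networks at n = 4 are degenerate, knowingly.** Four samples admit only
24 rank orders, so taxa sharing an order form perfect-correlation cliques
and chance edges are common (≈ 8 % of pairs). Betweenness inside clique
unions is mostly zero, which makes strict betweenness-increase driver
calls rare at this depth. The driver machinery is exercised and validated
on deeper-replication fixtures; conclusions from 4-sample networks should
rest on counts/connectance/cohesion rather than path statistics.

**NESH.** The implemented score is the case-specific-neighbor fraction
NESH(v) = \|B∖A\|/\|B\| over neighbor sets restricted to nodes common to
both networks (A control, B case; 0 when B is empty): 0 for an unchanged
neighborhood, 1 when every case neighbor is newly gained, monotone in
turnover. A driver additionally requires strictly increased betweenness;
the scaled-NESH threshold defaults to the mean over common nodes because
the comparison tool being emulated publishes no threshold — both are
configurable. Restricting neighborhoods to common nodes avoids penalising
nodes whose partners merely dropped out of the abundance filter.

**Cohesion.** Pairwise Pearson correlations on relative abundances are
corrected by subtracting the mean correlation across `n_null` tables in
which each taxon is independently permuted across samples. Positive
connectedness of taxon j is the mean over *all* other taxa of the positive
part of the corrected correlation (equivalently, negatives contribute
zero), and per-sample cohesion is the abundance-weighted sum. Averaging
the positive part over all partners (rather than over positive partners
only) makes null cohesion shrink as 1/√n_samples, which is what the
null-behaviour acceptance check quantifies; the convention is fixed and
documented here because the literature uses both.

**Sequence identity.** Identity is computed from a Needleman–Wunsch
alignment (match +1, mismatch −1, gap −2 per column) as identical columns
divided by aligned columns excluding terminal-gap columns, N never
matching. An ends-free (overlap) mode exists but is not the default: on
*unrelated* ~420-nt amplicons the optimal ends-free overlap collapses to a
short lucky window (~0.8 apparent identity on random pairs, occasionally
above 0.97), which destroys 97 %-threshold semantics. Penalised end gaps
with a trimmed-denominator identity — the convention of standard amplicon
clustering tools — keeps unrelated pairs near 50 % while substitution-only
pairs score exactly 1 − substitutions/length. Greedy clustering processes
unique sequences in decreasing abundance (ties by id), joining the
best-identity centroid at ≥ 97 % (inclusive boundary); matching breaks
ties by larger cluster size, then id.

**Determinism.** All stochastic stages derive per-stage substreams from
one master seed by hashing the stage name, so stages can be re-run
independently and the whole pipeline is byte-reproducible. Greedy
(agglomerative) modularity is used instead of stochastic Louvain for the
same reason. Config files are JSON.

## The synthetic world

`generate_community()` draws, per sample, a Dirichlet-multinomial vector
around a log-normal base composition (σ_log = 1.5 over 300 taxa; taxon ids
are assigned in decreasing base-abundance order):

- planted effects multiply chosen taxa by fold *f* in drought samples of
  affected ecotypes, and by *f* × `group_differential` in tolerant-class
  ecotypes (defaults: 10 taxa at abundance ranks 11–20, fold 3, 6 of 10
  ecotypes affected evenly across both classes, group differential 1.5);
- correlation modules multiply member taxa by exp(λ·σ_m·z) with one
  latent z ~ N(0,1) per module per sample (λ = 0.9, σ_m = 0.6) before
  renormalisation — a Gaussian-copula-style mechanism giving tunable
  positive Spearman blocks;
- read depth is uniform on 5,000–20,000 (fixed at 10,000 in recovery
  tests).

The Dirichlet precision default (5,000) was set a priori from a power
consideration, not tuned to tests: it gives a replicate-level CV of
≈ 14 % for a 1 %-abundance taxon (≈ 17 % including multinomial noise at
depth 10⁴), the clean end of what controlled greenhouse replicates show,
and the level at which a fold-3 effect is detectable by a 4 vs 4 exact
test demanding complete separation. Field data are noisier; with realistic
field-scale overdispersion the 4-replicate exact-test design has very
little power, which is worth knowing before porting the thresholds.

Planted enrichment has a compositional side effect: multiplying ~12 % of
community mass by 3–4.5 depresses every other taxon's relative abundance
by ~20 %, so the most abundant taxa are genuinely called core-depleted.
Recovery metrics for enrichment are therefore computed against the
enriched truth set specifically.

Sequences are uniform random ACGT 420-mers (no phylogenetic structure, no
indels, no chimeras); isolates differ from their source ASV by a
Binomial(420, divergence) number of substitutions, always to a different
base, so true identity is exactly 1 − k/420. A consequence faithfully kept
in the tests: at divergence 0.05 each isolate has ≈ 2 % probability of a
realised identity ≥ 97 %, so "no matches at 5 % divergence" holds only up
to that binomial tail, and the acceptance check asserts that matches are
exactly the above-threshold isolates rather than a literal zero.

Phenotypes draw control weights around per-ecotype means with CV 15 %,
drought weights around the control mean scaled by the soil-state tolerance
factor (sterilized 0.45/0.35 for tolerant/sensitive, live-soil protection
ratio 1.6/1.05), and map wilting scores monotonically from the live-soil
factor with ordinal noise.

What a green suite establishes: the statistics are computed correctly
(oracle equivalence), calibrated under their nulls, and able to recover
planted structure of the stated magnitude at the stated design size. What
it does not establish: performance under field-scale overdispersion,
phylogenetically structured communities, indel-bearing amplicons, or
compositional artefacts beyond the closure effect modelled here.

## Open questions, resolved

- **Bulk soil** is treated as its own pseudo-ecotype: it passes through
  networks and NESH (feeding the root/bulk driver overlap) but is excluded
  from per-ecotype DA and core calling.
- **Variance partitioning** is reported sequentially (ecotype first, then
  treatment), labelled as such in the output.
- **Cluster direction** of a core taxon (enrichment vs depletion cluster)
  is assigned by majority DA direction across ecotypes, not by heatmap
  clustering.
- **Tolerance index** is the arithmetic mean of drought wilting scores;
  **protection effect** is the live/sterilized ratio of mean relative
  fresh weights (a difference mode is exposed as a flag).

## Known limitations

- Exact-test discreteness at 4 replicates (see above) bounds per-ecotype
  sensitivity and the achievable type-I rate.
- Betweenness-based driver calling is uninformative on 4-sample networks;
  treat per-ecotype driver sets at that depth as conservative.
- Relative-abundance fold changes conflate absolute enrichment with
  compositional closure; no compositional (CLR-type) models are included,
  by design, since the reproduced procedure does not use them.
- The cohesion null (taxon shuffle, `n_null` tables) is this package's
  concrete choice; other nulls in circulation will shift absolute cohesion
  values, so compare cohesion only within one convention.
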