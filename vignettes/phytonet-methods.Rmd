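---
title: "Methods: from plant phytochemicals to a co-targeted protein space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from plant phytochemicals to a co-targeted protein space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Plants associated with a reduced risk of a disease — colon cancer is the
motivating case — contain hundreds of small molecules, and the phenotype is
unlikely to come from a single compound hitting a single protein. phytonet
implements a systems-chemical-biology workflow that asks, for a catalog of
plants and their phytochemicals: which proteins of a candidate disease
space are targeted by which plants, which proteins are targeted *together*
(by the same plants), and which metabolic reactions in the tissue can be
perturbed by diet-derived compounds.

The workflow has seven computational stages, each exposed as plain
functions:

1. **Bioactivity evidence** (`filter_records`, `is_positive`,
   `aggregate_evidence`). Assay records are kept only for the six
   measurement kinds Ki, IC50, EC50, Kd, potency and inhibition, from
   human, rat or mouse assays. A record is *positive* when the pChEMBL
   value exceeds 5.5 (Ki/IC50/EC50/Kd), the inhibition percentage exceeds
   20, or the potency is below 500 uM — all strict comparisons. Repeated
   measurements of a compound on a protein are reduced to the interaction
   probability P = n_positive / n_total, and a pair is called interacting
   when P >= 0.5 (positive evidence at least balances negative).
2. **Compound matching** (`tanimoto`, `match_compound`). Exact identity is
   the full 27-character InChIKey. Structural similarity is Tanimoto
   Tc >= 0.85 on circular-fingerprint bit sets combined with a molecular
   weight difference strictly below 50 g/mol. Tc of two all-zero
   fingerprints is defined as 0: a featureless fingerprint is no evidence
   of similarity.
3. **Target space** (`target_space`, `expand_neighbors`,
   `category_overlap`). Three seed categories (approved-drug targets,
   disease-pathway members, prognostic-signature proteins) are expanded by
   first-degree neighbors over a scored protein interaction graph with a
   strict confidence threshold (score > 400, the STRING medium-confidence
   convention), after removing interaction evidence from disallowed
   organisms; proteins without positive tissue expression are removed from
   seeds and neighbors alike.
4. **Interactome** (`build_interaction_table`, `build_matrix`, `efficacy`,
   `plant_projection`, `connectivity_ratio`, `top_targeted`). Interactions
   reach a plant through two routes: *direct* (a compound of the plant has
   interacting evidence; eligible targets are seeds plus neighbors) and
   *similar* (an evidence-free compound inherits the targets of a
   structurally similar evidenced compound; restricted to seed proteins,
   where the inherited prediction is most defensible). Plant efficacy is
   E(P) = |targets(P)| / |union of all plants' targets|; the weighted
   variant sums unique compounds per targeted protein and divides by the
   maximum over plants so the top plant scores 1 and relative differences
   are preserved.
5. **Co-targeting network** (`phi_coefficient`, `phi_test`,
   `build_phi_network`, `components_and_bridges`,
   `intra_cluster_distance`). For every pair of targeted proteins, the
   2x2 table of plants targeting both/one/neither gives the phi
   coefficient; the test statistic is chi2 = n * phi^2 with 1 df
   (no continuity correction — the correction would break this identity),
   Bonferroni-corrected over the evaluable pairs, retained at adjusted
   p <= 0.05. Pairs with a zero marginal (a protein targeted by all or no
   plants) are not evaluable and do not enter the correction multiplier.
   Significant negative edges are kept and flagged: proteins consistently
   avoided together are informative too.
6. **Metabolic perturbation** (`match_metabolites`, `perturbed_reactions`,
   `pathway_load`). Compounds map to network metabolites exactly (InChIKey)
   or by the same Tc/MW similarity rule. A reaction counts as perturbable
   only when a matched metabolite occurs as a *substrate*; product-only
   occurrences never count. A reaction is highlighted when strictly more
   than 20 plants perturb it.
7. **Chemical space** (`descriptor_matrix`, `standardize_columns`,
   `classical_mds`). Compounds are described by 1024 fingerprint bits plus
   MW, TPSA and SlogP (1027 columns), standardized jointly across all
   compound groups, embedded by classical multidimensional scaling of the
   Euclidean distance matrix.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| pChEMBL threshold | 5.5 | -log10 molar | positivity of Ki/IC50/EC50/Kd records (strict) |
| inhibition threshold | 20 | percent | positivity of inhibition records (strict) |
| potency threshold | 500 | micromolar | positivity of potency records (strict, below) |
| probability threshold | 0.5 | — | interaction call on P (inclusive) |
| Tc threshold | 0.85 | — | similarity (inclusive) |
| MW window | 50 | g/mol | similarity (strict) |
| PPI score threshold | 400 | — | neighbor expansion (strict, above) |
| alpha | 0.05 | — | Bonferroni-adjusted significance (inclusive) |
| highlight threshold | 20 | plants | pathway highlighting (strict, above) |

Boundary semantics are deliberate and tested: measurement values exactly at
a threshold are negative evidence, a 50-50 evidence split *is* an
interaction, Tc exactly 0.85 matches while a MW difference of exactly 50
does not, and a PPI score of exactly 400 is excluded.

## The synthetic study and its planted truth

No public dataset couples plant composition, bioactivity, protein space
and a tissue metabolic network, so `generate_dataset()` produces the whole
study with planted ground truth:

* **Plants and compounds.** Plants-per-compound counts follow a truncated
  power law P(k) proportional to k^-2 (k = 1..n_plants), so the majority
  of compounds are plant-specific while a small group occurs in many
  plants — the qualitative sharing pattern seen in curated plant-compound
  catalogs. Descriptors are drawn from ranges typical of natural products
  (log-normal MW around 350 g/mol, truncated-normal TPSA, normal SlogP);
  fingerprints are random sparse bit sets. No valence-correct chemistry is
  attempted; the pipeline accepts precomputed descriptors by design.
* **Planted co-targeting structure.** Each of three protein clusters
  (7 proteins, drawn from the seed-union and wired neighbors so they
  survive target-space assembly and are forced expression-positive) is
  paired with a disjoint group of 20 plants; three *marker* compounds per
  group occur in exactly the group's plants and are planted to interact
  with every cluster protein.
* **Bioactivity noise.** Each assayed pair receives 2-4 records; planted
  pairs have 85 percent per-record positive mass, decoy pairs 10 percent.
  Under the P >= 0.5 rule this yields planted-pair recall around 0.96 and
  decoy acceptance around 0.09-0.13. An additional 250 *background* planted
  pairs on non-cluster proteins give the recall estimate a sample of well
  over 200 pairs without diluting the planted phi structure; 25 *analog*
  compounds (fingerprint perturbed within the Tc >= 0.85 guarantee, MW
  within 20 g/mol, no evidence of their own) exercise the similarity route.
* **Metabolic toy network.** 120 reactions over 90 metabolites in 8
  pathways; 40 percent of metabolites share an InChIKey with some compound
  and a handful are near-duplicates without key identity, so both match
  routes occur.

### Why 80 plants and groups of 20

A planted intra-cluster protein pair stays significant only while its phi
survives contamination: an accepted decoy record on a compound shared by
many plants adds all those plants to one protein's column. With n plants,
group size g and c contaminating plants, phi falls to
sqrt(g(n - g - c) / ((n - g)(g + c))); at n = 80, g = 20 the
Bonferroni cutoff (|phi| around 0.47) tolerates c up to roughly 28 plants,
and compounds shared that widely are rare under the power law. With
7-protein clusters a single contaminated protein costs at most 6 of 63
intra-cluster pairs, inside the 90 percent recovery the test suite
demands. Smaller studies (30-40 plants, groups of 8-10) are measurably
fragile: one promiscuous false-positive compound can erase a cluster.

### What passing tests do and do not show

The generator emulates the *decision structure* of the analysis — threshold
boundaries, evidence aggregation, planted correlation — not real chemistry
or biology: fingerprints are random rather than structure-derived,
bioactivity noise is stipulated (no public error statistics exist for such
databases), compound-plant assignment is independent of chemistry, and the
PPI graph is a random backbone. Recovery of planted structure therefore
validates the statistical machinery and its calibration, not the biological
claims any specific real dataset would support.

## Numerical choices and degenerate inputs

* Standardization uses the sample (n-1) standard deviation; constant
  descriptor columns become all zeros rather than being dropped, keeping
  the 1027-column contract.
* Classical MDS truncates negative eigenvalues to zero; if fewer positive
  dimensions exist than requested, coordinates are zero-padded with a
  warning. An all-zero distance matrix embeds at the origin.
* Phi with any zero marginal is undefined (`NA`); such pairs are skipped
  and excluded from the Bonferroni multiplier. An all-zero table is an
  error.
* Report rounding of efficacy is half-away-from-zero at 2 decimals, as in
  printed tables; full precision is always carried alongside.
* Ranking ties (top-targeted proteins) break lexicographically by protein
  id for determinism.
* Duplicate undirected PPI rows keep the maximum score; self-edges are
  dropped; edges lacking an organism label are treated as allowed, with a
  warning.
* Inhibition values outside [0, 100] are clamped with a warning; negative
  potencies are dropped.
* All generator randomness flows from one seed through R's default RNG
  stream; a fixed seed reproduces every table byte-identically.

## Problem sizes

The default synthetic study (80 plants, 1,200 compounds, ~65 proteins,
~1,900 bioactivity records) runs end to end in a few seconds; the chemical
space embedding caps its input at 500 compounds by default
(`max_mds_compounds`), which is ample for a 2-D overview and keeps the
distance matrix small. Unit tests use a reduced study (20 plants, 250
compounds, 256-bit fingerprints) where statistical recovery is not the
property under test.

## Known limitations

* The interaction probability is a plain positive-evidence frequency; it
  ignores assay quality, measurement magnitude beyond the threshold, and
  correlation between repeated assays.
* The weighted efficacy is proportional to the per-plant compound-count
  sum scaled by the maximum; other normalizations (e.g. per-protein
  weighting) are plausible and would reorder plants with similar scores.
* The similarity route inherits *all* interacting targets of the matched
  compound; activity cliffs (small structural changes with large activity
  changes) are not modeled.
* Identifier harmonization (gene vs protein namespaces) is assumed done
  upstream; the package matches ids as opaque strings.
* Reaction reversibility is not resolved; the substrate rule is applied to
  the substrate list as given.
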