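---
title: "Methods: evidence-graded target-network comparison of natural products and cancer drugs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evidence-graded target-network comparison of natural products and cancer drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Natural products (NPs) — isolated compounds from plants and fungi with a
history of medicinal use — engage a molecular target space that only partly
overlaps the space reachable with FDA-approved antineoplastic drugs (the CT
class, after the Cancer Targetome's evidence-graded drug-target catalog).
Quantifying how much *additional* therapeutically relevant space NPs open
up, and where it sits relative to cancer driver genes, pathways, and
interaction networks, is the question this package operationalizes. The
package implements the full analysis as composable, tested operations:
compound identity resolution, evidence grading, coverage classification,
driver-gene enrichment, PPI topology comparison, pathway crosstalk, and
compound community detection, plus a seeded synthetic generator that stands
in for the seven public source databases so every stage is runnable and
verifiable offline.

## Evidence model

Every database entry supporting a compound-target pair is one evidence
item, graded into three tiers:

* **Level I** — a database entry only: no accessible literature reference
  and no (referenced) binding value. A binding value *without* a reference
  also grades I; accessibility of the supporting evidence is the criterion.
* **Level II** — a literature reference but no binding affinity value.
* **Level III** — both an experimental binding value (IC50, EC50, Ki or KD,
  in nM) and a literature reference.

A pair's level is the maximum over its items, and a target's level the
maximum over its pairs (optionally per compound class). This "max" rule is
monotone: adding evidence can only raise a grade, a property the test suite
asserts over random evidence subsets.

Affinity filtering keeps pairs whose *best exact* value — the minimum over
exact-relation assay values, i.e. the most potent qualifying assay — is
strictly below a threshold. Two thresholds matter: < 1,000 nM and < 100 nM,
the latter treated as clinically relevant strong binding. Two declared
decisions: relation-qualified bounds ("< 100", "> 10") never qualify, since
a bound is not an exact measurement; and all inputs must already be in nM —
the loader rejects any other unit rather than attempt conversion, because
unit normalization across heterogeneous sources is a curation task, not an
arithmetic one.

## Compound identity

Source records carry up to five keys: chemical name, SMILES, InChIKey,
PubChem CID, CAS number. Records merge iff connected under the transitive
closure of "share at least one exactly matching key"; names are compared
case-insensitively after trimming and collapsing whitespace, all other keys
verbatim. There is no synonym expansion and no SMILES canonicalization —
both would make merges depend on external chemistry toolkits and curated
thesauri, whereas the exact-key rule is deterministic and auditable. Key
fields that end up multi-valued after a merge are kept (pipe-delimited) and
flagged in a conflict report rather than treated as fatal; source data
quality problems are expected and should surface, not crash. When records
of both classes merge, the compound is classed CT: a drug identity
dominates, which is also why NP-side scrubbing against drug exclusion lists
exists at all. Scrubbing removes NP compounds matching an exclusion keyset
on any key under the same matching rules; CT compounds are never removed.

## Coverage classification and its arithmetic

An entity (target, pathway, PPI node) is classified NP_ONLY / CT_ONLY /
BOTH / NEITHER by whether its gene set intersects the NP and CT hit sets at
the working stratum. Note the deliberate reading of BOTH for pathways: the
pathway must intersect *both* hit sets, but no single target needs to be
hit by both classes — pathway-level overlap with little target-level
overlap is precisely one of the analysis's observations, and the stricter
reading would change every count.

The headline statistic is the relative coverage increase
`100 * NP_only / (CT_only + Both)`: how much the NP-only entities grow the
drug-covered set. Tables print percentages of the pathway universe at two
decimals; headline increases round to the nearest integer. The acceptance
script re-derives all six published increase figures (61, 29, 12, 6, 65,
60 percent) from the printed table counts through this one operation.

Per-compound promiscuity distributions (targets, pathways, tumor types,
drivers per compound; at both thresholds) are compared NP vs CT with the
asymptotic two-sided two-sample Kolmogorov-Smirnov test, flagged at the
Bonferroni-adjusted threshold 0.004. Compounds with zero qualifying
interactions are excluded by default (configurable): a compound absent at a
stratum carries no information about promiscuity there.

## Driver enrichment

Driver-enriched ("pan-cancer aberrational") pathways are found with a
hypergeometric upper-tail test, `P(X >= k)` inclusive, per pathway, with
Benjamini-Yekutieli FDR control across pathways. BY rather than
Benjamini-Hochberg because overlapping pathways make the tests dependent,
and BY is valid under arbitrary dependence. Declared choices where the
method leaves room: the gene universe is the union of genes over supplied
pathways (configurable to an explicit universe); alpha = 0.05; drivers
absent from the universe are dropped from K with a reported count so the
contingency table stays coherent.

Opportunity pathways are the actionable product: enriched pathways with no
CT target at < 100 nM but at least one NP target at < 100 nM, each flagged
for whether the NP engages a driver gene directly or a non-driver pathway
member.

## PPI topology

Targets are projected onto an undirected simple PPI network (self-loops and
duplicate edges dropped with reported counts). Per node: degree;
unnormalized exact betweenness (each unordered pair counted once,
fractional credit across tied shortest paths — unnormalized because raw
pair counts are what the published magnitudes reflect); eigenvector
centrality computed by power iteration on the shifted adjacency A + I
(identical eigenvectors to A; the shift guarantees convergence on
bipartite-like structures) from an all-ones start to 1e-10 infinity-norm
tolerance, max-normalized, with a hard error after 1000 iterations rather
than a silent partial result; and mean shortest distance to drivers,
excluding self for driver nodes and undefined when no driver is reachable
(per-node means, then group means). On disconnected graphs eigenvector
scores outside the dominant component decay toward zero — documented,
matching common library behavior.

Groups are compared with two-sided Mann-Whitney U tests (centrality
distributions are heavy-tailed; a location-shift t-test would be
inappropriate), and distance-to-driver group means additionally against
1000 size-matched uniformly random node sets without degree matching, with
the add-one empirical p `(1 + #{controls <= observed}) / (n + 1)`.

## Pathway crosstalk and compound communities

The crosstalk network has entity-level (leaf) pathways as nodes and an edge
wherever two pathways share at least one gene, weighted by the shared-gene
count. Distances are hop counts on the unweighted graph — the shared-gene
variant of the pathway-interaction model this follows makes no use of
weighted paths — and cross-component pairs are excluded with a reported
count rather than assigned infinity, keeping means finite and auditable.
Synergy candidates are edges pairing an NP_ONLY pathway with a
driver-enriched pathway labeled CT_ONLY or BOTH. One caution the test suite
encodes: the candidate count is *not* monotone in the affinity threshold,
because tightening the threshold can relabel a BOTH pathway as NP_ONLY and
thereby create candidates; the tests assert the sound containment
properties instead.

The compound network connects compounds sharing at least one sub-100-nM
target, weighted by the shared-target count. Communities come from
multilevel (Louvain) modularity optimization on the weighted graph at
resolution 1.0 — greedy, appropriate for disconnected networks. The
algorithm is visit-order sensitive, so the seed is fixed and recorded;
identical graph + seed reproduce the partition bit-for-bit. Community
class composition is tested per community with a two-sided Fisher exact
test (community x class against the rest of the graph; exact because
community counts are small), and community targets are tallied by protein
family from the input family table, with unannotated targets under
"unclassified".

## The synthetic scenario generator

The generator emulates the *statistical shape* of the real inputs, not
their content: multi-source evidence multiplicity (1..7 items per pair);
an NP-heavy Level-I vs CT-heavy Level-III evidence mixture via
class-specific reference/value probabilities (defaults 0.2/0.35 for NP,
0.95/0.9 for CT, with CT values always referenced — reproducing the
qualitative contrast that most NP support is bare database entries while
drug catalogs are assay-backed); log10-normal binding values (mean 2.2,
sd 1.3 decades, ~160 nM center — a free parameter documented as such, since
no empirical affinity distribution is reported for these sources);
family-biased target sampling (within-family odds x8) so compounds cluster
around protein families; driver-dense planted pathways (75% driver members
against a 10% scenario-wide driver fraction); planted opportunity pathways
(CT exact values on their genes pushed above 100 nM, one guaranteed NP hit
below); a pathway forest whose leaves are entity-level; a PPI with
within-pathway edge enrichment and +15 extra edges per driver node so the
published driver-topology contrast is recoverable; and three NP compounds
planted on the drug exclusion list.

Default scale — 150 NP + 50 CT compounds, 500 targets, 60 pathways, 20
tumor types — is the study condition used by the recovery tests and
analysis scripts throughout; it is large enough for the enrichment,
topology and community signals to be unambiguous while keeping the full
test suite fast. What passing recovery tests on these scenarios shows is
that the *operations* recover known planted structure; it does not validate
the 2017 database snapshots' absolute counts, which depend on curation
decisions and source coverage the generator does not model (text-mining
noise, synonym ambiguity beyond the exclusion-list planting, real SMILES
chemistry, inter-database correlation of evidence).

## Numerical and degenerate-input conventions

* Level ranks compare as I < II < III; ties in top-node rankings break
  lexicographically by node id.
* `relative_increase` errors explicitly on a zero denominator rather than
  returning Inf.
* Empty pathway membership classifies as NEITHER with a warning; empty
  edge-list files load as empty graphs with a warning; malformed rows are
  hard errors with line numbers.
* Group comparisons skip groups under 3 members with a warning.
* All TSV output is UTF-8, LF-terminated, NA-as-empty, so identical
  config + seed reruns produce byte-identical bundles (the determinism
  contract the pipeline tests enforce).

## Known limitations

* Exact-key identity merging under-merges relative to curated synonym
  matching; the conflict report is the audit trail, not a resolution.
* The Fisher/Mann-Whitney/KS choices are the package's declared defaults
  where the method description leaves the test unstated.
* The hypergeometric universe default (union of pathway genes) shrinks N
  relative to a whole-genome universe and is therefore conservative about
  enrichment; supply an explicit universe to change this.
* Scenario realism is structural, not chemical: SMILES are placeholder
  tokens, and no attempt is made to simulate assay-level noise or
  inter-source disagreement in binding values.
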