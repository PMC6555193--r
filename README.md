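# npnet

Evidence-graded target-network analysis comparing natural products (NPs —
isolated plant and fungal compounds with a history of medicinal use) with
FDA-approved antineoplastic drugs (the CT class). The package quantifies
how much additional cancer-relevant target space NPs open up, and where
that space sits relative to cancer driver genes, molecular pathways, and
interaction networks. It is aimed at computational pharmacologists and
systems biologists assessing NP/drug combination potential.

## What it computes

* **Compound catalog** — merges compound records from multiple source
  databases into unique compounds via the transitive closure of exact
  matches on five keys (name, SMILES, InChIKey, PubChem CID, CAS), and
  scrubs NPs matching drug exclusion lists.
* **Evidence model** — grades each interaction-evidence item into Level I
  (database entry only), II (+ literature reference), III (+ experimental
  binding value); aggregates per pair by the max rule with
  `best_exact_value_nM = min` over exact-relation assays (IC50/EC50/Ki/KD);
  filters at < 100 nM / < 1,000 nM, exact values only.
* **Coverage** — classifies targets, pathways, drivers, and tumor types as
  NP_ONLY / CT_ONLY / BOTH / NEITHER per evidence/affinity stratum, and
  reports the relative coverage increase
  `100 · NP_only / (CT_only + Both)`; compares per-compound promiscuity
  distributions (two-sample Kolmogorov–Smirnov, Bonferroni threshold
  0.004).
* **Driver enrichment** — hypergeometric upper-tail test `P(X ≥ k)` per
  pathway against the driver-gene set with Benjamini–Yekutieli FDR control;
  enumerates NP-only *opportunity pathways* (driver-enriched, no CT target
  < 100 nM, ≥ 1 NP target < 100 nM).
* **PPI topology** — degree, unnormalized betweenness, power-iteration
  eigenvector centrality, and mean shortest distance to drivers, compared
  across coverage groups (Mann–Whitney U) and against size-matched random
  node sets.
* **Pathway crosstalk** — shared-gene pathway–pathway network over
  entity-level pathways; set-to-set hop distances with random controls;
  neighboring-pathway synergy candidates.
* **Compound communities** — shared-target compound network at < 100 nM,
  weighted multilevel (Louvain) community detection, per-community class
  enrichment (Fisher exact) and protein-family profiles.
* **Synthetic scenarios** — a seeded generator emulating the statistical
  structure of the seven public source databases, with planted ground
  truth (enriched pathways, opportunity pathways, compound families,
  high-degree drivers) for recovery testing.

## Worked example

Generate a scenario and run the analysis steps (each step is a thin driver
over package functions and writes its tables under `results/`):

```sh
Rscript analysis/01_generate_scenario.R
Rscript analysis/02_integrate_catalog.R
Rscript analysis/03_evidence_coverage.R
Rscript analysis/04_driver_enrichment.R
```

which prints, for the default seeded scenario:

```
306 source records -> 200 unique compounds (150 NP, 50 CT)
0 key conflicts flagged; 3 NP compounds scrubbed as drugs
evidence mixture: 65% of NP interactions are Level I; 96% of CT are Level III
  Evidence levels I, II, III           NP-only pathways   1 ( 1.67%), relative increase 2%
  ...
  Evidence level III, binding LT100    NP-only pathways   7 (11.67%), relative increase 13%
10 of 20 tumor types gain driver coverage from NPs alone at <100 nM
6 of 60 pathways driver-enriched at BY q < 0.05
planted enriched pathways recovered: 6 of 6
5 NP-only opportunity pathways (5 with the NP target itself a driver)
```

Read: the 306 multi-source compound records resolve to exactly the 200
planted compounds; the evidence mixture shows the expected NP-Level-I /
CT-Level-III contrast; at the strong-binding stratum NPs alone cover 7
additional pathways (a 13% relative increase over drug-covered pathways);
all 6 planted driver-enriched pathways are recovered by the
hypergeometric/BY screen, and the 3 planted opportunity pathways are among
the 5 returned. Steps 05–07 continue with PPI topology, pathway crosstalk,
and compound communities. The same flow is available programmatically:

```r
library(npnet)
truth <- generate_scenario(scenario_config(seed = 1), "scenario")
res <- run_pipeline(list(scenario_dir = "scenario", out_dir = "out", seed = 1))
res$coverage          # stratified coverage table
res$opportunity       # NP-only opportunity pathways
res$partition         # compound communities
```

Identical config + seed reproduce a byte-identical report bundle.

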