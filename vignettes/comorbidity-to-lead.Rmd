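---
title: "From comorbidity gene panels to ADME-optimized dual-kinase leads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From comorbidity gene panels to ADME-optimized dual-kinase leads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comolead)
```

## The workflow

`comolead` implements a desk-scale, top-down drug-discovery workflow for
multimorbid diseases, built around obstructive sleep apnea (OSA) and its
comorbidities as the motivating system. Instead of starting from omics hit
lists, the pipeline starts from gene panels of clinically established
comorbidities and works backward to a small, phenotype-anchored target set,
then forward again through network analysis, scaffold design and ADME-guided
lead selection:

1. **Gene-set refinement** — comorbidity panels are pooled, intersected with
   the disease gene set, and a refined set with per-gene provenance is built.
2. **Network modules** — a protein-association graph over the refined set is
   summarized (degree, local clustering), mined for dense modules with MCODE,
   and related to co-expression structure and annotation enrichment.
3. **Scaffold hybridization** — parent inhibitor scaffolds are merged at
   detected connection ports, directly or through small linkers, under
   valence control.
4. **Docking-table analytics** — externally produced docking scores
   (AutoDock Vina convention: kcal/mol, more negative is stronger) are
   ingested and compared: best binders, improvement deltas, dual-target
   balance. Docking itself is never run here.
5. **ADME profiling and lead selection** — a local rule engine evaluates the
   five drug-likeness filters, ESOL solubility, the Abbott bioavailability
   score and structural alerts, classifies liabilities, bands binding
   retention, and ranks candidates by a weighted composite score.

Every input class has a generator in the synthetic-data module, so the whole
pipeline runs and is tested offline.

## Gene-set refinement

Panels are sets of case-normalized symbols. `aggregate_pool()` unions them
and reports per-panel unique contributions (panels adding nothing are
flagged, mirroring the exclusion of non-contributing comorbidities).
`refine_set()` forms `(disease ∩ pool) ∪ retained-unique`. The retained
disease-unique genes are an explicit argument rather than a computed
quantity: in the source data the retained subset (8 of 44 disease-unique
genes) reflects an upstream curation filter that is not derivable from the
counts, so the package refuses to guess it. The packaged study conditions —
thirteen panels sized 76, 43, 164, 101, 232, 471, 593, 607, 319, 113, 120,
100 and 95, a 2460-gene deduplicated pool, a 102-gene disease set, an
overlap of 58 and 8 retained unique genes — give a refined set of 66:

```{r refine}
u <- make_gene_universe(study_overlap_spec(seed = 1))
pool <- aggregate_pool(u$panels)$pool
refine_set(pool, u$osa_set,
           unique_retained = u$truth$gene[u$truth$role == "osa_unique_retained"])
```

The generator treats the 2460 figure as a post-deduplication count: the
panel sizes sum to 3034, so panels share genes; each pool gene is dealt one
mandatory panel slot and the remaining slots are filled without
within-panel duplication. The overlap is drawn uniformly from the pool, so
provenance ground truth is exact by construction.

## Network statistics and MCODE

`graph_stats()` reports `2E/N` average degree and the mean local clustering
coefficient with degree-&lt;2 nodes contributing zero (kept in the mean, the
common "average local clustering" convention; the reference network of 66
nodes and 171 edges has average degree 5.18). `mcode()` implements the
molecular-complex-detection algorithm: vertex weights are the highest
k-core of each node's closed neighborhood times that core's density;
complexes grow greedily from the heaviest unassigned seed, admitting
neighbors within `1 - node_score_cutoff` of the seed weight; complexes
lacking a 2-core are dropped and singly-connected members shaved (haircut
on, fluff off — the published defaults, with degree cutoff 2 and node score
cutoff 0.2). Ties in seed choice and ranking break lexicographically so the
output is deterministic.

```{r mcode}
g <- make_modular_graph(planted_graph_spec(3, 5, p_in = 1, p_out = 0, seed = 2))
lapply(mcode(g), `[[`, "nodes")
```

On planted-partition graphs with `p_in = 1, p_out = 0` recovery is exact;
the test suite also checks the top module against brute-force
densest-subgraph enumeration on graphs of up to 13 nodes. The reference
network's printed clustering coefficient (0.505) depends on the unpublished
edge list and is deliberately not asserted anywhere.

Co-expression partners use the Pearson coefficient with the t-transform
p-value (`|r| > 0.5`, `p < 0.01` defaults); `enrichment()` uses the
hypergeometric upper tail `P(X >= k)` (overlap 0 gives p = 1) with
Benjamini-Hochberg correction across terms.

## The synthetic-data generators

The generators define the study conditions rather than adapting to tests:

* `make_gene_universe()` — exact overlap structure as above; symbols are
  role-coded (`CMG`/`OSG`) so provenance is auditable.
* `make_modular_graph()` — a stochastic block model with constant
  within/between probabilities; the planted assignment ships as a vertex
  attribute.
* `make_expression_matrix()` — a single-common-factor model,
  `x = sqrt(rho) f_block + sqrt(1 - rho) e`, which gives an analytically
  known expected within-block correlation of `rho` at unit noise; larger
  `noise_sd` attenuates it toward independence.
* `make_alert_compounds()` — toy molecules covering every packaged
  structural alert plus alert-free controls.
* `table1_fixture()` — the packaged 20-row docking-score table.

What the generators do **not** emulate: real gene identities, STRING's
evidence-weighted topology, expression distributions beyond Gaussian
factors, or chemically realistic kinase pharmacophores. Passing tests
demonstrate the correctness of the algorithms under controlled structure,
not the biological conclusions drawn from any particular dataset.

## Molecules, ports and hybridization

Molecules are editable heavy-atom graphs (element, formal charge, aromatic
flag; kekulé bond orders; implicit hydrogens). Parsing, aromaticity
perception, canonical SMILES and 3D building are delegated to Open Babel
through ChemmineOB/ChemmineR; graph editing, valence accounting and port
matching are native. Connection ports name positions where a substituent
can be swapped for an inter-scaffold bond; the packaged library covers
methoxy groups (detach OCH3, attach at the ring carbon), unsubstituted
aromatic C–H positions, carboxyl (acyl) sites and phenolic oxygens. Each
port records a documenting SMARTS pattern, but matching runs on the
package's own graph because the backend's SMARTS search returns match
counts without atom maps, and graph editing needs indices. Overlapping
matches resolve greedily by lowest atom index; only single bonds are formed
at merge time (the conservative chemically-permissible default).

```{r merge}
benz <- mol_from_smiles("c1ccccc1", "benzene")
ports <- find_ports(benz, "aromatic_ch")
merge_scaffolds(benz, ports[[1]], mol_from_smiles("c1ccccc1"), ports[[2]],
                link = "ethylene")
```

Merges conserve heavy atoms (`heavyA + heavyB + linker - detached`) and
formal charge, are valence-checked before re-perception, and must come out
as a single connected component. The published hybrid structures
(ICLID/PFLID/ICL/PFL) were never disclosed, so the package ships no claimed
structures for them; their printed ADME values travel as a literature
fixture instead, and hybridization is demonstrated on public scaffolds.

`embed_3d()` produces all-atom conformers via the backend's builder plus
force-field cleanup. The backend's conformer search draws from a global,
time-seeded random state that cannot be reseeded from R, so the
reproducibility contract (same molecule and seed give identical
coordinates) is honored by per-session memoization; coordinates can differ
between sessions while topology, bond lengths and non-bonded clearance
(checked at &gt; 0.9 Å) do not. This trades cross-session bit-stability,
which the installed backend cannot provide, for an honest, documented
guarantee.

## The ADME rule engine

All bounds live in declarative tables. The five filters use their published
bound sets (Lipinski passing with at most one violation, the others with
none); descriptors missing from a record simply skip their bounds, which
lets literature profiles with partial coverage be screened on what they
report. ESOL is the linear model
`LogS = 0.16 - 0.63 logP - 0.0062 MW + 0.066 RB - 0.74 AP`. Solubility
bands assign boundaries to the less-soluble class (-2 is "soluble", -8 is
"insoluble") because the published banding states strict inequalities only
at the extremes. The Abbott bioavailability score follows the published
decision tree: anions score by TPSA band (0.85 / 0.56 / 0.11), everything
else scores 0.55 when Rule-of-Five compliant and 0.17 otherwise. With one
packaged logP estimator (atom-contribution), the consensus equals that
estimator; the "any single method above 6.0" liability check runs over all
supplied estimates, so fixture records carrying a second literature value
are screened against both.

The liability classifier checks: consensus logP above 4.5 or any estimator
above 6.0; LogS below -7; molecular weight above 500 (or 600) Da;
bioavailability score below 0.3 or predicted low GI absorption; any
structural alert; and failure of two or more drug-likeness rules. Fired
categories are ranked by a configurable severity order. CYP flags and GI
absorption are fixture inputs, not predictions — those come from trained
external models that are out of scope here.

```{r liabilities}
profs <- read_adme_fixture()
identify_liabilities(profs$PFLID)
```

## Retention, improvement and the composite score

`classify_retention()` bands a binding-energy change at 1.0 and
2.0 kcal/mol (retained / moderately / substantially reduced) and converts it
to an implied Ki fold-change via `exp(delta / RT)` with RT = 0.5925 kcal/mol
(298.15 K). The verbal five-fold / twenty-five-fold glosses that accompany
those thresholds correspond to exp(1.0/RT) = 5.4 and exp(2.0/RT) = 29.3;
the computed fold is reported rather than forced to the gloss.
`adme_deltas()` signs every delta so that positive means improvement, and
`variant_success()` fires on any of: 30% relative logP improvement, one or
more log-unit solubility gain (inclusive), Lipinski compliance, or a
two-fold bioavailability ratio. `lead_designation()` requires retained
binding on both targets plus the 30% condition, which defaults to the
relative-logP clause — the only criterion stated as a percentage.

The composite lead score weights ADME 0.40, binding 0.40, synthetic
accessibility 0.10 and strategic balance 0.10. The component definitions
are a declared design choice (the source names the components and weights
but no formulas): the ADME sub-score averages a Lipinski indicator,
bioavailability relative to 0.55 (capped), a rescaled solubility band and
an alert-free indicator; the binding sub-score averages
`clamp(1 - max(delta, 0)/2, 0, 1)` over the two targets; synthetic
accessibility scores 1 up to 4.5 then decays linearly to 0 at 10; and
"strategic balance", which has no published definition, is the explicit
stand-in `1 - |adme_sub - binding_sub|`. All four plug in through
`rank_leads()`, so alternative constructions are drop-in replacements.

```{r rank}
t1 <- table1_fixture()
cand <- list(
  ICL = list(profile = profs$ICL,
             delta_ck1d = -improvement(t1, "ICL", "ICLID", "CK1D")$delta,
             delta_pink1 = -improvement(t1, "ICL", "ICLID", "PINK1")$delta),
  PFL = list(profile = profs$PFL,
             delta_ck1d = -improvement(t1, "PFL", "PFLID", "CK1D")$delta,
             delta_pink1 = -improvement(t1, "PFL", "PFLID", "PINK1")$delta))
rank_leads(cand)
```

## Numerical and design notes

* Problem sizes in the test suite (blocks of 3-6 genes, 200-sample
  expression matrices, 1000-gene null panels, graphs of 15-24 nodes,
  100-merge sweeps) were chosen as the smallest sizes at which each
  statistical check is decisive; all generators scale up by spec.
* Random draws always flow through a seeded spec (`withr::with_seed`), so
  every generator is a pure function of its spec.
* Hypergeometric p-values use the upper tail with `p = 1` at zero overlap;
  BH correction can leave `fdr` equal to `p`.
* Gene symbols upper-case and strip whitespace on ingestion; mixed-case
  duplicates are the dominant real-world collision mode.
* Edge-list ingestion accepts 2- or 3-column TSV; a numeric third column is
  a confidence filtered at 0.4 by default (the usual medium-confidence
  export threshold).
* The docking fixture keeps one decimal at reporting (`delta_reported`)
  while internal arithmetic is unrounded.
* Known limitations: no generic SMARTS engine (ports are a fixed library
  with a documented extension point); one logP estimator; no trained
  CYP/BBB/P-gp models; no stereochemistry handling in merges; MCODE fluff
  expansion not implemented (off in the published defaults).
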