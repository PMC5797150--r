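---
title: "Mining the polyphenol-protein interactome: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining the polyphenol-protein interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`polyphenome` implements a desk-scale pipeline for profiling the protein
interactions of dietary polyphenols: a substructure taxonomy classifies
small molecules into polyphenol classes, a deterministic standardization
scheme makes structures comparable across sources, interaction tables from
three database dialects are filtered by evidence quality and merged into a
bipartite compound-protein network, interacting-protein sets are tested for
pathway over-representation, and the same machinery is applied to whole
foods (the citrus-fruit motif). Because the original data sources are
proprietary or versioned web resources, the package ships seeded generators
that emulate each input with planted ground truth; every stage can be
validated against that ledger without any download.

# The chemical taxonomy

Polyphenols are defined operationally: a compound is a polyphenol when it
carries at least one of 43 substructure scaffolds. Each scaffold maps to one
or more of 31 subclasses (flavonols, hydroxycinnamic acids, lignans,
tyrosols, ...) which roll up to 5 queryable classes — flavonoids, phenolic
acids, lignans, stilbenes, other polyphenols. A declared sixth class,
non-phenolic metabolites of polyphenols, has no fixed structural feature and
is therefore not queryable; `polyphenol_classes()` records it as such.

The scaffolds are shipped as SMARTS expressions in an editable TSV
(`system.file("extdata", "polyphenol_patterns.tsv", package =
"polyphenome")`). Design decisions:

* **Permissive cores.** Published subclass definitions fix the scaffold, not
  the substitution pattern, so patterns are written as open cores: a ring
  `O` in a pattern matches hydroxy, methoxy and glycosyloxy substituents
  alike. Esterified acids (e.g. acetylsalicylic acid, chlorogenic-type
  esters) still count as their parent acid subclass.
* **Multi-label by construction.** A catechol-bearing flavonol legitimately
  carries both the flavonol and the catechol label; classification is a set,
  never a single class, and some patterns name two subclasses at once
  (flavones/flavonols share the 2-phenylchromen-4-one core; flavanones and
  dihydroflavonols share the chroman-4-one core). Positional variants
  (ortho/meta/para) of the phenolic acids are separate patterns mapping to
  one subclass.
* **Guard atoms where leakage was observed.** The carboxyl carbon of the
  acid patterns is required to be acyclic (`[CX3;R0]`), otherwise
  dibenzylbutyrolactone lignans match as phenylpropanoic acids; the chalcone
  and dihydrochalcone carbonyls are likewise acyclic so that flavanones do
  not match as their open-chain isomers; the flavanol C4 must be CH2 so
  dihydroflavonols stay distinct.
* **Subclass naming.** Names follow the common two-level food-polyphenol
  taxonomy. The residual subclass is split into `catechols` (benzene-1,2-
  diol cores) and `other polyphenols` (phloroglucinol-type cores), which
  makes the shipped library exactly 31 subclasses across the 43 patterns.

## Exclusion rules

Before matching, a standardized structure is removed when

1. its average molecular mass exceeds 1200 Da (strictly greater),
2. it contains any nitrogen atom, or
3. it matches the steroid scaffold,

checked in that order with the first hit winning; the order is a convention
fixed for reproducibility. The steroid scaffold is the gonane
(cyclopenta[a]phenanthrene) tetracycle written with any-order ring bonds so
saturated, Δ5-unsaturated and A-ring-aromatic steroids (cholesterol,
testosterone, estradiol) all match; the expression was cross-checked
against an independent cheminformatics toolkit on steroid and non-steroid
exemplars before being frozen. Excluded compounds never carry class labels.

# Structure standardization

`standardize()` applies, in order: (i) fragment removal, (ii) charge
neutralization, (iii) explicit-hydrogen suppression, (iv) tautomer
normalization, (v) aromatization, and then emits a unique canonical SMILES.
OpenBabel (via ChemmineOB) is the single chemistry engine, so one
aromaticity model and one canonical serialization hold throughout.

* *Fragment removal* keeps the largest fragment by heavy-atom count; ties
  break by average mass, then lexicographically smallest canonical SMILES —
  a total order, so the step is deterministic.
* *Neutralization* uses OpenBabel's +1/-1 charge transform (carboxylates,
  phenolates, ammonium-type centres).
* *Tautomer normalization* is a deliberately small, deterministic rule: an
  acyclic enol (hydroxyl on a non-ring C=C, gated by the SMARTS
  `[OX2H][CX3;R0]=[CX3;R0]`) is rewritten to its keto form by editing the
  mol-block bond orders, lowest atom index first, iterated to a fixed
  point. Aromatic systems are untouchable by construction — phenols are
  never "ketonized" — and ring tautomers are out of scope. This covers the
  one tautomer family that matters for the shipped scaffolds (curcuminoids
  drawn as enols reach the diketone core pattern) while keeping the
  procedure auditable. An InChI round-trip was evaluated as an alternative
  canonical-tautomer device and rejected: in this toolchain it drops stereo
  descriptors and does not actually collapse keto/enol pairs.
* *Canonical keys.* `canonical_key(x, strict_stereo = TRUE)` keeps stereo
  descriptors; `FALSE` strips them before canonicalization. List matching
  (`match_lists()`) pairs entries with equal keys; under strict stereo an
  entry with unspecified stereocentres does not match a specified one — the
  conservative reading that avoids wrong identifier assignments at the cost
  of missing some true matches. Duplicate keys within one list are reported
  and the first occurrence used.

Idempotence (`standardize(standardize(x)) == standardize(x)`) and
atom-order invariance are asserted at scale in the test suite (500
generated compounds, each also re-serialized under a random atom
permutation).

# The interactome layer

Three input dialects are supported: a STITCH-like TSV carrying per-channel
evidence scores (experimental, database, prediction, textmining) as raw
integers 0-999 that are scaled by 1/1000, a Pathway-Commons-like SIF triple
file, and a BindingDB-like affinity TSV. Only the STITCH-like dialect is
scored, so the confidence filter applies to it alone:

* a record supported **solely by text mining** (textmining > 0, all other
  channels 0) is removed regardless of its combined score — the two
  exclusions are independent;
* a record with combined score **< 0.9** (strictly) is removed; the looser
  0.7 setting used for micronutrient-style queries is the same code path
  with a different `min_score`.

BindingDB-like records are direct binding by definition and are not
affinity-filtered by default; an optional ceiling (`max_affinity_nM`) is
exposed but off. Protein identifiers are uppercased into one gene-symbol
namespace (an optional two-column mapping handles other namespaces).

Merging deduplicates (compound, protein) pairs, each edge keeping the set
of supporting sources; `source_overlap()` partitions the node sets by exact
source combination, and `degree_histogram()` bins node degrees with the
conventional schemes (compounds: <=10 up to >2000; proteins: 1 up to >70).
A value shared by two printed bins goes to the higher bin — a protein with
exactly 50 partners counts in 50-70 — except where a label is explicitly
closed ("<=10") or explicitly open (">70").

# Over-representation analysis

For a query set of n proteins in a universe of N, a pathway with K members
and k query hits is scored with the exact upper-tail hypergeometric
probability

P[X >= k] = sum_{i=k..min(K,n)} C(K,i) C(N-K, n-i) / C(N,n),

computed from log-binomial coefficients (no normal approximation; verified
against exhaustive enumeration for every feasible configuration with
N <= 12, and against the distribution functions in base R at larger sizes).
Per query, all tested pathways form one Benjamini-Hochberg family
(`bh_adjust()` wraps the standard step-up; a brute-force implementation of
the definition is the test oracle). A pathway is significant when

* BH-adjusted p < alpha (default 0.1), **and**
* coverage k/K > `min_coverage` (default 0.1 class-level, 0.2 food-level),

both strict. The dual criterion means a tiny pathway cannot become
significant on one or two hits, which is why no minimum gene-set size is
imposed. The universe defaults to the union of all gene-set members;
queries are intersected with it and out-of-universe proteins are dropped
with a logged count. `use_raw_p = TRUE` reproduces the looser raw-p reading
for comparison; the adjusted reading is the default everywhere.

Class-level analysis (`enrich_by_class()`) pools the interactors of all
compounds carrying a class label and tests each class independently —
families are never pooled across classes. `category_summary()` rolls
significant pathways up to their ontology categories and adds a
cardiometabolic super-category (CMD) as the union of the Cardiovascular
Diseases and Endocrine and Metabolic Diseases subcategories.

# Food-level analysis

A food is a binary set of compounds — presence irrespective of
concentration; concentration-weighted or bioavailability-aware modelling is
explicitly out of scope. Composition entries resolve by exact compound id
first, then by strict canonical-key match when the entry parses as a
structure; unresolved names are reported, never silently dropped.
`food_enrichment_network()` runs enrichment **individually per compound**
(never pooled) against the shared universe and draws a compound-pathway
edge only for significant pairs under the stricter food-level coverage
(> 0.2); pathway nodes carry their category and hit proteins are grouped
per category. `compare_foods()` reports exact pairwise Jaccard overlaps of
the composition sets.

# The synthetic study system

The generators in `simulate_all()` emulate the shape of the real inputs,
not their content:

* **Compound library** (default 120 compounds, 75% polyphenols): class
  scaffolds (flavone, flavonol, flavanone, isoflavone, flavanol,
  dihydrochalcone, stilbene, three phenolic-acid series, lignan, tyrosol,
  guaiacol, coumarin) decorated at open ring positions with hydroxy,
  methoxy or glucosyl substituents; decoys cover all three exclusion rules
  (N-heterocycles, steroid cores, >1200 Da chain constructs) plus plain
  non-phenolics that must survive the filters and match nothing. The ledger
  records every intended subclass and exclusion reason; the classifier is
  required to recover subclasses with recall >= 0.95 and exclusion reasons
  exactly.
* **Interaction tables** (default 300 proteins): nodes are partitioned into
  source-combination cells and one filter-surviving anchor edge per node
  and source realizes the planted source-overlap structure exactly; extra
  STITCH-like records carry realistic channel mixtures with scores in
  [0.15, 0.999] and a known fraction of text-mining-only records. One hub
  compound is wired to the entire protein pool (the "prima donna" motif of
  heavily studied compounds), which makes its deduplicated degree strictly
  maximal by construction.
* **Pathway collection** (default 20 pathways, 3 categories): members drawn
  uniformly from the universe except planted pathways, whose members are
  over-sampled from a designated query at a given odds ratio. Because the
  hub's interactors are the whole universe, planted class effects target a
  class the hub does not carry, and the food-level plant anchors on the
  busiest non-hub compound, which is also forced into one food
  (grapefruit).
* **Food table**: six citrus-style foods built from a shared core plus
  private compounds, with two supersets (lemon, lime) realizing the
  "contains almost all polyphenols" motif; pairwise Jaccard overlaps are
  exact by construction.

All generators draw from labelled sub-streams of one master seed
(`derive_seed()`), so adding a generator does not shift the streams of the
others, and identical seeds give byte-identical files.

What the generators do **not** emulate: real chemical diversity beyond the
shipped scaffolds, correlated membership between pathways, annotation noise
or identifier ambiguity, and realistic degree distributions beyond the
single hub. A green suite therefore demonstrates that the machinery is
correct and calibrated on data whose truth is known — not that any
particular biological conclusion transfers to live databases.

# Statistical calibration

Two simulation suites pin the enrichment layer:

* **Power.** A pathway of 100 members over-sampled at odds ratio 5 from a
  50-protein query in a universe of 1,000 must be recovered (BH < 0.1,
  coverage > 0.1, family of 20) in at least 90 of 100 seeded runs. At these
  settings the expected hit count is ~21 (each member lands in the query
  with probability 5*50/(5*50+950) ~ 0.21) against a null expectation of 5,
  giving >95% power; a planted size of 50 would sit at ~80-85% power,
  i.e. right at the criterion's edge, so the planted pathway was sized at
  100 — comfortably inside the 10-300-member range of curated pathway
  collections.
* **False positives.** Under the global null (no planted effect) the
  fraction of 200 families with any significant pathway must stay <= 0.15
  at alpha 0.1; the discreteness of the hypergeometric makes the realized
  rate far lower (~3%).

Problem sizes used elsewhere in the suite: exhaustive hypergeometric
verification for all N <= 12; 1,000 random vectors against the brute-force
BH oracle; 500 compounds for the standardization invariances; pipeline
determinism at 40 compounds x 120 proteins, run twice from one seed and
compared byte-for-byte.

# Known limitations

* The tautomer rule covers acyclic keto-enol only; ring-chain and
  heteroaromatic tautomerism are not normalized, so exotic tautomer pairs
  can yield distinct canonical keys.
* Scaffold substituent tolerance is deliberately permissive; on libraries
  dominated by unusual chemotypes the multi-label smear (e.g. every
  guaiacyl lignan also counting as alkylmethoxyphenol) may be unwanted —
  the pattern TSV is editable precisely for such refinements.
* Strict-stereo matching will miss matches against sources that omit
  stereochemistry; that is the intended conservative trade-off.
* The atom-renumbering utility used by the invariance tests is restricted
  to stereo-free molecules (mol-block parity is numbering-relative).
* Protein identifiers are treated as opaque symbols in one namespace;
  orthology, isoforms and complexes are out of scope.

# Reproducing the full analysis

```{r, eval = FALSE}
# numbered drivers under analysis/ run the whole study on synthetic data
# (seed 42), writing tables under results/:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_classify.R
#   Rscript analysis/03_interactome.R
#   Rscript analysis/04_enrichment.R
#   Rscript analysis/05_food.R
# scripts/acceptance.R recomputes the headline quantities from scratch:
#   Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
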