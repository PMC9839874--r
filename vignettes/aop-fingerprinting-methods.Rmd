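---
title: "Methods: AOP fingerprinting, biomarker prioritization and dose-response validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AOP fingerprinting, biomarker prioritization and dose-response validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aopfinger)
```

`aopfinger` turns a collection of adverse outcome pathways (AOPs) into a
quantitative lens on transcriptomic data. This vignette explains the
models and procedures behind each stage, the parameters that matter, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Text-based annotation of key events

Key events (KEs) carry free-text descriptions; gene-set terms (GO
biological processes, HPO phenotypes, KEGG/Reactome/WikiPathways pathways)
do too. The annotation engine scores each KE/term pair on their token
overlap.

**Preprocessing** applies, in order: lower-casing, punctuation removal,
multiword concept collapse ("positive regulation" becomes the single
token "upregulated"), whitespace tokenization, stop-word removal, and
rule-based rooting (plural `-s`/`-es`, inflections `-ed`/`-ing` with
doubling repair, `-ies` to `-y`) backed by an exception dictionary that
also unifies symbol styles ("pparα", "pparalpha" → "ppar-alpha"). The
stop-word list and concept dictionary ship frozen under
`inst/extdata/` so results are reproducible, and both are user-replaceable
(`load_stopwords()`, `load_concept_dictionary()`). Rooting is
deliberately rule-based rather than a statistical stemmer: every mapping
is auditable, and because both sides of every comparison pass through the
same rules, residual stemming artifacts ("activat") still match each
other. Dictionary replacement tokens are protected from further rooting,
which makes the whole mapping idempotent — a property the test suite
asserts.

**Scoring.** Tokens are weighted by inverse document frequency over the
combined corpus of KE and term descriptions, `idf(t) = ln(N / df(t))`
(natural log; a token present in every document weighs zero). A token
never seen at model-building time is treated as `df = 1`, i.e. maximally
informative. The match score is the IDF-weighted Jaccard index

$$JI_W(A, B) = \frac{\sum_{t \in A \cap B} idf(t)}{\sum_{t \in A \cup B} idf(t)} \in [0, 1],$$

which reduces to the plain Jaccard index when all weights are equal
(property-tested). For each KE the top `k = 5` scoring terms are emitted
as candidates, ties broken by term id for determinism; terms sharing no
token (score 0) are not considered matches. Candidate acceptance is a
human curation step: the package round-trips a status column
(`candidate`/`accepted`/`rejected`/`manual`) and never auto-accepts.

**Gene-set assembly.** A KE's gene set is the union over its accepted
terms' human genes. A term with no human genes falls back to the human
orthologs of its mouse/rat genes (supplied as an explicit two-column
table — gene identity throughout the package is plain uppercase symbols
treated as opaque strings). A KE whose accepted terms all resolve to
nothing is dropped and reported.

## Enrichment and the AOP fingerprint

Enrichment is a one-sided over-representation test: for a query of size
$q$ against a set of size $m$ in a universe of size $N$ with overlap $k$,
$p = P(X \ge k)$ for $X$ hypergeometric$(N, m, q)$, computed via
`stats::phyper` and verified in the tests against exhaustive tail
enumeration for all universes up to 30. Benjamini–Hochberg adjustment is
applied across all sets tested in one call — one family for the AOP-level
pass and one for the KE-level pass; pooling both families into a single
correction would be the other defensible convention, and the per-pass
choice is fixed here and documented. The default
universe is the union of all KE gene sets — the scope of the annotation
itself — overridable per call.

The **fingerprint rule**: an AOP enters an exposure's fingerprint when
the AOP-level set (union of its KEs' genes) is enriched at FDR < 0.05
*and* at least one third of its KEs are enriched — or at least two KEs
when the AOP has fewer than six. KEs carrying identical gene sets are
grouped before testing so the same set is never tested twice; each KE
inherits its group's verdict. "Length of the AOP" counts the AOP's
annotated KEs (a KE without a gene set cannot be enriched either way).
The rule is monotone: flipping any KE group to enriched never turns a
pass into a fail (property-tested exhaustively for lengths up to 10).

**Chemical screening** applies the same test to chemical–gene association
profiles, restricted to chemicals with 50–1000 genes (both bounds
inclusive) to keep the test well-posed, at a stricter FDR < 0.01, and
reports the top five significant AOPs per chemical (fewer if fewer pass),
ranked by FDR, then raw p, then AOP id.

## KE grouping and network merging

KE similarity is the Jaccard index of gene sets. Grouping collapses KEs
with *identical* sets (JI = 1) only; no approximate threshold is offered
because downstream enrichment must never test one set twice. Two
implementations exist and are tested for equality: hashing the sorted
gene sets (default, O(n)), and complete-linkage hierarchical clustering
of the 1 − JI distance cut at height zero — equivalent because set
equality is transitive. Group ids are the lexicographically smallest
member KE id, for stable outputs.

The AOP network has one node per KE and directed edges from the key event
relationships; parallel edges contributed by several AOPs collapse into
one edge listing its supporting AOPs. Merging contracts nodes by group,
unions attributes, drops self-loops and collapses parallels. The
containment report flags every AOP whose merged nodes *and* edges are a
subset of the union of the other AOPs' — pathways made fully redundant by
the merge. Note containment is mutual for exact duplicates: if pathway X
duplicates pathway Y's gene sets node-for-node, both are reported. Graphs
export to GraphML (via igraph) for external layout tools; no layout is
computed in the package.

## Biomarker prioritization

**Robust network.** Protein–protein edges carry a supporting-source
count. Rather than a global cut (which would erase sparsely studied
genes), each node's mean source count over its incident edges defines a
local threshold; an edge survives if its count reaches the mean of at
least one endpoint (inclusive). The comparison is done in integer
arithmetic (`count × degree ≥ sum`), so floating-point ties cannot flip a
verdict. A node's best-supported edge always reaches its own mean, so no
node is isolated (asserted as a property). The directed TF–target network
is *not* filtered — its source coverage is too thin to threshold — and is
used as a second network alongside the robust one.

**Centralities.** Degree (in+out on directed graphs), betweenness,
closeness, eigenvector. Closeness uses the Wasserman–Faust variant for
disconnected graphs: within each node's reachable set, scaled by
(reachable − 1)/(N − 1), keeping values comparable across components.
Eigenvector centrality is a deterministic power iteration (uniform start,
tolerance 1e-10, at most 1000 iterations) on the directed adjacency —
a node inherits its in-neighbours' scores — falling back to the
undirected view if it fails to converge. Both are verified against
brute-force path-enumeration oracles and dense eigendecomposition on
small graphs.

**Aggregation.** Rank lists combine by the Borda method, here the
arithmetic mean of ranks (rank-aggregation toolkits also offer
median/geometric/L2 variants; the arithmetic mean is fixed as default), with
a gene missing from a list assigned that list's worst rank plus one, ties
shared as mean ranks and broken lexicographically for output stability.
The chain runs: per KE, the four centrality ranks are combined within
each network, then across networks; the result is combined with the
KE-level and AOP-level specificity ranks; a final Borda across the target
KEs yields one global rank. The alternative of pooling all eight
centrality lists at once is exposed by composing the exported functions
differently, but per-network-then-across is the default order.

**Specificity** of a gene is its occurrence count among target-pathway
KEs divided by its count among all other KEs, infinite when it never
occurs outside the target (ranked first; serialized as `inf`).

**Selection.** Within the top 10% of the global rank, evidence flags
assign tiers: (1) deregulated in vivo *and* in vitro, (2) deregulated in
vitro only, (3) not differentially expressed but dose-dependent; within
tiers, dose-dependent genes first, then rank. A trailing "coverage" tier
admits, for each target KE not covered by the tiered picks, the
best-ranked remaining gene from that KE's set — trading rank for breadth
across the pathway.

## Benchmark-dose modeling

For each feature, every model of the family is fitted by least squares:
linear and second-order polynomial by ordinary least squares, the
nonlinear models (hill, power, exponential, and for qPCR additionally
log-logistic, Weibull, Michaelis–Menten) by bounded Levenberg–Marquardt
with five deterministic starts derived from the data (baseline and range
from the dose-group means, shape parameters over a fixed lattice). The
hill exponent is bounded in [0.5, 8] for identifiability; the
log-logistic shares the hill form with a looser exponent bound (0, 20];
Michaelis–Menten is the hill with exponent fixed at 1. All mean functions
are listed in one reference table at the top of `R/dose_response.R`.

Model choice is by AIC on the common scale `n·ln(RSS/n) + 2(k + 1)`
(`k` mean-function parameters plus the variance), valid for comparing
fits to the same data; RSS is floored at numerical precision relative to
the data scale so that exact fits compare by parameter count rather than
rounding noise. Lack of fit is the classical F-test of the model against
the saturated per-dose-means model; features whose optimal model has
lack-of-fit p < 0.10 are discarded.

The benchmark response is `BMR = 1.349 σ` under constant variance — about
a 10% change relative to controls — with σ the residual SD of the
selected model, `sqrt(RSS/(n − k))` (a pooled per-dose σ would be the
alternative reading; the model residual is used). The BMD is the smallest
positive dose where the fitted curve departs from its dose-zero value by
BMR in either direction, located by sign-change scan plus root bisection
up to 10× the highest dose; no crossing below that cap means no BMD. A
residual SD at numerical zero (flat or exact fits) makes the BMR
degenerate and the BMD absent.

BMDL/BMDU are two-sided 95% profile-likelihood bounds: for a candidate
BMD the amplitude parameter is eliminated in closed form through the
constraint `|f(b) − f(0)| = BMR`, the remaining parameters re-optimized,
and the deviance `n·ln(RSS(b)/RSŜ)` compared to the 0.95 χ²₁ quantile.
One subtlety: for non-monotone models the point constraint can hold at a
candidate dose while the curve crosses the BMR earlier, which silently
widens the profile; candidate parameter vectors whose *first* crossing is
not at the candidate dose are rejected inside the optimization. A bound
that never crosses the threshold within (0, 10× max dose] is reported
absent.

Passing features additionally satisfy BMD ≤ max dose, BMDU ≤ max dose,
BMD/BMDL ≤ 20, BMDU/BMD ≤ 20 and BMDU/BMDL ≤ 40 (all inclusive). Worth
knowing: on pure-noise features the flexible models occasionally trace a
noise wiggle into a well-behaved-looking BMD; this false-positive mode of
unscreened BMD analysis is why practice prefilters features by
differential expression before dose-response modeling.

## qPCR validation statistics

Fold changes follow the comparative-Ct method: `dCt = Ct_gene − Ct_ref`
per sample (reference gene configurable, ACTB by default), `ddCt`
subtracts the mean control-group dCt per gene, `FC = 2^−ddCt`,
`log2FC = −ddCt`. The construction makes log2FC invariant to any
per-sample additive shift of all Ct values — the point of reference
normalization — and zero-centred in the control group; both are asserted
as properties.

Outlier handling follows the validation protocol as printed: per gene and
concentration, only values within the 25th–75th percentile band
(type-7 linear-interpolation quantiles) are retained — a deliberately
harsh filter that removes roughly half the samples. Whether an
interquartile *fence* (Q1 − 1.5·IQR, Q3 + 1.5·IQR) was intended is
genuinely ambiguous; both behaviors ship
(`percentile_filter(method = "fence")`), with as-printed the default.
Fewer than three values are returned unfiltered with a warning.

Deregulation is a one-way fixed-effects ANOVA of log2FC across
concentrations (significant below 0.05, the package-wide convention)
with Tukey HSD pairwise comparisons; F is verified against the textbook
sum-of-squares decomposition. Dose dependence delegates to the
benchmark-dose machinery with the extended qPCR family: a gene is
relevant when its optimal model shows no lack of fit (p > 0.10) and BMD,
BMDL and BMDU are all estimable. Two consequences deserve note. First,
the relevance rule has no max-dose cap, so a flat gene whose fitted curve
reaches the BMR somewhere below the search cap counts as relevant — kept
as printed. Second, the lack-of-fit gate rejects a uniform-tail fraction
of genuinely dose-responsive genes by construction (about 10%, and
somewhat more after the quartile filter, which shrinks pure error and so
inflates the lack-of-fit statistic): perfect recovery of a planted gene
panel is a per-seed outcome, not a guarantee.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic: one master seed cascades to fixed
per-generator offsets, so any stage regenerates independently, and
re-runs are bit-identical (tested). Each generator emits the ground truth
needed to score its stage's recovery.

- `simulate_corpus`: term descriptions are random token sentences; each
  KE description paraphrases its true term's (per-token corruption
  probability 0.2 by default). This tests retrieval under vocabulary
  noise; it does not mimic real ontology prose, hierarchical term
  relations, or the curation judgment the real pipeline adds.
- `simulate_aop_structure`: linear KE chains; each KE either gets a fresh
  random gene set or (probability 0.3) duplicates an earlier one,
  emulating the redundant-semantics duplication seen across real
  pathways; the last pathway duplicates the first chain KE-for-KE,
  planting a known fully contained AOP. Real AOPs branch; chains suffice
  for the merging/containment logic, which is topology-agnostic.
- The default scaffold (6 AOPs × 5 KEs, 500-gene pool) mirrors a small
  disease-focused subnetwork like the six pulmonary-fibrosis pathways
  and is used for the grouping/containment demonstrations. Fingerprint
  screening, however, emulates a collection-wide scan in which the truly
  affected pathways are a small fraction of the annotated universe; run
  it on a collection-scale scaffold (`n_aops = 20`,
  `gene_pool_size = 2000`, as the tests and acceptance script do) — on a
  6-pathway scaffold with 3 planted targets, the signature covers most of
  the universe and small KE sets cannot reach FDR significance, which is
  a property of the design, not of the method.
- `simulate_moa`: target-pathway genes are differentially expressed with
  probability 0.7 per comparison (large fold changes, small adjusted p);
  background genes carry a 2% noise floor. Gene-gene correlation and
  platform effects are not modeled, so passing tests show decision-rule
  correctness, not robustness to correlated transcriptomes.
- `simulate_dose_response` / `simulate_ct`: known linear responses (plus
  flat nulls) with Gaussian noise; the Ct generator uses the validation
  protocol's shape — five concentrations (0, 2.5, 5, 10, 100), five
  samples each, a stable reference gene — with responsive genes lowering
  Ct linearly in concentration. Heteroscedastic amplification noise and
  plate effects are not modeled.

Problem sizes throughout the tests and acceptance script (30-KE corpora,
20-pathway scaffolds, 100-seed calibrations, 24-point dose-response
designs) are chosen as the smallest sizes at which each statistical claim
is meaningfully testable; the hill model-selection check uses a
six-dose design spanning pre-EC50 through saturation
(0, 2.5, 5, 10, 20, 40 at EC50 = 5) because a design truncated before the
plateau cannot distinguish a sigmoid from a quadratic.

## Known limitations

- Annotation curation is human; the package only ranks and round-trips.
- The exact Borda application order across two networks and the pooling
  of AOP- vs KE-level FDR families are conventions with defensible
  alternatives; the defaults are fixed and documented above.
- Centrality computation materializes distance matrices; it is meant for
  networks up to a few tens of thousands of nodes, not millions.
- BMD confidence bounds assume the selected model is true; model-averaged
  BMDs are out of scope, as are quantal endpoints and time-course
  designs.
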