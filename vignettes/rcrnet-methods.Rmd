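---
title: "Methods: reverse causal reasoning on a signed two-layer metastasis network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reverse causal reasoning on a signed two-layer metastasis network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcrnet)
```

## The problem

Metastasis suppressor genes (MSGs) restrain the formation of overt metastases
without blocking primary tumor growth. Their activity is regulated by a small
set of transcription factors (TFs), and the resulting circuit — seventeen
MSGs, eleven TFs, and a handful of intermediate regulators — is documented
statement-by-statement in the literature rather than in any single dataset.
`rcrnet` turns that curated knowledge into a quantitative, testable model for
one cell context (the breast cancer line MCF7) and asks which regulatory
routes into a target node, by default the metastasis suppressor PEBP1/RKIP,
are consistent with how drugs that inhibit cell growth perturb gene
expression.

The package implements the full chain: parsing causal statements written in a
subset of the Biological Expression Language (BEL), assembling a signed
directed graph, pruning and augmenting it with knockdown differential
expression, scoring drug expression profiles on the resulting two-layer
model, and ranking directed paths into the target by how coherently the
inferred node activities follow the edge signs.

## The curated functional layer

Statements have the form `subject relation object`, where terms are
`p(X)` (protein), `r(X)` (mRNA), `act(...)` (molecular activity, optionally
annotated `ma(kin)` for kinase activity) and `comp(...)` (complex), and the
relation is one of `increases`, `decreases`, `directlyIncreases`,
`directlyDecreases`. The relation fixes the edge sign (+1 for the increase
pair, -1 for the decrease pair) and a direct flag. For graph topology the
entity forms are collapsed to the gene level — the scorer works with per-node
coefficients, not per-form coefficients — while forms, activity notes and
namespace information survive as metadata. A complex subject with *k* members
contributes *k* edges sharing the statement's sign.

The packaged table carries 70 curated statements. After complex expansion and
deduplication by ordered pair they yield 33 nodes and 67 signed edges:

```{r}
bb <- metastasis_backbone()
bb
```

Three curation decisions are worth making explicit:

* **Duplicate statements merge; sign conflicts are fatal.** The same ordered
  pair asserted with both signs among curated rows indicates a curation error
  that must surface, so `build_backbone()` stops and lists both evidence
  strings rather than voting. Duplicate identical assertions (the quadruple
  GATA3 → CD44 entry) merge into one edge that keeps all four references.
* **One printed row is internally inconsistent.** The row indexed
  MAP2K4/CASP8 carried a statement text naming MAPK14 as the subject. Reading
  the statement text would create a MAPK14 → CASP8 activation directly
  contradicting the curated kinase-activity statement that MAPK14 represses
  CASP8 — a fatal sign conflict. The packaged table therefore follows the
  row's subject and object index columns (MAP2K4 → CASP8), keeping the
  curated set sign-consistent; the fixture documents this in a comment.
* **Free-text names resolve through an alias table.** "ets-Domain Protein
  Elk-4" maps to SAP1A; namespace prefixes such as `HGNC:` are stripped. The
  table is a TSV and can be extended. MAP2K3, a complex member that the MSG
  table does not list, is retained as an `other`-role node alongside the
  documented extra regulators (SATB1, SNAI1, RELA, MTA3, TNFSF10, RUNX2,
  TGFB1, CASP8, SAP1A).

## Contextualization against knockdown expression

Curated links originate from heterogeneous systems; not all hold in MCF7.
Each backbone node's knockdown experiment supplies a differential expression
table (gene, log2FC, p-value), and three mechanical rules confront the graph
with it. The direction convention throughout: a knockdown lowers its target,
so an edge u → v with sign *s* predicts that v moves in direction −*s* when u
is knocked down.

1. **Efficiency gate.** A knockdown is usable when its own target shows
   log2FC < −1 at p < 0.05; inefficient experiments are excluded (or kept
   with a warning).
2. **Conflict removal** (thresholds |log2FC| > 1, p < 0.05): a curated edge
   u → v is dropped iff v moved *significantly in the predicted-opposite
   direction* under the knockdown of u. Only the source's knockdown is
   consulted — causality is directional. Edges whose source lacks data are
   untouched, and the decision table is emitted for manual review, because
   the adjudication of genuinely ambiguous conflicts (context, evidence
   strength, effect size) is a judgement call no threshold encodes.
3. **Data-driven edges** (same thresholds): a significant response of
   another backbone node v with no existing u → v edge becomes a new direct
   mRNA-level edge with sign −sign(log2FC). Edge existence is checked
   against the *original* curated set, so a link removed as contradicted is
   not silently re-added from the same evidence; this also makes removal and
   addition commute.

The **transcript (terminal) layer** uses the stricter pair (|log2FC| > 0.5,
p < 0.01) and collects, for each backbone node, all *non-backbone* genes
responding in its knockdown, signed with the same convention. These terminal
sets are the measurable proxy for node activity. No multiple-testing
correction is applied — the thresholds are raw p-value cutoffs, matching the
upstream analyses this design follows; a Benjamini–Hochberg option would sit
naturally on the DE tables but defaults off to keep threshold semantics
comparable.

## NPA-style scoring

Given one drug's expression profile (gene → log2FC vs control), each node u
gets a terminal score
$t_u = \mathrm{mean}_{g \in T(u)}\, \sigma_{ug}\, x_g$, the mean of signed
downstream fold-changes. Backbone coefficients $f$ then minimize the
data-anchored signed-graph smoothing objective

$$
\sum_{(u,v) \in E} (f_u - s_{uv} f_v)^2 \;+\;
\lambda \sum_u w_u (f_u - t_u)^2 ,
$$

with $w_u = |T(u)|$ (zero when the score is undefined) and coupling
$\lambda = 1$ by default. The first term rewards sign-consistency along
edges; the second anchors nodes to their own measured downstream response,
with well-measured nodes anchoring harder. The objective is a
positive-definite quadratic wherever a weakly connected component contains at
least one anchored node, so the minimizer is the solution of one small linear
system per component; unanchored components are set to zero and reported.
Coefficients are deliberately *not* clipped to [−1, 1]: their scale is set by
the data.

This is an NPA-style formulation — it reproduces the contract of network
perturbation amplitude scoring (signed per-node coefficients, a non-negative
network-level score, confidence intervals) with a self-contained quadratic
model; it is not a bit-compatible reimplementation of any published scoring
package, whose additional O/K statistics are out of scope.

The network amplitude is the mean squared co-perturbation across edges,
$\frac{1}{|E|}\sum (f_u + s_{uv} f_v)^2 / 4$: zero exactly when every edge is
anti-coherent or all coefficients vanish, quadratic in the profile scale.
Uncertainty comes from two seeded resampling schemes: per-node percentile
bootstrap over terminal genes (intervals are widened, when necessary, to
contain the point estimate, so the reported triple is always ordered), and a
network-level permutation p-value from shuffling the profile's gene labels —
the add-one estimator $(1 + \#\{A^{perm} \ge A\})/(n_{perm}+1)$ keeps it in
(0, 1]. Bootstrap sizes below 100 are refused rather than silently producing
degenerate intervals. Two exact symmetries are useful for testing and hold to
machine precision: scaling the profile by *c* scales coefficients by *c* and
the amplitude by *c²*; negating the profile negates coefficients and
preserves the amplitude.

## Agreement: concordance, coherence, κ, D+

Coefficients are binarized (activation > 0 → +1, repression < 0 → −1); exact
zeros carry no direction information and are excluded by default rather than
assigned a side (a `positive` policy exists for sensitivity checks).

* **Concordance** looks one edge out from an upstream node u: the expected
  sign of each neighbor is (state of u) × (edge sign), and the rate is the
  fraction of non-excluded neighbors matching. One subnetwork per node with
  outgoing edges, one rate per (drug, subnetwork).
* **Coherence** walks a directed path into the target, re-reading the
  *observed* upstream state at every step: the expected sign of $v_i$ is
  $x'(v_{i-1}) \cdot s_i$. The alternative convention — propagating the root
  state through the cumulative edge-sign product — is available behind
  `anchor = "root"` for sensitivity analysis; re-reading the observation at
  each step was chosen as the default because each comparison then tests one
  edge given the best available estimate of its source, rather than
  compounding upstream errors along the walk.

Both rates are chance-corrected with Cohen's κ = (observed − expected)/(1 −
expected) at a fixed 50% chance level, where κ = 2·rate − 1; undefined units
(excluded states) never contribute zeros to aggregates, which are plain means
by drug, node, path or cell line. Agreement distributions are compared to a
random baseline — i.i.d. uniform ±1 states over the involved nodes — with the
one-sided two-sample KS statistic D+ = max over t of
(ECDF_baseline − ECDF_sample), clamped at zero, and the asymptotic p-value
exp(−2 D² nm/(n+m)). The unscaled statistic lives in [0, 1]; a
√(nm/(n+m))-scaled variant is provided because scaled magnitudes well above 1
appear in the applied literature this package accompanies, and the flag makes
the two conventions explicit rather than guessing which one a reader means.

## Paths into the target and the extracted model

All simple directed paths of bounded length ending at the target are
enumerated by depth-limited reverse traversal, ordered lexicographically for
determinism. The bound matters: on the packaged network the path count into
PEBP1 grows 5, 6, 9, 11, 15 at bounds 2–6 and reaches 64 unbounded, because
the CDH1/MAPK14 hubs feed combinatorial blowup. The package default is
`max_len = 5`, the smallest bound at which the enumeration covers both
documented regulatory routes into PEBP1 — the RELA/SNAI1 repressing arm and
the ESR1 → NME1 activating arm — in all their curated variants (11 paths).

Paths are ranked by mean coherence across drugs (undefined rates dropped,
not zero-filled), ties broken by shorter path then lexicographically, and the
model is the edge union of the top-k paths above a coherence threshold
(defaults 5 and 0.6), each edge annotated with the best coherence among the
paths using it — suitable for driving edge thickness in exports (SIF,
GraphML, DOT).

One property of this pipeline deserves emphasis. Because the scorer smooths
coefficients along the graph, a strong perturbation on one route pulls its
signal-free upstream neighbors toward sign-consistency (the pull is roughly
1/(degree + λw) per unit of neighbor coefficient). Validating smoothed states
against the same graph therefore inflates coherence on the perturbed route's
entire upstream cone — several paths tie at coherence 1 on synthetic data.
This circularity is inherent to reverse-causal scoring, not a defect of the
implementation; it is why the synthetic recovery checks ask whether the
planted route attains the *maximum* coherence (joint first place) rather
than whether it is the unique table leader, and why exact zeros and
significance reporting are kept visible to the user.

## The synthetic-data generator

The generator emulates the statistical structure the pipeline assumes, with
a recorded ground truth:

* **Knockdowns** — per node: the target itself at `knockdown_depth` (default
  −2 log2FC), curated direct successors at −sign × `effect_size`, planted
  terminal genes (default 20 per node) with sign-consistent effects, and
  null genes (default 500) with pure noise. P-values are two-sided z-tests
  against the known noise model, so the 0.05/0.01 cutoffs behave with
  calibrated false-positive rates by construction rather than by accident.
* **Drug profiles** — planted ±1 activities on a few nodes (or along one
  designated pathway, with signs propagated so that the path is fully
  coherent by construction), one signed propagation step to non-planted
  neighbors at attenuation 0.5 (the minimal structure that makes coherence a
  non-trivial discriminator; planted nodes keep their planted sign so the
  truth record stays unambiguous), then terminal-gene effects plus noise.
* **Growth** — GRmax values in [−1, 1.3] with an exactly-controlled fraction
  of drugs ineffective at every dose, exercising the strict GRmax < 1
  filter.

Defaults (`effect_size = 2`, `noise_sd = 0.3`) describe a clean, deeply
sequenced knockdown screen: true effects of about four noise standard
deviations, which is what a well-powered microarray comparison of an
efficient knockdown delivers. The generator does *not* emulate probe
structure, the landmark/inferred gene distinction of L1000-style panels,
correlated noise, or realistic expression marginals — so green tests
demonstrate the machinery's correctness and calibration, not performance on
real data. All draws are seeded; the same configuration reproduces its
outputs byte for byte, and the generators restore the caller's RNG state.

## Numerical and interface choices

* Linear systems are solved densely per component (the networks here are a
  few dozen nodes); the system matrix is factor-free and rebuilt only once
  per network, then reused across bootstrap replicates.
* Strict inequalities follow the documented thresholds everywhere (GRmax <
  1, |log2FC| > 1, coherence > 0.6); boundary values are excluded.
* Degenerate inputs are flagged, not silently patched: empty terminal sets
  are undefined scores, unanchored components are zeroed and reported,
  all-excluded agreement units are dropped from aggregation with their
  exclusion visible in the long tables.
* Every pipeline output is a commented TSV or JSON with units and
  conventions named in the header; reruns with identical inputs and seeds
  are byte-identical, and the run manifest records config, package version
  and seeds (no timestamps, by design).

Test and acceptance runs use reduced problem sizes chosen to exercise every
code path at comfortable margins: 5–8-node random graphs against exhaustive
oracles, the full 33-node curated network for recovery experiments with
20 terminal genes per node, 50–100 seeded replicates for rate estimates.

## Known limitations

* The concordance/coherence chance level is fixed at 50%, which is exact for
  balanced binary states but conservative if a drug set skews strongly to
  activation or repression.
* Conflict adjudication beyond the mechanical rule (context, evidence
  weight) is surfaced as a report for human review, not automated.
* The scorer's smoothing-induced circularity (above) means coherence ranks
  routes *within* the model; it does not certify edges against data the
  model never saw.
* Cell-line-level aggregation is supported in the agreement tables, but the
  shipped pipeline drives a single cell context at a time.
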