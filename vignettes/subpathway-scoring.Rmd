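---
title: "Scoring signed linear subpathways: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring signed linear subpathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subpathways)
```

## The problem

Gene-set enrichment treats a pathway as a bag of genes. Signalling biology
is directional: a receptor activates a kinase, the kinase represses a
transcription factor, and the *pattern* of up- and down-regulation along
that chain is evidence that the cascade is engaged. `subpathways`
formalises this: it looks for chains inside signed, directed pathway
topologies whose case/control expression changes agree with every edge's
regulation sign, and attaches a permutation p-value to each such chain.

## From topology files to linear subpathways

Pathway topologies are read from KGML (the KEGG XML dialect). Only
gene-type entries are kept (group entries become the union of their member
genes); relation subtypes are simplified to two signs, +1 activation and
-1 repression, via a configurable sign map. Subtypes that carry no
regulation direction (binding/association, dissociation, indirect effect,
state change, bare phosphorylation, ...) are dropped; when several subtypes
decorate one relation, explicit inhibition outranks explicit activation,
so "phosphorylation + inhibition" is a repression edge. This is a
documented default, overridable per run, since topology files do not
standardise which subtype combinations imply which direction.
Self-loops are removed and duplicate edges collapsed: linear-path
semantics can use neither.

A **linear subpathway** is a simple directed path from a root (in-degree
0) to a leaf (out-degree 0), with multi-gene nodes expanded to every
gene-level combination. Two choices matter here:

* **Cycles.** Feedback loops are common in signalling maps but a chain
  score needs termination, so enumeration yields *simple* paths only (no
  node revisited), and only nodes reachable from in-degree-0 roots can
  appear. A pure cycle contributes nothing, which the run report flags.
* **Deduplication.** The same gene chain routinely arises from several
  entry paths or several pathways. Chains are deduplicated on the (gene
  sequence, edge-sign sequence) key with pathway provenance merged, so
  each unique chain is scored and tested once. Scoring before or after
  deduplication yields the same unique score set; deduplicating first is
  cheaper.

Enumeration streams under a per-pathway cap (default $10^6$) so dense
pathways cannot exhaust memory; hitting the cap sets an explicit truncation
flag rather than failing silently.

## Gene-level statistics

Expression input is a preprocessed log2-scale matrix (probes or genes by
samples) with a two-group case/control labelling; no normalisation or
batch correction is attempted here. Probe-level rows are collapsed to
genes by the per-sample **median** across the gene's probes — robust and
order-independent (mean and max-variance-probe collapse are available).

Per gene, three quantities drive everything downstream:

* fold change $f = 2^{\tilde{x}_{case} - \tilde{x}_{ctrl}}$, the ratio of
  2 raised to the *group medians* of log2 expression. Medians are used in
  both the fold change and the reported group summaries; a mean-based
  variant exists behind a flag but is never the default.
* binary sign $b = +1$ iff $f > 1$, else $-1$. The tie $f = 1$ maps to
  $-1$ deterministically.
* a two-sided two-sample t-test p-value on the log2 values. The
  pooled-variance (equal-variance) test is the default, matching the
  classical analysis style of two-group microarray comparisons; Welch is a
  flag. If both groups are constant and equal the p-value is defined as 1
  (no evidence); constant but unequal groups give the smallest positive
  double rather than 0.

## The well-defined segment and the statistic S

Index a chain from its leaf: genes $G_1$ (leaf) to $G_p$ (root), edge
$e_i$ joining source $G_{i+1}$ to sink $G_i$. An edge is *consistent* when
$e_i b_i b_{i+1} = 1$. Scanning upward from the leaf, the **well-defined
subpathway** is the leaf plus the maximal run of consecutive consistent
edges; the first violating edge stops the scan, and nothing beyond it
contributes. A segment needs at least two nodes — if the leaf's own edge
violates, the chain has no well-defined segment (and contributes nothing
for that labelling; under permutation it may re-enter with other signs).

Each segment of $n$ nodes is scored $S = -\ln(F_{node} F_{edge} F_{num})$:

* $F_{node} = \prod_{i=1}^{n} p(G_i)$, the product of the segment genes'
  t-test p-values. We deliberately apply no cutoff: signalling
  intermediates often shift modestly, and a hard threshold would sever
  otherwise coherent cascades. The product is the minimal form with the
  required behaviour — every node counts, and lowering any single p-value
  strictly lowers $F_{node}$ (raises $S$).
* $F_{edge}$ treats the chain as a first-order Markov chain on log2 fold
  changes: each gene is assumed regulated only by its direct upstream
  source. Over all edges of all loaded pathways (multi-gene entries
  expanded to all gene pairs), the pairs (log2 $f_{source}$, log2
  $f_{sink}$) are pooled and fitted with a bivariate normal by sample
  moments; the chain factorises as a prior at the upstream end times
  conditional densities,
  $F_{edge} = \Pr(\log_2 f_n) \prod_{i=1}^{n-1}
  \Pr(\log_2 f_{n-i} \mid \log_2 f_{n-(i-1)})$,
  with the prior a univariate normal over all measured pathway genes.
  These are normal *densities* — the only continuous reading of the
  normality assumption — so $F_{edge}$ can exceed 1 and $S$ is not
  sign-restricted in principle. A sink far from what its source predicts
  is a rare event: small density, large $S$.
* $F_{num}$ corrects for length: longer segments mechanically accumulate
  small factors. We simulate 1,000 directed $G(n{=}200, m{=}100)$ random
  graphs (uniform over simple directed graphs with exactly those counts,
  no self-loops), enumerate all simple root-to-leaf paths, and take the
  pooled empirical pmf of edge counts; a segment of $n$ nodes is looked up
  at $n-1$ edges. Lengths the simulation never produced get an
  additive-smoothing floor $\varepsilon = 1/(\text{total paths} +
  \text{support size})$ instead of zero — a zero would make $S$ infinite
  for a length the finite simulation merely missed. The simulation is
  seeded and its parameters configurable; at the 200/100 setting the pmf
  decreases from a mode at one edge.

$S$ is computed as a sum of logs throughout; products of tiny p-values
never underflow.

## Permutation significance

The null distribution of $S$ comes from shuffling the case/control labels:
for each permutation all gene statistics are recomputed, the well-defined
segment of every original chain is *re-extracted* under the permuted signs
(segments can shorten, lengthen, or vanish), and re-scored. Three design
points:

* **Pooled null.** All permuted $S$ values from all chains form one pool
  (default), so with $10^4$ permutations over hundreds of chains the
  attainable p-value resolution is far below $1/n_{perm}$. A
  per-subpathway null is available behind a flag; it is the stricter
  reading but needs orders of magnitude more permutations for the same
  tail resolution.
* **Add-one correction.** $p = (1 + \#\{S_{null} \ge s\})/(1 + N)$ by
  default, so no empirical p-value is exactly zero; the raw proportion is
  a flag for literal $\Pr(S \ge s)$ runs.
* **Fixed edge model.** The bivariate model and the prior are fitted once
  on the observed labelling and held fixed across permutations: they are
  treated as a property of the pathway corpus, and since the same fixed
  scoring function evaluates the observed and every permuted labelling,
  observed and null scores remain exchangeable under the null. Refitting
  per permutation exists behind a flag and is disproportionate at
  $10^4$–$10^6$ permutations.

Multiple testing uses Benjamini–Hochberg step-up q-values, implemented
directly (and cross-checked against the reference implementation in the
test suite). Results are reported one row per unique chain, sorted by
p-value with ties broken by $S$ descending, the chain rendered upstream
end first with `->`/`-|` edges and per-gene fold changes.

The permutation loop re-scores every chain with a handful of vectorised
operations over flattened node/edge index arrays, and the per-gene group
medians are computed in C++; $10^4$ permutations over a few hundred chains
take seconds on one CPU.

## What the synthetic fixtures emulate — and what they do not

`fixture_spec()` / `write_fixture_bundle()` generate complete toy studies:
random DAG pathways (default 5 pathways of 20–30 nodes, 70% activation
edges, a fifth of nodes carrying two genes), probe-level log2 expression
for 12 case and 10 control samples (baseline means $\sim N(8, 1)$,
per-sample noise s.d. 0.3, two probes per gene with s.d. 0.1 offsets), and
optional **planted chains**: sign-coherent by construction
($b_{sink} = e \cdot b_{source}$ down the chain), embedded as fresh
root-to-leaf linear components, their case group shifted by $b \cdot 2.0$
log2 units by default. A `shape = "chain"` mode emits pure linear
pathways, used for calibration studies where the number of chains must be
controlled exactly.

The generator reproduces the *structure* the method consumes — signed
topologies, group design, probe multiplicity, planted coherent signal —
but not the artefacts of real platforms: no background or saturation
effects, no batch structure, no correlated noise between genes, no
realistic pathway topology (hubs, feedback density). Passing tests
therefore demonstrate correctness of the machinery and calibration under
exchangeable noise, not robustness to array artefacts; on real data the
usual preprocessing and batch diagnostics remain the analyst's job.

## Numerical and degenerate-input policy

* p-values of exactly 0 (possible only through degenerate variance) are
  replaced by the smallest positive double, with a warning.
* The edge-model fit refuses corpora with fewer than 30 measured pairs
  (configurable), zero marginal variance, or $|\rho| \ge 1$.
* Chains containing unmeasured genes are skipped and counted (strict mode
  errors instead, naming the gene).
* Graphs with no roots or no leaves, empty well-defined sets, and empty
  permutation pools degrade to empty results or explicit errors — never to
  NaN scores; the test suite asserts no fixture ever yields a non-finite
  $S$.
* All randomness (fixtures, random graphs, permutations) flows through
  explicit seeds; identical configuration gives byte-identical result
  files.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
complete suite finishes in a few minutes on one CPU: fixtures of 3–5
pathways (~300 unique chains), permutation counts of $10^3$ for
calibration (200 single-chain pathways) and $10^4$ for planted-signal
recovery (20 seeds), 200 random DAGs of at most 12 nodes against the
exhaustive enumeration oracle, and the default 1,000-graph $G(200, 100)$
length simulation. The permutation count for a real analysis is
configurable; $10^5$–$10^6$ is appropriate when the smallest reportable
p-values matter.

## Known limitations

* The sign simplification discards relation subtypes without
  activation/repression semantics; pathways dominated by such edges
  contribute few chains.
* The bivariate-normal edge model is a convenience assumption; heavy-tailed
  fold-change distributions will make extreme conditional densities (and
  hence $S$) conservative or anti-conservative at the margins. No
  copula/nonparametric alternative is provided.
* The pooled null trades per-chain exactness for tail resolution (see
  above).
* Exact enumeration is used; there is no sampling fallback, so extremely
  dense pathways are handled by the cap, not approximated.
* Headline counts from any particular historical pathway corpus and
  expression dataset depend on that corpus snapshot and preprocessing;
  they are not reproduced here, and the shipped checks validate the
  machinery on synthetic data instead.
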