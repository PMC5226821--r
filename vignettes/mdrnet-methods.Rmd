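---
title: "Methods: consensus m6A-driven gene networks by network propagation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus m6A-driven gene networks by network propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrnet)
```

## The model

`mdrnet` predicts which genes are functionally driven by differential
m6A methylation (mDrGenes) in a case–control MeRIP-seq study with
replicates. The premise is that a methylation-driven gene should sit in
a neighbourhood of the protein–protein interaction (PPI) network that is
*consistently* implicated across replicate sets, even when the gene
itself is not called in every set. The pipeline therefore scores
interactions, not calls:

* **Gene calls per replicate set.** A site table (host gene, interval,
  methylation log2 fold change, FDR) is aggregated per gene:
  a gene is a DmMG in a set if it harbors at least one site with
  FDR ≤ 0.05 (configurable). Its direction label comes from its *most
  differential* site — the smallest FDR, with ties broken by larger
  |log2fc| and then genomic order. "Most differential" has no unique
  definition; FDR is the natural ranking statistic of the differential
  peak callers whose output this consumes, which is why it anchors the
  tie-break chain.
* **Propagation.** Each DmMG seeds a random walk with restart,
  p^(t+1) = (1 − λ) M p^t + λ p^0, with M the column-normalized
  adjacency and p^0 uniform over the seed set (1/k each). The stationary
  vector ranks all genes by closeness to the seed; the top 10 non-seed
  genes become candidates.
* **Degree-conditioned null.** Propagation on scale-free networks is
  biased towards hubs, so raw candidacy is calibrated against
  degree-preserving random networks: in each random copy, one random
  node per degree class seeds a walk and the degrees of its top-10 are
  pooled. The occurrence frequency of candidate degree d under seed
  class j, divided by the number of degree-d genes in the reference
  network and then by the number of random networks, is the empirical
  p-value p = f_j(d). A smooth monotone surface is fitted per class so
  later queries need no walks at all — this is what makes assessment
  essentially free once the model is built, and what makes verdicts
  stable across random-network sets (the fitted surface averages over
  the whole ensemble rather than one seed's draws).
* **Filter.** A candidate is kept iff p < 0.05 (strict) **or** its
  shortest-path distance to the seed is L = 1. The L branch protects
  biologically direct interactions that the purely topological null
  would discard — high-degree candidates have large p by construction.
* **Consensus.** Kept seed–candidate pairs are pooled across replicate
  sets as undirected edges; both endpoints must be DmMGs in at least
  one set (the same or different ones). Edges recurring in every set
  constitute the consensus network; its incident genes are the
  mDrGenes. Per-gene direction at the consensus level is a majority
  vote over the sets calling the gene, ties resolved by the direction
  of its globally best-FDR call.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `fdr_cutoff` | 0.05 | site-level FDR for a DmM call |
| `restart` (λ) | 0.5 | restart probability per step; balances local and global exploration |
| `tol` | 1e-6 | L1 convergence threshold of the walk |
| `k` | 10 | candidates retained per seed; a primary filter only — candidates are still assessed downstream |
| `n_networks` | 100 | random networks behind the null |
| `switches_per_edge` | 10 | attempted double-edge switches per edge when randomizing |
| `span` | 0.7 | nearest-neighbour fraction of the local regression on log-degree |
| `alpha` | 0.05 | empirical p-value threshold (strict) |
| `min_recurrence` | all sets | consensus recurrence rule |

`min_recurrence` defaults to the strict "every replicate set" rule but
is exposed because sub-maximal recurrences are meaningful for display
and for studies with many sets; lowering it only ever adds edges. The
weighted edge score w = (−log10 x − log10 y)/2 (x, y the endpoint
gene-level FDRs per set; "lg" conventions read as log10), summed over
occurring sets, is provided for score-thresholded consensus
construction; when an endpoint is not a DmMG in a given set its best
FDR across sets is substituted, since a cross-set endpoint has no
within-set FDR by definition.

## Numerical and design choices

* **Node identity** is exact string match on gene symbols; alias
  resolution is data curation, not algorithm, so unmatched symbols are
  logged and skipped rather than guessed at.
* **Connectivity is not assumed.** On a disconnected reference network
  the walk's mass provably stays in the seed's component, so candidates
  always share the seed's component and the L = 1 branch remains
  well-defined; `path_length()` returns `Inf` across components for API
  completeness.
* **Seeds are excluded from their own top-k.** A seed trivially ranks
  first and a seed–seed edge would be a self-loop, which the network
  forbids.
* **Ties** in candidate ranking break lexicographically by gene
  identifier, making rankings bit-identical across platforms.
* **Fitting f_j.** The per-class regression uses `stats::loess`
  (degree-1 local regression, direct surface) on log10 degree over the
  full degree-class grid, followed by isotonic projection
  (`stats::isoreg`) and clipping to [0, 1]. Monotonicity is *enforced*,
  not assumed: the chance of hub candidacy grows with degree, but raw
  local fits can wiggle where occurrences are sparse. Classes with
  fewer than three degrees of non-zero occurrence fall back to a step
  interpolation of the raw values (logged). Queries outside the
  observed degree range return the boundary value; queries at a seed
  degree that is not a class (possible only for off-network seeds) use
  the nearest class with a warning. Raw frequencies can exceed the
  number of random networks in principle (p > 1); the raw table
  preserves them and clipping happens only at fit time.
* **Randomization** delegates to igraph's double-edge-switch rewiring,
  which preserves each node's exact degree and rejects switches that
  would create loops or multi-edges. Reproducibility under a seed is
  guaranteed by deriving an independent sub-seed per (network, class)
  stream, so parallel or partial re-execution cannot reorder draws.
* **Degenerate inputs**: preprocessing drops self-loops, then
  duplicates, then isolated nodes, and errors on an empty result;
  a network with fewer than two edges cannot be randomized; an empty
  gene call set warns rather than fails (a study can still proceed on
  the remaining sets); an empty consensus warns and returns an empty
  network object that still serializes.

## The synthetic generator

`generate_toy_ppi()` produces scale-free (preferential attachment),
Erdős–Rényi, or configuration-model networks, cleaned so they pass
preprocessing unchanged. `generate_planted_study()` emulates the
replicate-set structure of a knockdown MeRIP-seq study: a module of
`module_size` genes — a hub, its strongest neighbours, plus extra
within-module edges planted at density `module_density` — represents a
functional process whose members interact densely. Per replicate set,
each module gene is emitted as 1–3 differential sites with probability
1 − `dropout` (FDR log-uniform in [1e-10, 1e-3], positive log2 fold
changes for the default hyper-methylation direction), and each
background gene is spuriously called with probability
`background_rate` (FDR log-uniform in [1e-3, 0.049], i.e. just under
the call threshold). The defaults — 100-node network, 12-gene module,
4 replicate sets, dropout 0.3, background rate 0.02 — model a
realistically noisy small study: roughly a third of true calls missing
per set and a trickle of false calls, the regime the consensus rule is
designed to survive.

What the generator does *not* emulate: read-level MeRIP-seq noise,
realistic genomic coordinates, correlated dropout between replicate
sets, mixed hyper/hypo modules (available via `direction = "mixed"`
but not the default), or symbol-mapping artefacts between call tables
and the network. Passing tests on these fixtures therefore demonstrate
the algorithm's contracts — propagation correctness, null calibration,
filter logic, consensus closure, dropout repair — not performance on
any particular biological dataset.

## Verification strategy and problem sizes

The test suite checks the walk against an independent closed-form
oracle, p* = λ(I − (1 − λ)M)⁻¹p⁰, on over a hundred random graphs of up
to 50 nodes (agreement within 1e-6 per entry), verifies degree
preservation and simplicity on 50 randomized copies of a 500-node
scale-free network, checks the null-model arithmetic against the
defining formulas and the filter against its exhaustive truth table,
and exercises the full pipeline on the planted fixture above, including
a robustness check (two null models from 20 independent random networks
each, disagreeing on at most 5% of 100 keep/drop verdicts) and repeated
recovery runs (module recovery rate must beat background recovery in at
least 9 of 10 studies). These sizes keep the whole suite to a few
minutes while still exercising degree heterogeneity; all of them are
the package's own choices and scale up by changing the corresponding
arguments.

## Limitations

* Calibration quality is bounded by `n_networks`: with the default 100
  random networks the smallest non-zero empirical p is 0.01/`n_ppi`
  per occurrence, and rarely-seen degree classes rely on the fallback
  step fit.
* No multiple-testing correction is applied across candidates; the
  filter is a per-candidate rule by design.
* The method inherits the biases of its reference network: missing
  interactions cannot be recovered, and heavily studied genes have
  inflated degree, which the null corrects for only topologically.
* Replicate sets are treated as exchangeable; systematic batch
  structure between sets is not modelled.
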