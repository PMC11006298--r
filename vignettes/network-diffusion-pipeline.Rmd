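---
title: "From curated DEG evidence to pathways: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From curated DEG evidence to pathways: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppidiffuse)
```

## The problem

Transcriptome studies of a perturbed transcription factor — here THAP1,
mutated in an autosomal-dominant dystonia with roughly 50 % penetrance —
accumulate differentially expressed genes (DEGs) across heterogeneous
models: knockout mice, patient-derived iPSC neurons, cell lines. Each study
reports a handful of genes with a direction of regulation and a
significance level, often only as a star tier. The question this package
addresses is how to read such a curated evidence table as one signal:

1. Are the reported genes more functionally related than chance would
   allow? (seed-set connectivity on a protein–protein interaction network)
2. Which parts of the network do they jointly point at? (signed network
   diffusion)
3. Which pathways do those parts correspond to? (hypergeometric
   over-representation of the extreme diffusion scores)

## Seed scores from evidence rows

Each evidence row contributes a signed score
$$s_g = \sigma(\text{direction}) \cdot (-\log_{10} p),$$
with $\sigma(\mathrm{UP}) = +1$, $\sigma(\mathrm{DOWN}) = -1$. Star tiers
are converted at their boundary values (`*` → 0.05, `**` → 0.01, `***` →
0.001); the boundary is the conservative choice when only a range is
reported, and it makes the scores reproducible from the printed table
alone. With this orientation, stronger evidence has larger magnitude, so
"most positive" and "most negative" diffusion scores correspond to up- and
down-regulated neighbourhoods respectively.

Genes observed in several models can disagree (in the packaged table,
RRM1 and TOMM40 carry one UP and one DOWN record each). The default policy
sums the signed scores, so contradictory evidence attenuates rather than
being silently dropped; `combine = "max_abs"` keeps the single strongest
record instead (magnitude ties fall back to the sum). Which policy a
published analysis used is rarely stated, which is why both are exposed as
options rather than one being asserted as *the* method.

Two parser edge cases are handled explicitly rather than erroring: a row
whose significance lists several tiers (`"**, ***"`) resolves to the
weakest listed tier, and an `N/A` significance is assigned the weakest
tier `*`, both with a warning (`na_action = "drop"` removes such rows
instead). Both choices are conservative: they can only shrink a seed's
magnitude.

```{r}
deg <- suppressWarnings(read_deg_table(thap1_deg_example()))
nrow(deg); length(unique(deg$gene))
rrm1 <- subset(deg, gene == "RRM1")
sum(record_score(rrm1$direction, rrm1$p_value))
```

## Connectivity against random node sets

The test statistic is the number of edges the mapped seed set induces in
the network. The null distribution is Monte-Carlo: `n_samples` node sets
of the same size drawn uniformly at random (the stated null of the
original analysis style; a degree-decile-matched variant is available as a
sensitivity analysis, since literature-derived seeds tend to be
well-studied, high-degree proteins). The empirical p-value uses the
add-one permutation convention $(1 + \#\{X_i \ge x\}) / (1 + B)$, which is
never zero and is slightly conservative.

Because published connectivity p-values (of order $10^{-8}$) are far
beyond any feasible Monte-Carlo resolution, the test also reports an
analytic upper tail: $P(X \ge x)$ for a Poisson with rate equal to the
null mean edge count. A Poisson tail was chosen over a normal
approximation because the statistic is a small count; neither is claimed
to be the published computation, which is unstated. The two routes are
reported side by side so a reader can see when they disagree.

The density-based expectation $\binom{k}{2} \cdot 2|E|/(|V|(|V|-1))$
equals the uniform-null mean exactly in expectation, which the test suite
checks within three standard errors at $G(1000, 0.01)$, $k = 45$.

## The diffusion kernel

Scores are propagated with the regularised Laplacian kernel
$$K = (I + \sigma L)^{-1}, \qquad L = D - A,$$
and $f = K s$ as the steady-state diffusion score. Properties that the
tests enforce, and that make this kernel the natural choice here:

* $K$ is symmetric positive definite;
* rows of $K$ sum to one, so $\sum f = \sum s$ — total evidence mass is
  conserved, and signed contributions cancel where they collide;
* $\sigma \to 0$ gives $f \to s$ (no smoothing), $\sigma \to \infty$ on a
  connected graph gives the constant mean — $\sigma$ interpolates between
  "trust only the seeds" and "trust only the topology".

Defaults: $\sigma = 1$ (the common default of regularised-Laplacian
implementations; the original analysis states no value) and the unweighted
Laplacian (the network is already thresholded at confidence 0.7;
`weighted = TRUE` switches to confidence-weighted adjacency). Raw scores
$f$ are ranked directly — no z-scoring or permutation normalisation —
because the selection rule is "most positive / most negative" raw signed
scores. Disconnected graphs are allowed; the kernel is block-diagonal per
component, so no largest-component restriction is imposed.

Numerically, `diffuse()` solves the sparse SPD system
$(I + \sigma L) f = s$ by a sparse Cholesky factorisation and never forms
$K$; `regularized_laplacian_kernel()` materialises the dense inverse only
when the explicit matrix is requested, which is intended for graphs of at
most a few thousand nodes. A two-node worked example pins the arithmetic:
one edge $a\!-\!b$, $\sigma = 1$, $s = (3, 0)$ gives exactly
$f = (2, 1)$.

The selection takes $m = \mathrm{round}(q\,|V|)$ nodes per tail with
$q = 0.01$ by default (1 % of a ~16,900-node network is 169 proteins, the
scale of the motivating analysis). Boundary ties break lexicographically
by identifier so results are deterministic; with all-equal scores this
degenerates to the alphabetically first $m$ nodes, which is documented
rather than hidden.

## Enrichment and its filters

Each tail is tested separately against the pathway collection by a
one-sided hypergeometric upper tail (over-representation), with the
pathway size $K$ computed after intersecting members with the universe.
The universe is all network nodes — the diffusion ranks every node, so
every node was selectable; restricting to annotated nodes is a config
choice, not the default. A record passes when the overlap is at least 3
**and** raw $p < 0.05$, the filter pair used in dot-plot style summaries
of this kind of analysis. Benjamini–Hochberg q-values are reported
alongside but deliberately do not enter the pass flag, preserving that
published filter; readers who want FDR control can filter on `q`.

## What the synthetic generator emulates

`simulate_study()` produces the full input bundle with known ground
truth. Defaults (chosen once, as the study conditions for all calibration
and recovery tests):

| parameter | default | rationale |
|---|---|---|
| network | preferential attachment, $n = 2000$, $m = 3$ | heavy-tailed degrees like a PPI network; full-pipeline tests stay under a minute |
| module | 45 nodes, $p_{in} = 0.3$ | the size of the mapped seed set in the motivating analysis; clearly but not absurdly denser than background |
| DEG table | all 45 module genes + 100 background genes, $p \sim \mathrm{Beta}(0.05, 1)$ signal / uniform background, coherence 0.9 | a curated table: mostly strong, directionally coherent findings plus a trickle of background; rows with $p \ge 0.05$ are dropped, as only significant findings get curated |
| pathways | 5 true (overlap 0.5) / 45 decoys, sizes 20–80 | Reactome-like set sizes; decoys dominate so false-positive behaviour is measurable |

Under Beta$(a,1)$ the tier composition of *emitted* signal rows is
analytic: $P(p < 0.001 \mid p < 0.05) = (0.001/0.05)^a \approx 0.82$ at
$a = 0.05$, which the generator tests assert over replicates.

What the generator does **not** emulate: STRING's confidence-score
distribution, Reactome's pathway hierarchy and overlap structure, and the
correlation between degree and study bias in real literature-derived seed
sets. Passing recovery tests therefore show the pipeline's machinery is
correct and calibrated on planted structure — they do not certify
biological conclusions on real networks, where identifier mapping loss and
annotation bias add noise the generator leaves out.

All generators are bit-reproducible from their integer seed
(`withr::with_seed` around every draw), and the writers emit sorted,
deterministic text files, so two pipeline runs with the same seed are
byte-identical — which is itself an acceptance-tested property.

## Problem sizes used in the checks

The packaged checks run at sizes chosen to finish quickly on one CPU while
keeping every statistical assertion well-powered: kernel algebra on twenty
random graphs of up to 500 nodes; null calibration at $G(1000, 0.01)$ with
10,000 null draws for the mean and 1,000 replicates × 300 draws for the
type-I error; end-to-end recovery over 25 replicates of the full
$n = 2000$ default bundle with 1,999 connectivity draws each (the add-one
convention needs at least 999 draws to resolve $p \le 10^{-3}$).

## Reproducing a published-scale analysis

Numbers tied to the external STRING v11 human network (45 mapped genes,
33 connected proteins sharing 62 interactions against 27 expected,
$p = 1.02 \times 10^{-8}$, 169 selected proteins) require downloading that
network and a Reactome GMT release; no such download ships here. The
recipe is: `read_string_links(<protein.links file>, cutoff = 0.7)`,
`read_alias_map(<aliases>)`, then the pipeline as in the README. Which 4
of the 49 table symbols fail to map depends on the alias release (one
symbol is a pathway component rather than a gene, one is murine), so the
package documents its own unmapped list at run time rather than asserting
the published one.

## Known limitations

* The dense kernel path is quadratic in memory; use `diffuse()` (sparse
  solve) beyond a few thousand nodes.
* The Poisson analytic tail assumes the null edge count is approximately
  Poisson; for very dense networks the Monte-Carlo empirical p is the
  safer report.
* Seed scores from tier-only tables are step functions of the evidence;
  two genes with $p = 0.04$ and $p = 0.011$ receive identical scores.
* The uniform null ignores degree bias of curated seed sets; the
  degree-matched null is provided, but its decile stratification is
  coarse.
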