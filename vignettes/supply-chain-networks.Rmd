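---
title: "Analysing medicine supply chains as directed networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing medicine supply chains as directed networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supplynet)
```

## The model

A medicine supply chain is represented as a directed graph over four kinds
of business: importers (or local manufacturers) at the head of chains,
wholesalers, pharmacies that also wholesale, and retail outlets (licensed
pharmacies and over-the-counter shops). Each recorded purchase becomes an
edge stored **from buyer to supplier**. Two readings follow immediately:

* **in-degree** = number of customers a node supplies (its distribution
  network);
* **out-degree** = number of suppliers a node buys from (its purchasing
  network).

Reversing every edge recovers the physical drug-flow direction; the role
classifier (`classify_roles()`) performs exactly that translation when it
derives a node's role from its link pattern (no suppliers of its own =
top of a chain; suppliers only = end retailer; both = intermediary).

The whole network is held in a binary adjacency matrix $G$:
$G_{uv} = 1$ iff $u$ buys from $v$. Duplicate records of the same ordered
pair collapse to a single entry; the same pair may, however, appear once
per medicine price category, since a trading relationship can carry goods
in several price bands. Self-loops are permitted and are read as a
business that manufactures and supplies from the same premises.

Matrix powers do the path accounting: $(G^n)_{ij}$ counts directed walks
of length $n$, and $\mathrm{Tr}(G)$ counts self-loops. For loop lengths
$n > 1$, `count_cycles()` takes the trace over powers of $G$ with its
diagonal removed: the raw trace would re-count a single self-loop at every
power ($v \to v \to v$ is a closed walk of length 2), which is not what a
loop audit of a supply chain means. On a network whose only short cycles
are self-loops the deloop-ed trace is exactly the number of directed
$n$-loops, and a healthy supply chain should return zero for every
$n > 1$.

## Degree-distribution fitting

`degree_distribution()` tabulates $p_k$, the probability that a random
node has degree $k$, normalised over **all** nodes including degree zero.
Three models are then fitted to the $(k, p_k)$ pairs by
Levenberg–Marquardt least squares (`minpack.lm`):

$$p(k) = a k^{-b}, \qquad p(k) = a e^{-bk}, \qquad
p(k) = \frac{1}{k\sigma\sqrt{2\pi}}
       \exp\!\left(-\frac{(\ln k - \mu)^2}{2\sigma^2}\right).$$

Numerical choices, all configurable:

* The power law and the log-normal are undefined at $k = 0$, so their fits
  and their goodness-of-fit comparisons run over $k \ge 1$; the zero bin
  still participates in the normalisation of $p_k$. The exponential uses
  the full support.
* Starting values come from a log–log slope (power law), a log-linear
  slope (exponential) and the moments of $\ln k$ (log-normal), with up to
  five perturbed restarts on non-convergence.
* The $\chi^2$ statistic compares bin **counts** by default, with the
  model renormalised over the used bins so observed and expected totals
  agree (the behaviour of standard `chisquare` routines); a
  probability-scale mode is available (`use_counts = FALSE`). Degrees of
  freedom default to $\mathrm{bins} - 1$; the textbook
  $\mathrm{bins} - 1 - n_{\mathrm{params}}$ correction sits behind
  `dof_correction`. A strictly positive model can underflow at extreme
  degrees; expectations are floored at $10^{-12}$ of the observed total so
  that the (enormous) misfit stays finite rather than erroring.
* `select_best_model()` picks the minimal $\chi^2$, breaking exact ties by
  parameter count and then model name, and records the tie-break.

Maximum-likelihood power-law estimation (Clauset-style) is deliberately
out of scope: the fitting surface here is the curve-fit convention, which
is what the comparison statistics are defined against.

## PageRank

The random-walk story runs along the stored orientation: start at a random
outlet, repeatedly follow a random out-link (a purchase) back up the
chain; suppliers visited often are important. The default `"normalised"`
variant is the standard library convention — per-node teleport
$(1-d)/N$, and the mass of dangling nodes (out-degree 0, i.e. the
top-level suppliers, which are numerous here) redistributed uniformly each
iteration — so scores sum to 1 and ratios between nodes are the meaningful
comparison. The `"eq1_literal"` variant iterates the classic recursion
$PR(A) = (1-d) + d \sum_i PR(N_i)/C(N_i)$ exactly as written: no $1/N$,
dangling nodes contribute nothing. Self-loops count in the out-link
divisor $C(N)$ in both variants. Defaults: $d = 0.85$, L1 tolerance
$10^{-10}$, 1000 iterations, non-convergence flagged rather than thrown.

## Clustering conventions

The undirected coefficient is $C_u = 2L_u / (d_u(d_u-1))$ on the
symmetrised graph. The directed generalisation counts all directed
triangle configurations through $u$ via
$T(u) = \tfrac12\,\mathrm{diag}\big((A + A^\top)^3\big)_u$ and normalises
by $\deg^{tot}_u(\deg^{tot}_u - 1) - 2\deg^{\leftrightarrow}_u$. Two
normalisations of that ratio are in circulation: Fagiolo's
$T/\mathrm{denom}$ — the convention of the standard network libraries, and
the only one under which a fully reciprocal network reproduces its
undirected coefficient — and a halved form $T/(2\,\mathrm{denom})$ that
appears in some published statements of the formula. The package defaults
to `convention = "fagiolo"` and exposes `"printed"` for comparability with
sources using the halved form; the two differ by an exact factor of 2.
Self-loops never count towards triangles, and nodes with fewer than two
partners score 0 by convention, so the average is always defined.

## Supply-chain lengths

The conventional "average path length" over all node pairs is not the
quantity of interest in a distribution network; what matters is how many
purchases a drug passes through before reaching a customer. `chain_stats()`
therefore measures shortest directed distances from retail-role nodes to
top-level suppliers (out-degree 0, self-loops ignored — a set that is
*network-relative*, so a sub-network can expose more top-level nodes than
its parent). `L_avg` averages over all reachable ordered retailer–top
pairs by default; whether a practitioner would rather average each
retailer's *nearest* top-level supplier is a genuinely open choice, so
`mode = "per_retailer_min"` implements the alternative. A *direct link* is
an edge running straight from a retailer to a top-level node.

Regional sub-networks are seeded by the retail outlets of a region (label
or bounding box) and include the **full upstream closure** — every node
reachable along buyer→supplier edges and every traversed edge. One-hop
inclusion of immediate suppliers only is available (`mode = "one_hop"`),
but closure is the default because observed regional chains reach length
4, which one-hop extraction cannot represent.

## The synthetic generator

The generator exists so that every analysis stage is testable at survey
scale without restricted survey data. It must deliver, simultaneously:
a power-law in-degree tail, a log-normal out-degree over 0–6, no directed
cycles apart from a few self-loops, chains of at most 4 links, and a
dominant geographic hub. No textbook random-graph model gives all five, so
the construction is layered:

1. **Levels.** Nodes sit in `n_levels` levels — top-level suppliers,
   intermediate wholesalers, retailers. Every non-top node buys only from
   strictly lower levels, which *guarantees* acyclicity and bounds every
   chain at `n_levels − 1` links for every seed.
2. **Supplier counts.** Each non-top node draws its number of suppliers
   from a discretised log-normal clipped to `[1, max_suppliers = 6]`. The
   defaults `out_mu = 0.5`, `out_sigma = 0.4` put the discretised mode at
   2 suppliers and the mean at 1.78, matching the observed 0–6 range and
   the surveyed link density (about 350 links over 229 nodes); the
   surveyed fit's own log-normal parameters are not published, so these
   values are this package's choice and are not claimed to match them.
3. **Attachment.** Each supplier stub attaches to a lower-level node with
   probability proportional to
   $(\text{in-degree} + \varepsilon c_i) \times \text{affinity}$, where
   the capacity $c_i$ is drawn from a Pareto density $\propto c^{-b}$
   truncated to `[1, attractiveness_range]` with $b$ the configured
   `target_exponent`. Realised in-degrees are then (approximately) a
   Poisson mixture over power-law rates, so the in-degree distribution
   follows $k^{-b}$ over the observed range and the configured exponent is
   mechanically recovered by the package's own fitting route — a plain
   homogeneous-offset preferential attachment on a near-fixed supplier
   pool cannot achieve this, because the resulting urn produces too flat a
   small-$k$ distribution whatever the offset. The in-degree term retains
   rich-get-richer reinforcement; affinity is 2 for a same-region
   supplier, 1.5 for the hub region, 1 otherwise.
4. **Tree-likeness.** A buyer discounts (factor `redundancy_penalty`,
   default 0.1) any candidate already trading with one of its chosen
   suppliers: buying from both an intermediary and that intermediary's own
   source is commercially redundant. Since in a layered construction every
   triangle has exactly this form, the penalty keeps the average directed
   clustering near zero — as observed in real chains — while still
   permitting occasional triads.
5. **Dressing.** Self-loops (default 6) go to the highest in-degree
   top-level nodes, reflecting that manufacturer-suppliers are
   well-connected businesses, and are always labelled CHEAP (locally made
   stock is cheap stock). EXPENSIVE labels are biased (default 90%) onto
   direct retailer-to-top edges — imported premium products bypass
   intermediaries. Coordinates scatter around region centroids.

`ghana_like_preset()` fixes the study design of the motivating survey:
six regions (three urban, three rural) with 20 retail outlets each, 69
intermediate wholesalers across three levels, 40 top-level suppliers
concentrated in the Accra hub — 229 nodes, six self-loops, chains of at
most 4 links.

```{r}
net <- generate_network(ghana_like_preset(seed = 1))
net
c(self_loops = count_cycles(net, 1), two_loops = count_cycles(net, 2))
chain_stats(net)
```

### What the generator does and does not emulate

It reproduces the *structural* signature: degree distributions and their
best-fitting model families, loop content, chain lengths, hub dominance,
price-category patterning. It does **not** attempt to reproduce
socio-economic covariates, actual trade volumes (edges are binary — the
surveyed data carry no quantities), seasonal or temporal dynamics, or the
sampling artefacts of link-tracing surveys (e.g. the unobserved out-degree
of never-visited top suppliers beyond setting them to zero). Tests passing
on generated networks therefore certify the analysis machinery and the
stated structural properties, not distributional claims about any real
country's market beyond those properties.

## Problem sizes and determinism

Structural properties are exercised at survey scale (229 nodes), where a
network generates in well under a second. Exponent recovery and the
power-law-vs-log-normal model ranking are statistical properties of the
tail, so they are checked at simulation scale — 2000 retailers, roughly
3800 nodes — across ten fixed seeds; one such generation plus all six
model fits takes about a second. Every stochastic step in the package
draws from the single generator seeded by `seed` (in
`generator_config()`, `run_config()` or `--seed` on the scripts), so a
fixed seed yields byte-identical outputs, including the pipeline manifest
checksums.

## Known limitations

* Degree-distribution fitting is least squares on the empirical pmf, not
  maximum likelihood; for small networks the fitted exponent depends
  noticeably on the low-$k$ bins. This matches the convention the
  comparison statistics are defined against, but it is not the estimator
  one would choose for inference about the tail alone.
* The `dof = bins − 1` default ignores estimated parameters; switch on
  `dof_correction` for the conservative convention.
* `L_avg` has two defensible definitions (all pairs vs per-retailer
  nearest); both are implemented, and reported values should state which
  was used.
* Price categories are relative, per-outlet judgements in the source
  surveys; the package treats the labels as given and makes no attempt to
  harmonise them across outlets.
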