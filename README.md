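# supplynet

Directed network analysis of medicine supply chains in R.

Antimalarial medicines reach patients through chains of importers,
wholesalers and retail outlets. Where those chains are long, opaque or
dominated by a few hub distributors, they are vulnerable both to targeted
disruption and to the entry of substandard and falsified products. This
package turns survey-style tables of outlets ("who did you buy from, and
was it cheap or expensive?") into directed networks and computes the
structural statistics that characterise them, for researchers in
pharmaco-epidemiology, supply-chain studies and network science.

Edges are stored **buyer → supplier**, so a node's in-degree counts its
customers (its distribution network) and its out-degree counts its
suppliers (its purchasing network); reversing every edge recovers the
physical drug-flow direction.

## What it computes

* **Adjacency algebra** — binary adjacency matrix *G*; `(Gⁿ)ᵢⱼ` counts
  walks of length *n*; trace-based loop detection (`Tr(G)` = self-loops;
  longer directed loops via powers of the deloop-ed adjacency).
* **Degree-distribution model fits** — empirical *p(k)* per direction,
  least-squares fits of *p(k) = a·k⁻ᵇ* (power law), *a·e⁻ᵇᵏ*
  (exponential) and the log-normal density, compared by χ² goodness of
  fit with upper-tail p-values (`dof = bins − 1`).
* **PageRank** — power iteration with explicit dangling-node handling
  (top-level suppliers have no out-links), plus the literal textbook
  recursion as a variant; `PR(A) = (1−d) + d·Σ PR(Nᵢ)/C(Nᵢ)`.
* **Clustering** — undirected `C_u = 2L_u/(d_u(d_u−1))` and the directed
  (Fagiolo) triangle generalisation, under two normalisation conventions.
* **Supply-chain lengths** — shortest directed distances between retail
  outlets and top-level suppliers: `L_max` (diameter in the supply-chain
  sense), `L_min`, `L_avg`, and the count of direct retailer-to-importer
  links.
* **Sub-networks** — regional extraction with full upstream closure, and
  per-price-category slices; a Table-style attribute report across all of
  them.
* **Synthetic generator** — layered preferential attachment with
  Pareto-distributed supplier capacities that reproduces the five
  structural features of surveyed chains: power-law in-degree (target
  exponent *b* ≈ 1.57), log-normal out-degree bounded at 6, no directed
  cycles beyond a handful of self-loops, chains of at most 4 links, and a
  dominant geographic hub.

## Worked example

```r
library(supplynet)

net <- generate_network(ghana_like_preset(seed = 1))
net
#> <supply_network> 229 nodes, 318 links (6 self-loops)

attribute_table(standard_subnetworks(net))[1:3, 1:9]
#>           label nodes links avg_degree l_max l_min l_avg direct_links    c_avg
#> 1 Whole Network   229   318      2.777     4     1 1.780          104 0.003040
#> 2         Accra    43    58      2.698     4     1 1.923           10 0.000000
#> 3        Kumasi    43    59      2.744     4     1 1.744           19 0.006025

din  <- degree_distribution(net, "in")
fits <- lapply(c("power_law", "exponential", "log_normal"),
               function(m) fit_model(din, m))
select_best_model(fits)
#> <degree_model_fit> power_law on in-degree: a=0.09074, b=1.223;
#>   chi2 = 13.53 (dof 14, p = 0.4852)

head(rank_nodes(pagerank(net), net), 3)
#>    rank node_id score in_degree
#> 1     1 N0009   0.290        67
#> 2     2 N0038   0.159        16
#> 3     3 N0025   0.127        36
```

Reading the output: the generated survey-scale network has 229 outlets and
318 distinct trading links, six of them self-loops (businesses that
manufacture and supply from the same premises). Every supply chain runs at
most 4 links from a retailer up to a top-level supplier, with an average of
1.78, and 104 links run straight from a retailer to a top-level supplier. The in-degree
distribution is best described by a power law (χ² = 13.5 against 2.2×10¹⁰
for the exponential), the signature of a scale-free distribution network in
which a handful of hubs — here node N0009 with 67 customers — supply most
of the market. Note the second-ranked node by PageRank (N0038) has far
fewer direct customers (16) than the third (N0025, 36): walk-based
importance and raw link counts rank nodes differently.

To analyse real survey tables instead, use
`load_network("nodes.csv", "edges.csv")` (schema in `?supply_network`), or
run the bundled command-line front end
`inst/cli/supplynet.R analyze --nodes nodes.csv --edges edges.csv --out dir`.

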