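# netexposure

Network exposure analysis of annotated recommendation networks, built for
infodemiology studies of vaccine (mis)information on video platforms.

A platform's "related videos" links, crawled breadth-first from a set of
start videos, form an undirected recommendation network. When every video in
the network is annotated — vaccine-related or not, pro- or antivaccine
stance, autism-related, health-related, health misinformation, source type —
the **network exposure model** (diffusion of innovations; Valente) measures
how much misinformation surrounds each video:

```
E_i = (# neighbours of i carrying the attribute) / degree(i),   E_i = 0 for isolated nodes
```

A video with four recommendations, three of which lead to misinformation,
has exposure 3/4 = 0.75. A node is *exposed* when `E_i > 0`, and
**case-control odds ratios** `OR = ad/bc` from the exposed-by-type 2×2
tables quantify which video types sit closest to antivaccine content, with
Woolf, Cornfield-approximate and exact conditional (noncentral
hypergeometric inversion) confidence intervals — the exact construction
gives informative one-sided bounds even for zero cells.

The package provides:

* `build_network()` / `recode_stance()` — cleaning and annotation
  conventions (dedup, undirected collapse, self-loop removal, language
  exclusion, misinformation→antivaccine recoding);
* `read_network()` / `write_network()` — GraphML, GEXF 1.2 and CSV
  edge-list + node-table IO;
* `simulate_crawl()` / `preset_scenario()` — a synthetic snowball-crawl
  generator (branching 6, depth 3, re-attachment, first-order category
  homophily) with presets calibrated to the four study networks, so the
  whole pipeline is testable without platform access;
* `global_stats()` — average degree, largest-component diameter, average
  clustering;
* `network_exposure()`, `exposure_summary()`, `exposed_flags()` — the core
  statistic;
* `build_table()`, `odds_ratio()`, `exact_ci()`, `woolf_ci()`,
  `cornfield_ci()` — the case-control analysis;
* `krippendorff_alpha()`, `systematic_sample()`, `pct()`, `run_report()`,
  `write_report()` — annotation-stage utilities and table-style reports;
* a thin CLI at `inst/cli/netexposure.R` (subcommands `simulate`, `stats`,
  `exposure`, `odds`, `alpha`, `report`).

## Worked example

```r
library(netexposure)

# the canonical worked example: degree-4 node, 3 misinformation neighbours
ann <- data.frame(id = c("z", paste0("n", 1:4)),
                  vaccine_related = c(FALSE, TRUE, TRUE, TRUE, FALSE),
                  stance = c("none", "anti", "anti", "anti", "none"))
net <- build_network(data.frame(src = "z", dst = paste0("n", 1:4)), ann)
node_exposure(net, "z", "stance=anti")
#> [1] 0.75

# a synthetic conspiracy-playlist crawl: 16 seeds, branching 6, depth 3
sim <- simulate_crawl(preset_scenario("conspiracy_seed", rng_seed = 17))
sim$network
#> <rec_network> 555 nodes, 1161 edges (provenance: synthetic, 16 seeds)
#>   stance: pro 31, anti 89, none 435
global_stats(sim$network)
#> Nodes 555 | Edges 1161 | Avg degree 4.2 | Diameter 7 | Avg clustering 0.015

res <- network_exposure(sim$network, "stance=anti")
exposure_summary(res)
#>   mean (SD) 0.19 (0.28); exposed 248 (44.7%); range 0.08-1.00

tab <- build_table(sim$network, "stance=anti", exposed_flags(res),
                   type = "antivaccine")
exact_ci(tab)
#> OR 12.35 (6.285-26.37), 95% CI, method exact_conditional
```

Reading the output: the simulated conspiracy-seeded network has 555 videos
of which 89 are antivaccine after recoding; 44.7% of videos have at least
one antivaccine recommendation; and antivaccine videos are about 12 times
more likely than other videos in the network to be recommended further
antivaccine content (95% exact conditional CI 6.3–26.4) — the
rabbit-hole structure the exposure model is designed to detect. Simulated
networks match the study networks' node counts and category composition by
construction, not their edge densities, so exposure levels are higher than
the observed ones; see the methods vignette
(`vignettes/network-exposure-methods.Rmd`) for what the generator does and
does not emulate.

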