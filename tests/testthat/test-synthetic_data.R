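test_that("degenerate crawl configs produce the expected shapes", {
  sim <- simulate_crawl(crawl_sim_config(n_seeds = 1, branching = 1,
                                         depth = 0, reattach_prob = 0.5,
                                         rng_seed = 1))
  expect_equal(n_nodes(sim$network), 1L)
  expect_equal(n_edges(sim$network), 0L)
})

test_that("no re-attachment gives the closed-form forest", {
  cfg <- crawl_sim_config(n_seeds = 6, branching = 6, depth = 3,
                          reattach_prob = 0, rng_seed = 123)
  sim <- simulate_crawl(cfg)
  expect_equal(n_nodes(sim$network), 6L * (1 + 6 + 36 + 216))  # 1554
  expect_equal(n_edges(sim$network), n_nodes(sim$network) - 6L)
  expect_equal(average_clustering(sim$network), 0)
  # acyclic: every component is a tree
  g <- as_igraph(sim$network)
  comp <- igraph::components(g)
  expect_equal(igraph::ecount(g), igraph::vcount(g) - comp$no)
})

test_that("identical configs reproduce byte-identical results", {
  cfg <- crawl_sim_config(n_seeds = 4, branching = 4, depth = 3,
                          reattach_prob = 0.4, rng_seed = 99)
  a <- simulate_crawl(cfg)
  b <- simulate_crawl(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  # and the caller's RNG stream is not consumed
  set.seed(7); x <- runif(1)
  set.seed(7); invisible(simulate_crawl(cfg)); y <- runif(1)
  expect_identical(x, y)
})

test_that("truth covers every node and every level", {
  sim <- simulate_crawl(crawl_sim_config(n_seeds = 3, branching = 4,
                                         depth = 3, reattach_prob = 0.3,
                                         rng_seed = 5))
  expect_setequal(sim$truth$id, sim$network$nodes$id)
  expect_true(all(sim$truth$level %in% 0:3))
  expect_equal(sum(sim$truth$level == 0), 3)
  expect_true(all(is.na(sim$truth$parent_id[sim$truth$level == 0])))
  expect_false(anyNA(sim$truth$parent_id[sim$truth$level > 0]))
})

test_that("higher re-attachment shrinks the expected node count", {
  counts <- sapply(c(0.1, 0.5), function(rho) {
    mean(sapply(1:10, function(s) {
      n_nodes(simulate_crawl(crawl_sim_config(
        n_seeds = 4, branching = 5, depth = 3, reattach_prob = rho,
        rng_seed = s))$network)
    }))
  })
  expect_lt(counts[2], counts[1])
})

test_that("children follow the configured category transition matrix", {
  cats <- sim_categories()
  H <- matrix(1 / 6, 6, 6, dimnames = list(cats, cats))
  H["antivaccine", ] <- c(0.05, 0.6, 0.05, 0.1, 0.15, 0.05)
  seed_dist <- setNames(as.numeric(cats == "antivaccine"), cats)
  sim <- simulate_crawl(crawl_sim_config(
    n_seeds = 40, branching = 6, depth = 2, reattach_prob = 0.2,
    category_transition = H, seed_category_dist = seed_dist, rng_seed = 21))
  tr <- sim$truth[!is.na(sim$truth$parent_category) &
                    sim$truth$parent_category == "antivaccine", ]
  p_hat <- mean(tr$category == "antivaccine")
  se <- sqrt(0.6 * 0.4 / nrow(tr))
  expect_gt(nrow(tr), 100)
  expect_lt(abs(p_hat - 0.6), 3 * se)
})

test_that("presets reproduce the study crawl parameters", {
  cfg <- preset_scenario("conspiracy_seed")
  expect_equal(cfg$n_seeds, 16L)
  expect_equal(cfg$branching, 6L)
  expect_equal(cfg$depth, 3L)
  expect_equal(preset_scenario("expert_seed")$n_seeds, 8L)
  for (nm in c("provaccine_search", "antivaccine_search",
               "conspiracy_seed", "expert_seed")) {
    cc <- preset_scenario(nm)
    expect_equal(unname(rowSums(cc$category_transition)), rep(1, 6),
                 tolerance = 1e-12)
    expect_equal(sum(cc$seed_category_dist), 1, tolerance = 1e-12)
  }
  # seed networks start from antivaccine videos
  expect_equal(preset_scenario("expert_seed")$seed_category_dist[["antivaccine"]], 1)
  expect_error(preset_scenario("no_such_network"))
})

test_that("preset expected node counts match the calibrated closed form", {
  targets <- c(provaccine_search = 283, antivaccine_search = 354,
               conspiracy_seed = 483, expert_seed = 551)
  s_vals <- c(6, 6, 16, 8)
  for (i in seq_along(targets)) {
    cfg <- preset_scenario(names(targets)[i])
    q <- cfg$branching * (1 - cfg$reattach_prob)
    expect_equal(s_vals[i] * (1 + q + q^2 + q^3), unname(targets[i]),
                 tolerance = 1e-6)
  }
})

test_that("provaccine search preset hits the annotated vaccine share", {
  shares <- sapply(1:50, function(s) {
    net <- simulate_crawl(preset_scenario("provaccine_search",
                                          rng_seed = s))$network
    mean(net$nodes$vaccine_related)
  })
  # annotated share of vaccine-related videos in that network: 41/283 = 14%
  expect_lt(abs(mean(shares) - 41 / 283), 0.03)
})

test_that("config validation rejects malformed inputs", {
  expect_error(crawl_sim_config(n_seeds = 2, reattach_prob = 1.2), "reattach")
  cats <- sim_categories()
  H <- matrix(1 / 6, 6, 6, dimnames = list(cats, cats))
  H[1, 1] <- 0.9
  expect_error(crawl_sim_config(n_seeds = 2, category_transition = H),
               "sum to 1")
  bad_seed <- setNames(rep(0.5, 6), cats)
  expect_error(crawl_sim_config(n_seeds = 2, seed_category_dist = bad_seed),
               "probability vector")
})

test_that("JSON config round-trips through read/write", {
  cfg <- preset_scenario("expert_seed", rng_seed = 17)
  path <- tempfile(fileext = ".json")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(back$n_seeds, cfg$n_seeds)
  expect_equal(back$reattach_prob, cfg$reattach_prob, tolerance = 1e-12)
  expect_equal(back$category_transition, cfg$category_transition,
               tolerance = 1e-12)
  expect_equal(back$seed_category_dist, cfg$seed_category_dist,
               tolerance = 1e-12)
  expect_identical(back$rng_seed, cfg$rng_seed)
})
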