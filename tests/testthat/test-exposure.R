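test_that("exposure is the fraction of attribute-bearing neighbours", {
  expect_equal(node_exposure(make_star(4, 3), "z", "stance=anti"), 0.75)
  expect_equal(node_exposure(make_star(4, 0), "z", "stance=anti"), 0)
  expect_equal(node_exposure(make_star(4, 4), "z", "stance=anti"), 1)
  # isolated node: exposure 0 by convention
  net <- rec_network(data.frame(id = c("solo", "a", "b")),
                     data.frame(src = "a", dst = "b"))
  expect_equal(node_exposure(net, "solo", "stance=anti"), 0)
  expect_error(node_exposure(net, "ghost", "stance=anti"), "unknown node")
})

test_that("a node's own attribute does not enter its exposure", {
  ann <- data.frame(id = c("z", "n1", "n2"),
                    vaccine_related = c(TRUE, FALSE, FALSE),
                    stance = c("anti", "none", "none"))
  net <- build_network(data.frame(src = "z", dst = c("n1", "n2")), ann)
  expect_equal(node_exposure(net, "z", "stance=anti"), 0)
})

test_that("exposure equals the brute-force neighbour enumeration oracle", {
  for (seed in 1:6) {
    n <- sample(c(20, 80, 200), 1)
    net <- random_network(n, p_edge = 3 / n, p_attr = 0.3, seed = seed)
    fast <- network_exposure(net, "stance=anti")$values
    slow <- brute_force_exposure(net, "stance=anti")
    expect_equal(fast[names(slow)], slow)
  }
})

test_that("the exposure conservation law holds exactly", {
  for (seed in 1:20) {
    net <- random_network(60, p_edge = 0.05, p_attr = 0.25, seed = seed)
    e <- network_exposure(net, "stance=anti")$values
    deg <- node_degrees(net)
    f <- node_flags(net, "stance=anti")
    expect_identical(sum(e * deg), as.numeric(sum(deg[f])))
  }
})

test_that("attribute extremes give exposure extremes", {
  net <- random_network(50, p_edge = 0.08, seed = 3)
  none <- network_exposure(net, function(d) rep(FALSE, nrow(d)))$values
  expect_true(all(none == 0))
  all_f <- network_exposure(net, function(d) rep(TRUE, nrow(d)))$values
  deg <- node_degrees(net)
  expect_true(all(all_f[deg > 0] == 1))
  expect_true(all(all_f[deg == 0] == 0))
})

test_that("adding an attribute-bearing neighbour never lowers exposure", {
  for (seed in 1:5) {
    net <- random_network(30, p_edge = 0.08, p_attr = 0.3, seed = seed)
    before <- network_exposure(net, "stance=anti")$values
    # attach one new anti node to a random existing node
    set.seed(seed)
    tgt <- sample(net$nodes$id, 1)
    nodes2 <- rbind(net$nodes,
                    normalize_nodes(data.frame(id = "new_anti",
                                               vaccine_related = TRUE,
                                               stance = "anti")))
    edges2 <- rbind(net$edges[, c("src", "dst")],
                    data.frame(src = tgt, dst = "new_anti"))
    net2 <- build_network(edges2, nodes2)
    after <- network_exposure(net2, "stance=anti")$values
    expect_gte(after[[tgt]], before[[tgt]])
  }
})

test_that("exposure summaries reproduce hand arithmetic", {
  s <- exposure_summary(c(0.25, 0.5, 0, 1))
  expect_equal(s$mean, 0.4375)
  expect_equal(s$n_exposed, 3L)
  expect_equal(s$range_over_exposed, c(0.25, 1))
  z <- exposure_summary(rep(0, 10))
  expect_equal(z$mean, 0)
  expect_equal(z$sd, 0)
  expect_equal(z$n_exposed, 0L)
  expect_true(all(is.na(z$range_over_exposed)))
  expect_error(exposure_summary(numeric(0)), "empty")
})

test_that("exposed flags mark exactly the nodes with positive exposure", {
  net <- random_network(80, p_edge = 0.04, p_attr = 0.2, seed = 13)
  res <- network_exposure(net, "stance=anti")
  fl <- exposed_flags(res)
  expect_equal(sum(fl), sum(res$values > 0))
  expect_equal(unname(fl), unname(res$values > 0))
  s <- exposure_summary(res)
  expect_equal(s$n_exposed + sum(!fl), n_nodes(net))
  expect_equal(s$pct_exposed, 100 * sum(fl) / n_nodes(net))
})

test_that("edge weights generalize exposure when supplied", {
  ann <- data.frame(id = c("z", "a", "b"),
                    vaccine_related = c(FALSE, TRUE, FALSE),
                    stance = c("none", "anti", "none"))
  net <- build_network(data.frame(src = c("z", "z"), dst = c("a", "b")), ann)
  # weight the z-a tie 3x: exposure = 3 / 4
  w <- ifelse(net$edges$dst == "a" | net$edges$src == "a", 3, 1)
  e <- network_exposure(net, "stance=anti", weights = w)
  expect_equal(e$values[["z"]], 0.75)
  expect_error(network_exposure(net, "stance=anti", weights = 1:3),
               "one entry per edge")
})
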