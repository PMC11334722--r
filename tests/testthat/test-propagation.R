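test_that("PPR matches the closed-form fixed points on toy graphs", {
  # two nodes u-v, seed u: p(u) = (1-l)/(1-l^2), p(v) = l p(u)
  l <- 0.85
  ix2 <- interactome("u", "v")
  res2 <- personalized_pagerank(ix2, seed_set("u"), damping = l,
                                tolerance = 1e-14)
  pu <- (1 - l) / (1 - l^2)
  expect_equal(unname(res2$p["u"]), pu, tolerance = 1e-10)
  expect_equal(unname(res2$p["v"]), l * pu, tolerance = 1e-10)

  # three-node path u-v-w, seed u:
  #   p_u = (1-l) + l p_v/2;  p_v = l(p_u + p_w);  p_w = l p_v / 2
  # solving: p_u = (1-l)(1 - l^2/2)/(1 - l^2), p_w = p_u - (1-l)
  ix3 <- interactome(c("u", "v"), c("v", "w"))
  res3 <- personalized_pagerank(ix3, seed_set("u"), damping = l,
                                tolerance = 1e-14)
  pu3 <- (1 - l) * (1 - l^2 / 2) / (1 - l^2)
  expect_equal(unname(res3$p["u"]), pu3, tolerance = 1e-10)
  expect_equal(unname(res3$p["w"]), pu3 - (1 - l), tolerance = 1e-10)
  expect_equal(unname(res3$p["v"]), l * (2 * pu3 - (1 - l)),
               tolerance = 1e-10)
})

test_that("PPR conserves probability mass and respects teleport weights", {
  withr::local_seed(4)
  for (rep in 1:5) {
    ix <- random_interactome(30, p = 0.15)
    seeds <- seed_set(sample(ix$nodes, 4L),
                      weights = stats::runif(4, 0.5, 3),
                      interactome = ix)
    res <- personalized_pagerank(ix, seeds)
    expect_true(res$converged)
    expect_equal(sum(res$p), 1, tolerance = 1e-8)
    expect_true(all(res$p >= 0))
  }
  # uniform teleport reproduces plain PageRank (igraph as cross-check)
  ix <- random_interactome(25, p = 0.2)
  mine <- personalized_pagerank(ix, teleport = "uniform", tolerance = 1e-12)
  ig <- igraph::page_rank(as_igraph(ix), damping = 0.85,
                          weights = NA)$vector
  expect_equal(unname(mine$p[names(ig)]), unname(ig), tolerance = 1e-6)
  # seed teleport concentrates mass on the seed side
  s <- seed_set(ix$nodes[1L])
  pers <- personalized_pagerank(ix, s)
  expect_gt(pers$p[ix$nodes[1L]], mine$p[ix$nodes[1L]])
})

test_that("edge flux follows the propagation/confidence/degree formula", {
  # deg(u) = 2, deg(t) = 1 on a path t-u-x with crafted p
  ix <- interactome(c("t", "u"), c("u", "x"), c(1.0, 1.0))
  prop <- structure(list(p = c(t = 0.1, u = 0.5, x = 0.4)),
                    class = "propagation_result")
  tab <- compute_edge_flux(ix, prop, log_base = "10")
  row <- tab[tab$from == "t" & tab$to == "u", ]
  expect_equal(row$flux_forward, 0.1 / 1)     # p(t) c / deg(t)
  expect_equal(row$flux_backward, 0.5 / 2)    # p(u) c / deg(u)
  expect_equal(row$min_flux, 0.1)
  expect_equal(row$score, 1.0)                # -log10(0.1)

  # symmetric endpoints give equal directional fluxes
  sym <- interactome("a", "b", 0.8)
  prop_sym <- structure(list(p = c(a = 0.5, b = 0.5)),
                        class = "propagation_result")
  tab_sym <- compute_edge_flux(sym, prop_sym)
  expect_equal(tab_sym$flux_forward, tab_sym$flux_backward)

  # zero-probability endpoint -> infinite score, excluded from selection
  prop0 <- structure(list(p = c(t = 0, u = 0.6, x = 0.4)),
                     class = "propagation_result")
  tab0 <- compute_edge_flux(ix, prop0)
  expect_true(is.infinite(tab0$score[tab0$from == "t"]))
  ggn_like <- ix
  sel <- select_edges(ggn_like, tab0, tau = 1)
  expect_false("t" %in% sel$network$nodes)
})

test_that("flux is strictly decreasing in the source degree", {
  p <- 0.4; conf <- 0.9
  expect_true(all(diff(p * conf / (1:10)) < 0))
  # and through the API: same p, higher degree -> smaller forward flux
  star <- interactome(rep("h", 3), c("l1", "l2", "l3"))
  pair <- interactome("h", "l1")
  prop <- structure(list(p = c(h = 0.5, l1 = 0.2, l2 = 0.2, l3 = 0.1)),
                    class = "propagation_result")
  f_star <- compute_edge_flux(star, prop)
  f_pair <- compute_edge_flux(pair, prop)
  expect_lt(f_star$flux_forward[f_star$from == "h" & f_star$to == "l1"],
            f_pair$flux_forward[1L])
})

test_that("tau selection follows the budget rule on a hand-worked case", {
  # GGN with min-flux {0.1, 0.01, 0.001} -> base-10 scores {1, 2, 3},
  # F = 6; tau = 0.5 selects the 0.1 and 0.01 edges (cumulative 1 then 3)
  ggn <- interactome(c("a", "b", "c"), c("b", "c", "d"), rep(1, 3))
  scores <- data.frame(
    from = c("a", "b", "c"), to = c("b", "c", "d"),
    confidence = 1, flux_forward = c(0.1, 0.01, 0.001),
    flux_backward = c(0.2, 0.02, 0.002),
    min_flux = c(0.1, 0.01, 0.001), score = c(1, 2, 3),
    stringsAsFactors = FALSE)
  class(scores) <- c("edge_score_table", "data.frame")
  sel <- select_edges(ggn, scores, tau = 0.5)
  expect_equal(sel$total_flux, 6)
  expect_equal(nrow(sel$network$edges), 2L)
  expect_setequal(graphflux:::edge_key(sel$network$edges$from,
                                       sel$network$edges$to),
                  c("a\rb", "b\rc"))
  expect_equal(sel$scores$selected_rank, c(1L, 2L))

  expect_equal(nrow(select_edges(ggn, scores, tau = 0)$network$edges), 0L)
  expect_equal(nrow(select_edges(ggn, scores, tau = 1)$network$edges), 3L)
  expect_error(select_edges(ggn, scores, tau = 1.5), "tau")
})

test_that("selection is nested in tau and contained in GGN and reference", {
  withr::local_seed(11)
  taus <- c(0, 0.25, 0.5, 0.75, 1)
  for (rep in 1:12) {
    inst <- generate_benchmark(n_nodes = 60, pathway_size = 8,
                               seed_fraction = 0.6, rng_seed = rep)
    census <- suppressWarnings(
      graphlet_significance(inst$interactome, inst$seeds,
                            n_permutations = 12, rng_seed = rep))
    ggn <- suppressWarnings(build_ggn(inst$interactome, inst$seeds, census))
    prop <- personalized_pagerank(inst$interactome, inst$seeds)
    scores <- compute_edge_flux(inst$interactome, prop)
    prev <- character()
    for (tau in taus) {
      sel <- suppressWarnings(select_edges(ggn, scores, tau = tau))
      keys <- graphflux:::edge_key(sel$network$edges$from,
                                   sel$network$edges$to)
      expect_true(all(prev %in% keys))              # nestedness
      ggn_keys <- graphflux:::edge_key(ggn$network$edges$from,
                                       ggn$network$edges$to)
      ref_keys <- graphflux:::edge_key(inst$interactome$edges$from,
                                       inst$interactome$edges$to)
      expect_true(all(keys %in% ggn_keys))          # C subset of G
      expect_true(all(ggn_keys %in% ref_keys))      # G subset of R
      prev <- keys
    }
  }
})

test_that("infer is deterministic and chains the three stages", {
  inst <- generate_benchmark(n_nodes = 100, pathway_size = 12,
                             seed_fraction = 0.5, rng_seed = 31)
  f1 <- infer(inst$interactome, inst$seeds, n_permutations = 15,
              rng_seed = 31)
  f2 <- infer(inst$interactome, inst$seeds, n_permutations = 15,
              rng_seed = 31)
  expect_identical(f1$network$network, f2$network$network)
  expect_identical(f1$census$table, f2$census$table)
  expect_true(all(f1$network$network$nodes %in% f1$ggn$network$nodes))
})
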