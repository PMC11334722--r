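test_that("the catalogue lists exactly the connected graphs on 2-4 nodes", {
  cat_ <- graphlet_catalogue()
  expect_length(cat_, 9L)
  orders <- vapply(cat_, `[[`, 0L, "order")
  expect_equal(unname(table(orders)), c(1L, 2L, 6L), ignore_attr = TRUE)
  expect_equal(nrow(cat_$G8$edges), 6L)       # complete 4-clique

  # every pattern is connected and pairwise non-isomorphic
  igs <- lapply(cat_, function(g) {
    igraph::graph_from_edgelist(g$edges, directed = FALSE)
  })
  expect_true(all(vapply(igs, igraph::is_connected, TRUE)))
  for (i in seq_along(igs)) {
    for (j in seq_along(igs)) {
      if (i >= j) next
      same_order <- cat_[[i]]$order == cat_[[j]]$order
      expect_false(same_order && igraph::isomorphic(igs[[i]], igs[[j]]))
    }
  }

  # the intermediate orbit attains the maximum pattern degree
  for (g in cat_) {
    expect_true(all(g$degrees[g$intermediate_orbit] == max(g$degrees)))
  }
})

test_that("constrained counts match hand-worked toy cases", {
  tri <- interactome(c("a", "a", "b"), c("b", "c", "c"))
  s_ab <- seed_set(c("a", "b"), interactome = tri)
  expect_equal(count_constrained(tri, s_ab, "G2")$count, 1L)
  expect_equal(count_constrained(tri, s_ab, "G0")$count, 1L)
  expect_equal(count_constrained(tri, s_ab, "G1")$count, 0L)
  # the G2 match covers the whole triangle
  m <- count_constrained(tri, s_ab, "G2")$matches
  expect_setequal(m$nodes, c("a", "b", "c"))
  expect_equal(nrow(m$edges), 3L)

  path3 <- interactome(c("a", "b"), c("b", "c"))
  s_ac <- seed_set(c("a", "c"), interactome = path3)
  expect_equal(count_constrained(path3, s_ac, "G1")$count, 1L)
  expect_equal(count_constrained(path3, s_ac, "G0")$count, 0L)

  star <- interactome(rep("m", 3), c("s1", "s2", "s3"))
  s_star <- seed_set(c("s1", "s2", "s3"), interactome = star)
  expect_equal(count_constrained(star, s_star, "G4")$count, 1L)
  expect_equal(count_constrained(star, s_star, "G1")$count, 3L)
})

test_that("counts agree with brute-force subset enumeration", {
  withr::local_seed(42)
  for (rep in 1:40) {
    n <- sample(5:12, 1L)
    ix <- random_interactome(n, p = stats::runif(1, 0.2, 0.5))
    n_seeds <- sample(2:min(6L, length(ix$nodes)), 1L)
    seeds <- seed_set(sample(ix$nodes, n_seeds), interactome = ix)
    expect_identical(count_constrained(ix, seeds),
                     oracle_census(ix, names(seeds$weights)))
  }
})

test_that("adding a seed never decreases a constrained count", {
  withr::local_seed(7)
  for (rep in 1:15) {
    ix <- random_interactome(10, p = 0.35)
    base <- sample(ix$nodes, 3L)
    extra <- sample(setdiff(ix$nodes, base), 1L)
    c0 <- count_constrained(ix, seed_set(base, interactome = ix))
    c1 <- count_constrained(ix, seed_set(c(base, extra), interactome = ix))
    expect_true(all(c1 >= c0))
  }
})

test_that("edge swaps preserve the degree sequence and confidence multiset", {
  withr::local_seed(3)
  for (rep in 1:10) {
    ix <- random_interactome(12, p = 0.3)
    pm <- permute_network(ix, swap_factor = 10, rng_seed = rep)
    expect_identical(sort(node_degree(pm, ix$nodes)),
                     sort(node_degree(ix)))
    expect_equal(sort(pm$edges$confidence), sort(ix$edges$confidence))
    expect_equal(nrow(pm$edges), nrow(ix$edges))
  }
})

test_that("a triangle admits no legal swap and is returned unchanged", {
  tri <- interactome(c("a", "a", "b"), c("b", "c", "c"), c(0.5, 0.6, 0.7))
  expect_warning(pm <- permute_network(tri, rng_seed = 1), "no legal")
  expect_identical(pm, tri)
})

test_that("a 4-cycle swap yields the documented rewiring", {
  # ab,bc,cd,da: swapping (ab, cd) -> (ac, bd) gives {ac, bd, bc, da},
  # still a 4-cycle on the same degree sequence
  cyc <- interactome(c("a", "b", "c", "a"), c("b", "c", "d", "d"))
  swapped <- interactome(c("a", "b", "b", "a"), c("c", "d", "c", "d"))
  expect_identical(sort(node_degree(swapped)), sort(node_degree(cyc)))
  g <- as_igraph(swapped)
  expect_true(igraph::isomorphic(g, igraph::make_ring(4)))
})

test_that("z-test significance follows the stated rules", {
  z <- function(obs, counts) (obs - mean(counts)) / stats::sd(counts)
  expect_equal(z(50, c(5, 10, 15)), 8.0)
  expect_true(z(50, c(5, 10, 15)) > 1.65)
  expect_equal(z(10, c(5, 10, 15)), 0)

  # end-to-end: a dense planted region should make some graphlet
  # significant, and sd = 0 columns fall back to the strict-max rule
  inst <- generate_benchmark(n_nodes = 120, pathway_size = 12,
                             seed_fraction = 0.6, rng_seed = 5)
  census <- graphlet_significance(inst$interactome, inst$seeds,
                                  n_permutations = 30, rng_seed = 5)
  tb <- census$table
  expect_true(any(tb$significant))
  expect_true(all(is.finite(tb$z[tb$perm_sd > 0])))
  const <- tb$perm_sd == 0
  if (any(const)) {
    expect_equal(tb$significant[const],
                 unname(tb$observed[const] >
                   apply(census$perm_counts[, const, drop = FALSE], 2, max)))
  }
  # significant graphlets exceed their null mean
  expect_true(all(tb$observed[tb$significant] >= tb$perm_mean[tb$significant]))
})

test_that("census and permutations are reproducible per seed", {
  inst <- generate_benchmark(n_nodes = 100, pathway_size = 10,
                             seed_fraction = 0.5, rng_seed = 9)
  c1 <- graphlet_significance(inst$interactome, inst$seeds,
                              n_permutations = 10, rng_seed = 123)
  c2 <- graphlet_significance(inst$interactome, inst$seeds,
                              n_permutations = 10, rng_seed = 123)
  expect_identical(c1$perm_counts, c2$perm_counts)
  expect_identical(c1$table, c2$table)
  expect_identical(permute_network(inst$interactome, rng_seed = 77),
                   permute_network(inst$interactome, rng_seed = 77))
})

test_that("the GGN is the union of significant matches and sits inside R", {
  # only G2 significant, one triangle match -> GGN is that triangle
  tri_plus <- interactome(c("a", "a", "b", "c"), c("b", "c", "c", "d"),
                          c(0.9, 0.8, 0.7, 0.6))
  seeds <- seed_set(c("a", "b"), interactome = tri_plus)
  census <- suppressWarnings(
    graphlet_significance(tri_plus, seeds, n_permutations = 5, rng_seed = 1))
  census$table$significant <- census$table$graphlet == "G2"
  ggn <- build_ggn(tri_plus, seeds, census)
  expect_setequal(ggn$network$nodes, c("a", "b", "c"))
  expect_equal(nrow(ggn$network$edges), 3L)
  # confidences inherited from the reference
  expect_equal(ggn$network$edges$confidence[
    ggn$network$edges$from == "a" & ggn$network$edges$to == "b"], 0.9)

  # no significant graphlet -> empty GGN with a warning
  census$table$significant <- rep(FALSE, 9L)
  expect_warning(empty <- build_ggn(tri_plus, seeds, census), "empty")
  expect_equal(length(empty$network$nodes), 0L)

  # containment G <= R on a realistic instance
  inst <- generate_benchmark(n_nodes = 150, pathway_size = 15,
                             seed_fraction = 0.5, rng_seed = 21)
  cen <- graphlet_significance(inst$interactome, inst$seeds,
                               n_permutations = 20, rng_seed = 21)
  ggn2 <- build_ggn(inst$interactome, inst$seeds, cen)
  ref_keys <- graphflux:::edge_key(inst$interactome$edges$from,
                                   inst$interactome$edges$to)
  ggn_keys <- graphflux:::edge_key(ggn2$network$edges$from,
                                   ggn2$network$edges$to)
  expect_true(all(ggn_keys %in% ref_keys))
  expect_true(all(ggn2$network$nodes %in% inst$interactome$nodes))
  idx <- match(ggn_keys, ref_keys)
  expect_equal(ggn2$network$edges$confidence,
               inst$interactome$edges$confidence[idx])
})
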