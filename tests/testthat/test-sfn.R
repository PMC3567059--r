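test_that("classroom sizes are balanced, sum to N, larger rooms first", {
  expect_equal(classroom_sizes(108, 6), rep(18, 6))
  s <- classroom_sizes(108, 7)
  expect_equal(sum(s), 108)
  expect_equal(s, c(16L, 16L, 16L, 15L, 15L, 15L, 15L))
  expect_equal(classroom_sizes(5, 5), rep(1, 5))
  expect_error(classroom_sizes(4, 5), "exceed")
})

test_that("within-block probability follows the ER mean-degree identity", {
  expect_equal(intra_group_probability(9.315, 16), 9.315 / 15)
  expect_equal(intra_group_probability(15, 16), 1)
  expect_equal(intra_group_probability(7.518, 35), 0.2211, tolerance = 1e-4)
  expect_error(intra_group_probability(20, 16), "exceed")
  expect_equal(expected_block_clustering(2, 3), 1)
  expect_equal(expected_block_clustering(7.518, 35), 7.518 / 34)
})

test_that("sub-group count triggers only below the clustering threshold", {
  expect_equal(subgroup_count(16, 9.315, 0.25), 1L)
  expect_equal(subgroup_count(40, 4, 0.25), 3L)
  # threshold at or below the block clustering never subdivides
  for (a in c(10, 20, 35)) {
    k <- 6
    u <- intra_group_probability(k, a) * 0.99
    expect_equal(subgroup_count(a, k, u), 1L)
  }
  # the returned s is the smallest admissible one
  s <- subgroup_count(40, 4, 0.25)
  expect_gte(4 / (40 / s - 1), 0.25)
  expect_lt(4 / (40 / (s - 1) - 1), 0.25)
  expect_error(subgroup_count(40, 4, 1.2), "in \\(0, 1\\)")
})

test_that("shortcut rewiring conserves nodes and links exactly", {
  g <- generate_er(60, 0.1, seed = 9)
  expect_true(igraph::identical_graphs(add_shortcuts(g, 0, seed = 1), g))
  for (p in c(0.2, 0.7, 1)) {
    g2 <- add_shortcuts(g, p, seed = round(100 * p))
    expect_equal(igraph::vcount(g2), igraph::vcount(g))
    expect_equal(igraph::ecount(g2), igraph::ecount(g))
    check_school_graph(g2)
  }
  expect_error(add_shortcuts(igraph::make_full_graph(4), 0.5, seed = 1),
               "complete")
})

test_that("SFN edge counts match the N k/2 expectation", {
  pars <- sfn_params(108, 7, 9.315, 0.3)
  sizes <- vapply(1:100, function(s) igraph::ecount(generate_sfn(pars, seed = s)),
                  numeric(1))
  se <- sd(sizes) / sqrt(100)
  expect_lt(abs(mean(sizes) - 108 * 9.315 / 2), 3 * se)
})

test_that("p = 0 leaves isolated classroom blocks; p = 1 looks like ER", {
  pars0 <- sfn_params(108, 7, 9.315, 0)
  g0 <- generate_sfn(pars0, seed = 4)
  expect_gte(igraph::components(g0)$no, 7)
  expect_equal(igraph::vcount(g0), 108)

  pars1 <- sfn_params(108, 7, 9.315, 1)
  set.seed(8)
  cl1 <- replicate(40, igraph::transitivity(generate_sfn(pars1),
                                            type = "localaverage",
                                            isolates = "zero"))
  q <- 9.315 / 107
  expect_lt(abs(mean(cl1) - q), 3 * sd(cl1) / sqrt(40) + 0.01)
})

test_that("clustering decreases monotonically in the shortcut probability", {
  set.seed(15)
  means <- vapply(c(0, 0.3, 0.6, 1), function(p) {
    pars <- sfn_params(108, 7, 9.315, p)
    mean(replicate(40, igraph::transitivity(generate_sfn(pars),
                                            type = "localaverage",
                                            isolates = "zero")))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("degenerate single-classroom SFN is a plain ER graph", {
  pars <- sfn_params(100, 1, 5, 0, u = 0.01)
  g <- generate_sfn(pars, seed = 2)
  expect_equal(igraph::vcount(g), 100)
  # mean degree near 5, no block structure to inflate clustering
  set.seed(3)
  kbar <- replicate(40, mean(igraph::degree(generate_sfn(pars))))
  expect_lt(abs(mean(kbar) - 5), 3 * sd(kbar) / sqrt(40))
})

test_that("subdivided classrooms keep the edge budget", {
  # School3 geometry: classrooms of ~35 students subdivide under u = 0.25
  expect_gt(subgroup_count(35, 7.518, 0.25), 1L)
  pars <- sfn_params(419, 12, 7.518, 0.15)
  sizes <- vapply(1:60, function(s) igraph::ecount(generate_sfn(pars, seed = s)),
                  numeric(1))
  se <- sd(sizes) / sqrt(60)
  expect_lt(abs(mean(sizes) - 419 * 7.518 / 2), 3 * se)
})

test_that("parameter validation rejects inconsistent settings", {
  expect_error(sfn_params(100, 120, 2, 0.1), "exceed")
  expect_error(sfn_params(100, 10, 12, 0.1), "below the mean classroom")
  expect_error(sfn_params(100, 10, 5, 1.5), "probability")
  expect_error(sfn_params(100, 10, 5, 0.1, u = 1.5), "in \\(0, 1\\)")
})
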