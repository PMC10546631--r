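test_that("graph-mode population realises degrees and mixing targets", {
  pc <- population_config(800,
    traits = list(trait = list(labels = c("a", "b"), prevalence = c(0.5, 0.5))),
    degree_mu = 6, assortativity = 1)
  pop <- generate_population(pc, rng_seed = 2, mode = "graph")
  d <- pop$individuals$degree
  if (sum(d) %% 2 == 1) d[1] <- d[1] + 1L
  expect_equal(igraph::degree(pop$graph), d)   # configuration-model property
  el <- igraph::as_edgelist(pop$graph, names = FALSE)
  cats <- pop$individuals$trait
  same <- mean(cats[el[, 1]] == cats[el[, 2]])
  q <- tapply(d, cats, sum) / sum(d)
  expect_lt(abs(same - sum(q^2)), 0.011)       # proportionate mixing at h = 1

  # strong same-group preference pushes the same-category fraction up
  pc2 <- population_config(800,
    traits = list(trait = list(labels = c("a", "b"), prevalence = c(0.5, 0.5))),
    degree_mu = 6, assortativity = 1.8)
  pop2 <- generate_population(pc2, rng_seed = 2, mode = "graph")
  el2 <- igraph::as_edgelist(pop2$graph, names = FALSE)
  cats2 <- pop2$individuals$trait
  same2 <- mean(cats2[el2[, 1]] == cats2[el2[, 2]])
  expect_gt(same2, same + 0.2)

  # unreachable target errors with the achieved level attached
  pc3 <- population_config(200,
    traits = list(trait = list(labels = c("a", "b"), prevalence = c(0.5, 0.5))),
    degree_mu = 6, assortativity = 10)
  err <- tryCatch(generate_population(pc3, rng_seed = 1, mode = "graph"),
                  webrds_error_assortativity = identity)
  expect_s3_class(err, "webrds_error_assortativity")
  expect_true(is.numeric(err$achieved))
})

test_that("markov-mode mixing matrix is a proper stochastic matrix", {
  pc <- default_pop()
  pop <- generate_population(pc, rng_seed = 1, mode = "markov")
  M <- pop$mixing
  expect_equal(rowSums(M), c(a = 1, b = 1))
  # h = 1: every row equals the degree-weighted shares
  q <- c(0.3 * 8, 0.7 * 4) / (0.3 * 8 + 0.7 * 4)
  expect_equal(unname(M[1, ]), q, tolerance = 1e-12)
  expect_equal(unname(M[2, ]), q, tolerance = 1e-12)
})

test_that("identical seed and config give byte-identical outputs", {
  pc <- default_pop(size = 600)
  for (mode in c("graph", "markov")) {
    pop1 <- generate_population(pc, rng_seed = 4, mode = mode)
    pop2 <- generate_population(pc, rng_seed = 4, mode = mode)
    expect_identical(pop1$individuals, pop2$individuals)
    cfg <- sim_config(n_seeds = 4, mode = mode, max_sample = 120, rng_seed = 7)
    s1 <- simulate_recruitment(pop1, cfg)
    s2 <- simulate_recruitment(pop2, cfg)
    expect_identical(responses(s1), responses(s2))
    expect_identical(participants(s1), participants(s2))
    s3 <- simulate_recruitment(pop1, sim_config(n_seeds = 4, mode = mode,
                                                max_sample = 120, rng_seed = 8))
    expect_false(identical(responses(s3)$token, responses(s1)$token))
  }
})

test_that("participation 0 enrolls only seeds; p = 1 markov gives full ternary trees", {
  pc <- default_pop(size = 500)
  pop <- generate_population(pc, rng_seed = 1, mode = "markov")
  s0 <- NULL
  expect_warning(
    s0 <- simulate_recruitment(pop, sim_config(n_seeds = 5, mode = "markov",
                                               participation_prob = 0,
                                               rng_seed = 1)),
    "extinct")
  expect_equal(nrow(responses(s0)), 5)
  expect_true(all(sim_forest(s0)$nodes$wave == 0))

  # p = 1, max_waves = w -> each seed tree has (3^(w+1) - 1) / 2 nodes
  for (w in 1:3) {
    s1 <- simulate_recruitment(pop, sim_config(
      n_seeds = 2, mode = "markov", participation_prob = 1,
      max_waves = w, rng_seed = 3))
    m <- recruitment_metrics(sim_forest(s1))
    expect_equal(nrow(responses(s1)), 2 * (3^(w + 1) - 1) / 2)
    expect_equal(m$chain_length_max, w)
  }
})

test_that("simulator output honours coupon and graph constraints", {
  pc <- default_pop(size = 900)
  pop <- generate_population(pc, rng_seed = 6, mode = "graph")
  sim <- simulate_recruitment(pop, sim_config(n_seeds = 6, mode = "graph",
                                              max_sample = 400, rng_seed = 11))
  f <- sim_forest(sim)
  m <- recruitment_metrics(f)
  # max out-degree bounded by the coupon budget
  expect_lte(max(as.integer(names(m$out_degree_histogram))), 3)
  # nobody enrolled twice
  expect_equal(anyDuplicated(responses(sim)$id), 0)
  # every ledger invariant holds on simulator output by construction
  expect_true(coupon_conservation(sim$study)$balanced)
  ed <- f$nodes[!is.na(f$nodes$recruiter_id), ]
  pw <- f$nodes$wave[match(ed$recruiter_id, f$nodes$participant_id)]
  expect_equal(ed$wave, pw + 1L)
  # degrees reported are the true graph degrees by default
  r <- responses(sim)
  expect_equal(r$degree_contactable, r$degree_known)
})

test_that("misreporting perturbs reported degree but keeps it positive", {
  pc <- default_pop(size = 500)
  pop <- generate_population(pc, rng_seed = 2, mode = "markov")
  sim <- simulate_recruitment(pop, sim_config(
    n_seeds = 4, mode = "markov", max_sample = 150, rng_seed = 5,
    misreport_sdlog = 0.4))
  r <- responses(sim)
  expect_true(all(r$degree_contactable >= 1))
  expect_true(all(r$degree_contactable <= r$degree_known))
  expect_gt(sum(r$degree_contactable != r$degree_known), 0)
})

test_that("seeds can be added midstream and non-recruiting seeds removed", {
  pc <- default_pop(size = 700)
  pop <- generate_population(pc, rng_seed = 3, mode = "graph")
  sim <- simulate_recruitment(pop, sim_config(n_seeds = 3, mode = "graph",
                                              max_sample = 60, rng_seed = 2))
  m0 <- recruitment_metrics(sim_forest(sim))
  res <- add_seed_midstream(sim)
  m1 <- recruitment_metrics(sim_forest(sim))
  # only the new one-node tree differs
  expect_equal(m1$n_total, m0$n_total + 1)
  expect_equal(m1$n_seeds, m0$n_seeds + 1)
  expect_equal(m1$chain_lengths[names(m0$chain_lengths)], m0$chain_lengths)
  expect_equal(unname(m1$chain_lengths[as.character(res$participant_id)]), 0L)

  # removing the non-recruiting seed restores tree count; metrics recompute
  remove_seed(sim, res$participant_id)
  m2 <- recruitment_metrics(sim_forest(sim))
  expect_equal(m2$n_total, m0$n_total)
  expect_equal(m2$n_seeds, m0$n_seeds)
  expect_equal(m2$out_degree_histogram, m0$out_degree_histogram)
  # a recruiting seed is protected
  recruiting <- sim_forest(sim)$nodes
  sid <- recruiting$seed_id[recruiting$wave == 1][1]
  expect_error(remove_seed(sim, sid), class = "webrds_error_validation")
  expect_error(remove_seed(sim, 99999), class = "webrds_error_not_found")

  # field scenario: 8 initial + 6 added - 1 non-recruiting = 13 trees
  pop2 <- generate_population(default_pop(size = 2000), rng_seed = 9,
                              mode = "markov")
  sim2 <- simulate_recruitment(pop2, sim_config(n_seeds = 8, mode = "markov",
                                                max_sample = 150, rng_seed = 13))
  added <- replicate(6, add_seed_midstream(sim2)$participant_id)
  run_recruitment(sim2)
  f2 <- sim_forest(sim2)
  sizes <- table(f2$nodes$seed_id)
  lone <- names(sizes)[sizes == 1]
  if (length(lone)) remove_seed(sim2, as.integer(lone[1]))
  m <- recruitment_metrics(sim_forest(sim2))
  expect_equal(m$n_seeds, 14L - as.integer(length(lone) > 0))
})
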