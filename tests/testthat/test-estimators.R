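test_that("RDS-II matches hand-computed inverse-degree weights", {
  # group a degrees {2,2}, group b degrees {4,4} -> p_a = 1/(1+0.5) = 2/3
  r <- response_table(c("a", "a", "b", "b"), c(2, 2, 4, 4))
  est <- rds_ii_estimate(r, variable = "trait", exclude_seeds = FALSE)
  expect_equal(est$estimates$estimate[est$estimates$category == "a"],
               2 / 3, tolerance = 1e-12)
  expect_equal(est$n_used, 4)
  expect_equal(sum(est$estimates$estimate), 1, tolerance = 1e-9)
  expect_true(all(est$weights$weight > 0))

  # equal degrees -> unweighted sample proportions
  r2 <- response_table(c("a", "a", "a", "b"), rep(5, 4))
  est2 <- rds_ii_estimate(r2, variable = "trait", exclude_seeds = FALSE)
  expect_equal(est2$estimates$estimate, c(0.75, 0.25))

  # single category -> 1.0
  r3 <- response_table(rep("a", 3), c(1, 2, 3))
  est3 <- rds_ii_estimate(r3, variable = "trait", exclude_seeds = FALSE)
  expect_equal(est3$estimates$estimate, 1)
})

test_that("exclusion rules: seeds, zero/missing degrees, missing categories", {
  r <- response_table(c("a", "b", "a", NA, "b"), c(2, 4, 0, 3, NA),
                      token = c(NA, "tk", "tk", "tk", "tk"))
  est <- rds_ii_estimate(r, variable = "trait")   # exclude_seeds default TRUE
  expect_equal(est$n_used, 1)                      # only row 2 usable
  expect_equal(est$n_excluded, 4)
  expect_equal(unname(est$exclusion_reasons["seed"]), 1)
  expect_equal(unname(est$exclusion_reasons["missing_category"]), 1)
  expect_equal(unname(est$exclusion_reasons["zero_or_missing_degree"]), 2)
  # keeping seeds brings row 1 back
  est2 <- rds_ii_estimate(r, variable = "trait", exclude_seeds = FALSE)
  expect_equal(est2$n_used, 2)
  # all excluded -> typed error with the reason tally
  r3 <- response_table("a", 0)
  err <- tryCatch(rds_ii_estimate(r3, variable = "trait", exclude_seeds = FALSE),
                  webrds_error_validation = identity)
  expect_s3_class(err, "webrds_error_validation")
  expect_error(rds_ii_estimate(r, variable = "ghost"),
               class = "webrds_error_validation")
})

test_that("estimates are degree-scale invariant and match an independent oracle", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    tr <- sample(c("a", "b", "c"), n, TRUE)
    dg <- sample(1:12, n, TRUE)
    r <- response_table(tr, dg)
    est <- rds_ii_estimate(r, variable = "trait", exclude_seeds = FALSE)
    want <- oracle_rds_ii(tr, dg)
    expect_equal(setNames(est$estimates$estimate, est$estimates$category),
                 want, tolerance = 1e-12)
    # multiply every degree by a constant -> unchanged
    r5 <- response_table(tr, dg * 7)
    est5 <- rds_ii_estimate(r5, variable = "trait", exclude_seeds = FALSE)
    expect_equal(est5$estimates$estimate, est$estimates$estimate,
                 tolerance = 1e-12)
  }
})

make_sim_data <- function(seed = 5, n = 300, h = 1, prev_a = 0.4) {
  pc <- population_config(1500,
    traits = list(trait = list(labels = c("a", "b"),
                               prevalence = c(prev_a, 1 - prev_a))),
    degree_mu = c(a = 8, b = 5), assortativity = h)
  pop <- generate_population(pc, rng_seed = seed, mode = "markov")
  sim <- simulate_recruitment(pop, sim_config(n_seeds = 6, mode = "markov",
                                              max_sample = n, rng_seed = seed))
  list(responses = responses(sim), forest = sim_forest(sim))
}

test_that("chain bootstrap is reproducible and handles degenerate cases", {
  d <- make_sim_data()
  b1 <- chain_bootstrap_ci(d$responses, d$forest, "trait", replicates = 100,
                           seed = 123)
  b2 <- chain_bootstrap_ci(d$responses, d$forest, "trait", replicates = 100,
                           seed = 123)
  expect_identical(b1$estimates, b2$estimates)
  b3 <- chain_bootstrap_ci(d$responses, d$forest, "trait", replicates = 100,
                           seed = 124)
  expect_false(identical(b3$estimates$ci_low, b1$estimates$ci_low))
  expect_true(all(b1$estimates$ci_low <= b1$estimates$estimate + 0.05))
  expect_true(all(b1$estimates$ci_high >= b1$estimates$estimate - 0.05))

  # replicates = 1 -> degenerate percentile interval
  b4 <- chain_bootstrap_ci(d$responses, d$forest, "trait", replicates = 1,
                           seed = 9)
  expect_equal(b4$estimates$ci_low, b4$estimates$ci_high)

  # constant variable -> CI collapses at 1
  r <- d$responses
  r$konst <- "same"
  b5 <- chain_bootstrap_ci(r, d$forest, "konst", replicates = 50, seed = 1)
  expect_equal(b5$estimates$ci_low, 1)
  expect_equal(b5$estimates$ci_high, 1)

  # fewer than 2 usable edges -> typed error
  r2 <- response_table(c("a", "b"), c(2, 3))
  f2 <- forest_from_edges(1:2, c(NA, NA))
  expect_error(chain_bootstrap_ci(r2, f2, "trait", replicates = 10, seed = 1,
                                  exclude_seeds = FALSE),
               class = "webrds_error_validation")
})

test_that("homophily: constant, perfectly assortative and null cases", {
  # perfectly assortative two equal groups -> H = 2
  # two seeds, each recruiting a 3-chain of their own category
  ids <- 1:8
  parents <- c(NA, 1, 2, 3, NA, 5, 6, 7)
  f <- forest_from_edges(ids, parents)
  r <- response_table(c("a", "a", "a", "a", "b", "b", "b", "b"),
                      rep(4, 8), id = ids)
  h <- recruitment_homophily(r, f, "trait")
  expect_equal(h$ratio, 2)
  expect_equal(h$observed_same, 6)
  expect_equal(h$n_edges, 6)

  # constant variable -> exactly 1
  r$konst <- "k"
  expect_identical(recruitment_homophily(r, f, "konst")$ratio, 1)

  # no usable edges -> error
  f0 <- forest_from_edges(1:2, c(NA, NA))
  expect_error(recruitment_homophily(r[1:2, ], f0, "trait"),
               class = "webrds_error_validation")

  # permutation null centres at 1
  set.seed(33)
  n <- 400
  parents <- c(NA, vapply(2:n, function(i) sample(i - 1, 1), integer(1)))
  fbig <- forest_from_edges(1:n, parents)
  rbig <- response_table(sample(c("a", "b"), n, TRUE), rep(5, n))
  hs <- vapply(1:200, function(k) {
    rperm <- rbig
    rperm$trait <- sample(rperm$trait)
    recruitment_homophily(rperm, fbig, "trait")$ratio
  }, numeric(1))
  expect_lt(abs(mean(hs) - 1), 0.05)
})

test_that("include_seed_edges flag drops seed-origin edges", {
  ids <- 1:4
  f <- forest_from_edges(ids, c(NA, 1, 2, 3))
  r <- response_table(c("a", "b", "b", "b"), rep(3, 4), id = ids)
  h_all <- recruitment_homophily(r, f, "trait")
  h_ns <- recruitment_homophily(r, f, "trait", include_seed_edges = FALSE)
  expect_equal(h_all$n_edges, 3)
  expect_equal(h_ns$n_edges, 2)
  expect_equal(h_ns$observed_same, 2)
})

test_that("convergence series ends at the full-sample estimate", {
  d <- make_sim_data(seed = 8, n = 200)
  ser <- convergence_series(d$responses, d$forest, "trait", min_n = 10)
  full <- rds_ii_estimate(d$responses, d$forest, "trait")
  last <- ser[ser$k == max(ser$k), ]
  expect_equal(
    last$estimate[match(full$estimates$category, last$category)],
    full$estimates$estimate, tolerance = 1e-12)
  # prefix estimates match brute-force recomputation at a few k
  ord <- order(d$responses$submitdate, d$responses$id)
  sorted <- d$responses[ord, ]
  for (k in c(25, 80, 150)) {
    sub <- sorted[seq_len(k), ]
    esub <- rds_ii_estimate(sub, d$forest, "trait")
    at_k <- ser[ser$k == k, ]
    expect_equal(
      at_k$estimate[match(esub$estimates$category, at_k$category)],
      esub$estimates$estimate, tolerance = 1e-12)
  }
  # constant variable -> flat series at 1
  rkonst <- d$responses
  rkonst$konst <- "k"
  serk <- convergence_series(rkonst, d$forest, "konst", min_n = 5)
  # NA only while no usable (non-seed) respondent has accrued yet
  expect_true(all(serk$estimate[!is.na(serk$estimate)] == 1))
  expect_equal(serk$estimate[serk$k == max(serk$k)], 1)
  # unsortable timestamps -> error
  bad <- d$responses
  bad$submitdate[3] <- NA
  expect_error(convergence_series(bad, d$forest, "trait"),
               class = "webrds_error_validation")
})

test_that("bottleneck series splits by seed tree", {
  # two trees with disjoint categories -> per-tree endpoint estimates 1/0
  ids <- 1:10
  parents <- c(NA, 1, 2, 3, 4, NA, 6, 7, 8, 9)
  f <- forest_from_edges(ids, parents)
  r <- response_table(c(rep("a", 5), rep("b", 5)), rep(4, 10), id = ids)
  ser <- suppressMessages(bottleneck_series(r, f, "trait", min_n = 2))
  expect_setequal(unique(ser$seed_id), c(1L, 6L))
  end1 <- ser[ser$seed_id == 1 & ser$k == 5 & ser$category == "a", ]
  expect_equal(end1$estimate, 1)
  expect_false("a" %in% ser$category[ser$seed_id == 6])

  # one-seed forest: identical to plain convergence series
  d <- make_sim_data(seed = 21, n = 60)
  one_seed <- d$forest$nodes$seed_id ==
    d$forest$nodes$seed_id[which.max(table(d$forest$nodes$seed_id))[1]]
  # restrict to the largest tree
  keep <- d$forest$nodes$participant_id[one_seed]
  rsub <- d$responses[d$responses$id %in% keep, ]
  fsub <- subset_forest(d$forest, keep)
  ser1 <- suppressMessages(bottleneck_series(rsub, fsub, "trait", min_n = 5))
  ser2 <- convergence_series(rsub, fsub, "trait", min_n = 5)
  expect_equal(ser1[, c("k", "category", "estimate")], ser2,
               ignore_attr = TRUE)

  # small trees are omitted with a notice
  expect_message(bottleneck_series(r, f, "trait", min_n = 6), "Omitting")
})


test_that("diagnostic descriptives match direct tabulation", {
  r <- response_table(c("a", "b", "a"), c(3, 4, 5))
  r$prior_known <- c(0L, 2L, 4L)
  r$reciprocity <- c(TRUE, TRUE, FALSE)
  d <- diagnostics_descriptives(r)
  expect_equal(d$prior_known$mean, 2)
  expect_equal(d$prior_known$max, 4)
  expect_equal(d$prior_known$distribution, c(`0` = 1L, `2` = 1L, `4` = 1L))
  expect_equal(d$reciprocity$share_yes_pct, 66.7)
  # all zero / all yes
  r2 <- response_table(c("a", "b"), c(1, 2))
  r2$prior_known <- c(0L, 0L)
  r2$reciprocity <- c(TRUE, TRUE)
  d2 <- diagnostics_descriptives(r2)
  expect_equal(d2$prior_known$mean, 0)
  expect_equal(d2$reciprocity$share_yes_pct, 100)
})

test_that("plot helper returns a ggplot for both series shapes", {
  d <- make_sim_data(seed = 13, n = 80)
  ser <- convergence_series(d$responses, d$forest, "trait", min_n = 10)
  expect_s3_class(plot_convergence(ser), "ggplot")
  bser <- suppressMessages(bottleneck_series(d$responses, d$forest, "trait",
                                             min_n = 10))
  expect_s3_class(plot_convergence(bser), "ggplot")
})
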