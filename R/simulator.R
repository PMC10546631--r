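#' Configure a synthetic target population
#'
#' Describes the hidden population the recruitment simulator samples from:
#' its size, one or more categorical traits with prevalences, a per-category
#' degree distribution (negative binomial, the standard overdispersed choice
#' for personal network sizes), and an assortativity knob.
#'
#' The first trait listed is the *primary* trait: degree means are keyed by
#' its categories and assortative mixing acts on it.  `assortativity = 1`
#' means proportionate (random) mixing; values above 1 inflate the
#' probability of same-category contacts.
#'
#' No field degree distribution is available for populations like homecare
#' workers, so the defaults (negative binomial, mean 8, dispersion 1.5) are
#' placeholders chosen to be realistic for a well-connected occupational
#' group; treat them as a starting point, not an empirical claim.
#'
#' @param size Population size N.
#' @param traits Named list; each element is a list with `labels` (category
#'   names) and `prevalence` (probabilities summing to 1).
#' @param degree_mu Named numeric vector of mean degrees per category of the
#'   primary trait (single unnamed value recycles to all categories).
#' @param degree_size Negative-binomial dispersion (smaller = more
#'   overdispersed). Degrees are floored at 1 so everyone is reachable.
#' @param assortativity h >= 0; 1 = proportionate mixing.
#' @return A `population_config` list.
#' @export
population_config <- function(size,
                              traits = list(trait = list(
                                labels = c("a", "b"), prevalence = c(0.5, 0.5))),
                              degree_mu = 8, degree_size = 1.5,
                              assortativity = 1) {
  stopifnot(size >= 1, length(traits) >= 1, !is.null(names(traits)),
            assortativity >= 0, degree_size > 0)
  for (tr in traits) {
    stopifnot(length(tr$labels) == length(tr$prevalence),
              abs(sum(tr$prevalence) - 1) < 1e-8, all(tr$prevalence >= 0))
  }
  primary <- traits[[1]]
  if (is.null(names(degree_mu))) {
    stopifnot(length(degree_mu) %in% c(1L, length(primary$labels)))
    degree_mu <- setNames(rep_len(degree_mu, length(primary$labels)),
                          primary$labels)
  }
  stopifnot(setequal(names(degree_mu), primary$labels), all(degree_mu >= 1))
  structure(list(size = as.integer(size), traits = traits,
                 primary_var = names(traits)[1],
                 degree_mu = degree_mu, degree_size = degree_size,
                 assortativity = assortativity),
            class = "population_config")
}

#' Configure the coupon-limited referral process
#'
#' @param n_seeds Number of initial seeds.
#' @param coupons Invitation uses per recruiter (default 3).
#' @param participation_prob Probability an invited contact completes the
#'   survey. Default 0.6, a plausible conversion rate for a motivated,
#'   well-connected population recruited without monetary incentives.
#' @param max_sample Stop once this many respondents are enrolled.
#' @param max_waves Respondents at this wave do not recruit further.
#' @param mode `"graph"` simulates referral over an explicit contact graph
#'   (finite population, without-replacement enrollment); `"markov"` is the
#'   with-replacement random-walk regime of RDS theory — categories follow
#'   the mixing matrix and degrees are drawn size-biased, which is the clean
#'   setting for estimator-recovery experiments.
#' @param rng_seed Integer seed; identical seed and configs give
#'   byte-identical output tables.
#' @param seed_selection How initial seeds are chosen from the population:
#'   `"degree-weighted"` (probability proportional to degree),
#'   `"uniform"`, or `"diverse-profile"` (highest-degree individual of each
#'   primary category, round-robin).
#' @param misreport_sdlog Standard deviation (log scale) of multiplicative
#'   lognormal noise applied to the reported contactable degree; 0 (default)
#'   reports the true degree.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_seeds = 8, coupons = 3, participation_prob = 0.6,
                       max_sample = Inf, max_waves = Inf,
                       mode = c("graph", "markov"), rng_seed = 1,
                       seed_selection = c("degree-weighted", "uniform",
                                          "diverse-profile"),
                       misreport_sdlog = 0) {
  mode <- match.arg(mode)
  seed_selection <- match.arg(seed_selection)
  stopifnot(n_seeds >= 1, coupons >= 1,
            participation_prob >= 0, participation_prob <= 1,
            misreport_sdlog >= 0)
  structure(list(n_seeds = as.integer(n_seeds), coupons = as.integer(coupons),
                 participation_prob = participation_prob,
                 max_sample = max_sample, max_waves = max_waves, mode = mode,
                 rng_seed = as.integer(rng_seed),
                 seed_selection = seed_selection,
                 misreport_sdlog = misreport_sdlog),
            class = "sim_config")
}

# Zero-truncated negative-binomial degrees.
sample_degrees <- function(n, mu, size) {
  d <- rnbinom(n, mu = mu, size = size)
  d[d == 0L] <- 1L
  d
}

#' Generate a synthetic assortative population
#'
#' Graph mode builds an explicit contact network: degrees are sampled per
#' category, a simple configuration-model graph realises them exactly, and
#' degree-preserving double-edge swaps rewire the graph until the
#' same-category edge fraction is within ±0.01 of the target implied by the
#' assortativity parameter (h times the proportionate-mixing fraction,
#' capped at 1).  Markov mode skips the graph and derives a
#' category-mixing matrix from h and the degree-weighted prevalences.
#'
#' @param config A [population_config()].
#' @param rng_seed Integer seed.
#' @param mode `"graph"` or `"markov"` (see [sim_config()]).
#' @return An `rds_population`: list with `individuals` (tibble `id`, trait
#'   columns, `degree`), `graph` (igraph or `NULL`), `mixing` (matrix or
#'   `NULL`), `config`, `mode`.
#' @section Errors: if bounded rewiring cannot reach the assortativity
#'   target, a `webrds_error_assortativity` condition reports the achieved
#'   same-category fraction.
#' @export
generate_population <- function(config, rng_seed = 1,
                                mode = c("graph", "markov")) {
  stopifnot(inherits(config, "population_config"))
  mode <- match.arg(mode)
  withr::with_seed(as.integer(rng_seed), {
    N <- config$size
    ind <- tibble(id = seq_len(N))
    for (v in names(config$traits)) {
      tr <- config$traits[[v]]
      ind[[v]] <- sample(tr$labels, N, replace = TRUE, prob = tr$prevalence)
    }
    pcat <- ind[[config$primary_var]]
    ind$degree <- sample_degrees(N, config$degree_mu[pcat], config$degree_size)

    if (mode == "markov") {
      labs <- config$traits[[1]]$labels
      prev <- config$traits[[1]]$prevalence
      q <- prev * config$degree_mu[labs]   # degree-weighted category shares
      q <- q / sum(q)
      h <- config$assortativity
      M <- outer(rep(1, length(labs)), q)
      diag(M) <- diag(M) * h
      M <- M / rowSums(M)
      dimnames(M) <- list(labs, labs)
      pop <- list(individuals = ind, graph = NULL, mixing = M,
                  config = config, mode = "markov")
    } else {
      deg <- ind$degree
      if (sum(deg) %% 2 == 1) deg[1] <- deg[1] + 1L
      g <- tryCatch(igraph::sample_degseq(deg, method = "vl"),
                    error = function(e)
                      igraph::sample_degseq(deg, method = "fast.heur.simple"))
      g <- rewire_to_assortativity(g, pcat, deg, config$assortativity)
      pop <- list(individuals = ind, graph = g, mixing = NULL,
                  config = config, mode = "graph")
    }
    structure(pop, class = "rds_population")
  })
}

#' @export
print.rds_population <- function(x, ...) {
  cat(sprintf("<rds_population> N = %d (%s mode), primary trait '%s', h = %g\n",
              x$config$size, x$mode, x$config$primary_var,
              x$config$assortativity))
  invisible(x)
}

# Degree-preserving double-edge swaps toward a target same-category edge
# fraction.  Target: h * proportionate-mixing fraction (degree-weighted),
# capped at 1; tolerance ±0.01.
rewire_to_assortativity <- function(g, pcat, deg, h, tol = 0.01,
                                    max_iter = NULL) {
  q <- tapply(deg, pcat, sum) / sum(deg)
  target <- min(h * sum(q^2), 1)
  el <- igraph::as_edgelist(g, names = FALSE)
  nE <- nrow(el)
  if (nE == 0) return(g)
  same <- pcat[el[, 1]] == pcat[el[, 2]]
  frac <- mean(same)
  if (abs(frac - target) <= tol) return(g)
  max_iter <- max_iter %||% (400L * nE)
  ekey <- new.env(hash = TRUE, parent = emptyenv())
  kf <- function(a, b) paste0(min(a, b), "_", max(a, b))
  for (i in seq_len(nE)) assign(kf(el[i, 1], el[i, 2]), TRUE, envir = ekey)
  want_up <- target > frac
  it <- 0L
  while (abs(frac - target) > tol && it < max_iter) {
    it <- it + 1L
    ij <- sample.int(nE, 2L)
    a <- el[ij[1], 1]; b <- el[ij[1], 2]
    c <- el[ij[2], 1]; d <- el[ij[2], 2]
    # propose (a,d) and (c,b)
    if (a == d || c == b) next
    if (!is.null(ekey[[kf(a, d)]]) || !is.null(ekey[[kf(c, b)]])) next
    old_same <- (pcat[a] == pcat[b]) + (pcat[c] == pcat[d])
    new_same <- (pcat[a] == pcat[d]) + (pcat[c] == pcat[b])
    delta <- new_same - old_same
    if ((want_up && delta <= 0) || (!want_up && delta >= 0)) next
    rm(list = c(kf(a, b), kf(c, d)), envir = ekey)
    assign(kf(a, d), TRUE, envir = ekey)
    assign(kf(c, b), TRUE, envir = ekey)
    el[ij[1], 2] <- d
    el[ij[2], 2] <- b
    frac <- frac + delta / nE
  }
  if (abs(frac - target) > tol)
    stop_webrds(sprintf(
      "Assortativity target %.3f unreachable by rewiring; achieved same-category fraction %.3f.",
      target, frac), "assortativity", achieved = frac, target = target)
  igraph::graph_from_edgelist(el, directed = FALSE)
}

# Size-biased degree sampler for markov mode: P(d) proportional to
# d * f(d) over the zero-truncated support.
size_biased_degree_sampler <- function(mu, size) {
  dmax <- max(stats::qnbinom(0.99999, mu = mu, size = size), 2L)
  supp <- seq_len(dmax)
  f <- stats::dnbinom(supp, mu = mu, size = size)
  f[1] <- f[1] + stats::dnbinom(0, mu = mu, size = size)  # mass of floored zeros
  p <- supp * f
  p <- p / sum(p)
  function(n) sample(supp, n, replace = TRUE, prob = p)
}

#' Simulate coupon-limited recruitment
#'
#' Runs the chained-referral process over a synthetic population: seeds are
#' enrolled, each respondent receives an invitation token with `coupons`
#' uses and offers it to contacts, each invitation converts with
#' `participation_prob`, and every enrollment passes through the coupon
#' engine ([redeem_token()] then [complete_response()]) so all token-ledger
#' invariants hold for the output by construction.  Recruitment proceeds in
#' wave order and stops at `max_sample`, `max_waves`, or when all chains die
#' out (extinction with only seeds enrolled yields a warning, not an error).
#'
#' Submission timestamps are synthetic: enrollment-ordered increments (about
#' ten minutes apart with uniform jitter) from an April 2022 origin, so
#' convergence series are well defined.
#'
#' @param population An [generate_population()] result (its mode must match
#'   `config$mode`).
#' @param config A [sim_config()].
#' @return An `rds_simulation` environment with fields `study`
#'   ([rds_study()]), `population`, `config`; use [participants()],
#'   [responses()] and [sim_forest()] to extract the tables, and
#'   [add_seed_midstream()], [remove_seed()], [run_recruitment()] to
#'   continue a run.
#' @export
simulate_recruitment <- function(population, config) {
  stopifnot(inherits(population, "rds_population"),
            inherits(config, "sim_config"))
  if (population$mode != config$mode)
    stop_webrds(sprintf("Population was generated in '%s' mode but config asks for '%s'.",
                        population$mode, config$mode), "validation")
  if (config$n_seeds > population$config$size)
    stop_webrds("More seeds requested than individuals in the population.",
                "validation")
  sim <- new.env(parent = emptyenv())
  sim$population <- population
  sim$config <- config
  sim$study <- rds_study(coupon_budget = config$coupons)
  sim$enrolled <- logical(population$config$size)
  sim$frontier <- list()   # FIFO of list(pid, token, node, cat, wave)
  sim$clock <- as_time_num(as.POSIXct("2022-04-01 09:00:00", tz = "UTC"))
  sim$n_enrolled <- 0L
  sim$samplers <- NULL
  class(sim) <- "rds_simulation"
  withr::with_seed(config$rng_seed, {
    init_seeds(sim)
    run_recruitment(sim, reseed = FALSE)
  })
  if (sim$n_enrolled <= config$n_seeds)
    warn("Recruitment went extinct before any non-seed enrollment; forest is isolated seeds.")
  sim
}

#' @export
print.rds_simulation <- function(x, ...) {
  cat(sprintf("<rds_simulation> %d enrolled (%s mode), %d in frontier\n",
              x$n_enrolled, x$config$mode, length(x$frontier)))
  invisible(x)
}

tick <- function(sim) {
  sim$clock <- sim$clock + 600 + runif(1, 0, 300)
  num_to_time(sim$clock)
}

reported_degree <- function(sim, d) {
  sdlog <- sim$config$misreport_sdlog
  if (sdlog <= 0) return(as.integer(d))
  max(1L, as.integer(round(d * exp(rnorm(1, 0, sdlog)))))
}

individual_attributes <- function(pop, i) {
  vars <- names(pop$config$traits)
  setNames(as.list(vapply(vars, function(v) pop$individuals[[v]][i],
                          character(1))), vars)
}

enroll <- function(sim, node, cat, degree, receipt = NULL) {
  pop <- sim$population
  rep_deg <- reported_degree(sim, degree)
  if (!is.null(node)) {
    attrs <- individual_attributes(pop, node)
  } else {
    attrs <- list()
    attrs[[pop$config$primary_var]] <- cat
    for (v in setdiff(names(pop$config$traits), pop$config$primary_var)) {
      tr <- pop$config$traits[[v]]
      attrs[[v]] <- sample(tr$labels, 1, prob = tr$prevalence)
    }
  }
  args <- list(sim$study, attributes = attrs,
               degree_known = as.integer(degree),
               degree_contactable = min(rep_deg, as.integer(degree)),
               prior_known = 0L, reciprocity = NA, contact = NULL,
               now = tick(sim))
  res <- if (is.null(receipt)) {
    do.call(register_seed, args)
  } else {
    do.call(complete_response, append(args, list(receipt = receipt), after = 1))
  }
  if (!is.null(node)) sim$enrolled[node] <- TRUE
  sim$n_enrolled <- sim$n_enrolled + 1L
  res
}

select_seed_nodes <- function(sim, n) {
  pop <- sim$population
  avail <- which(!sim$enrolled)
  deg <- pop$individuals$degree[avail]
  sel <- sim$config$seed_selection
  if (sel == "uniform") {
    avail[sample.int(length(avail), n)]
  } else if (sel == "degree-weighted") {
    avail[sample.int(length(avail), n, prob = deg)]
  } else {  # diverse-profile: round-robin over primary categories by degree
    cat <- pop$individuals[[pop$config$primary_var]][avail]
    picked <- integer(0)
    ord <- avail[order(-deg)]
    ocat <- pop$individuals[[pop$config$primary_var]][ord]
    labs <- unique(pop$config$traits[[1]]$labels)
    while (length(picked) < n) {
      for (lb in labs) {
        cand <- setdiff(ord[ocat == lb], picked)
        if (length(cand)) picked <- c(picked, cand[1])
        if (length(picked) >= n) break
      }
      if (!any(!ord %in% picked)) break
    }
    head(picked, n)
  }
}

init_seeds <- function(sim) {
  pop <- sim$population
  cfg <- sim$config
  if (pop$mode == "graph") {
    nodes <- select_seed_nodes(sim, cfg$n_seeds)
    for (nd in nodes) {
      res <- enroll(sim, nd, NULL, pop$individuals$degree[nd])
      sim$frontier <- c(sim$frontier, list(list(
        pid = res$participant_id, token = res$token, node = nd,
        cat = pop$individuals[[pop$config$primary_var]][nd], wave = 0L)))
    }
  } else {
    ensure_samplers(sim)
    labs <- pop$config$traits[[1]]$labels
    prev <- pop$config$traits[[1]]$prevalence
    for (k in seq_len(cfg$n_seeds)) {
      cat <- sample(labs, 1, prob = prev)   # seeds chosen on profile
      d <- sim$samplers[[cat]](1)
      res <- enroll(sim, NULL, cat, d)
      sim$frontier <- c(sim$frontier, list(list(
        pid = res$participant_id, token = res$token, node = NA_integer_,
        cat = cat, wave = 0L)))
    }
  }
  invisible(sim)
}

ensure_samplers <- function(sim) {
  if (is.null(sim$samplers)) {
    cfg <- sim$population$config
    sim$samplers <- lapply(setNames(nm = cfg$traits[[1]]$labels), function(k)
      size_biased_degree_sampler(cfg$degree_mu[[k]], cfg$degree_size))
  }
  invisible(sim)
}

#' Continue processing the recruitment frontier
#'
#' Called internally by [simulate_recruitment()]; exported so a run can be
#' resumed after [add_seed_midstream()].
#'
#' @param sim An `rds_simulation`.
#' @param reseed Re-seed the RNG from `config$rng_seed` before processing
#'   (default `FALSE`: continue the current stream).
#' @return The simulation, invisibly.
#' @export
run_recruitment <- function(sim, reseed = FALSE) {
  stopifnot(inherits(sim, "rds_simulation"))
  if (reseed) set.seed(sim$config$rng_seed)
  pop <- sim$population
  cfg <- sim$config
  pvar <- pop$config$primary_var
  while (length(sim$frontier) && sim$n_enrolled < cfg$max_sample) {
    cur <- sim$frontier[[1]]
    sim$frontier <- sim$frontier[-1]
    if (cur$wave >= cfg$max_waves) next
    if (pop$mode == "graph") {
      nbrs <- as.integer(igraph::neighbors(pop$graph, cur$node))
      nbrs <- nbrs[!sim$enrolled[nbrs]]
      if (!length(nbrs)) next
      nbrs <- nbrs[sample.int(length(nbrs))]
      invitees <- head(nbrs, cfg$coupons)
      for (nd in invitees) {
        if (sim$n_enrolled >= cfg$max_sample) break
        if (runif(1) > cfg$participation_prob) next
        if (sim$enrolled[nd]) next
        receipt <- redeem_token(sim$study, cur$token, now = num_to_time(sim$clock))
        res <- enroll(sim, nd, NULL, pop$individuals$degree[nd],
                      receipt = receipt)
        sim$frontier <- c(sim$frontier, list(list(
          pid = res$participant_id, token = res$token, node = nd,
          cat = pop$individuals[[pvar]][nd], wave = cur$wave + 1L)))
      }
    } else {
      ensure_samplers(sim)
      for (j in seq_len(cfg$coupons)) {
        if (sim$n_enrolled >= cfg$max_sample) break
        if (runif(1) > cfg$participation_prob) next
        cat <- sample(colnames(pop$mixing), 1, prob = pop$mixing[cur$cat, ])
        d <- sim$samplers[[cat]](1)
        receipt <- redeem_token(sim$study, cur$token, now = num_to_time(sim$clock))
        res <- enroll(sim, NULL, cat, d, receipt = receipt)
        sim$frontier <- c(sim$frontier, list(list(
          pid = res$participant_id, token = res$token, node = NA_integer_,
          cat = cat, wave = cur$wave + 1L)))
      }
    }
  }
  invisible(sim)
}

#' Add a seed while recruitment is under way
#'
#' Mirrors the field practice of introducing replacement seeds when early
#' chains stall: a new wave-0 root is registered through the coupon engine
#' (so the tree count increments and prior trees are untouched) and pushed
#' onto the frontier.  Call [run_recruitment()] to let it recruit.
#'
#' @param sim An `rds_simulation`.
#' @param attributes Optional named list of attribute values for the new
#'   seed (markov mode); graph mode picks the highest-degree unenrolled
#'   individual matching `attributes` (or any, if `NULL`).
#' @return Invisibly, the new seed's `participant_id` and `token`.
#' @export
add_seed_midstream <- function(sim, attributes = NULL) {
  stopifnot(inherits(sim, "rds_simulation"))
  pop <- sim$population
  pvar <- pop$config$primary_var
  if (pop$mode == "graph") {
    avail <- which(!sim$enrolled)
    if (!length(avail))
      stop_webrds("No unenrolled individuals left to seed from.", "validation")
    if (!is.null(attributes)) {
      for (v in names(attributes))
        avail <- avail[pop$individuals[[v]][avail] == attributes[[v]]]
      if (!length(avail))
        stop_webrds("No unenrolled individual matches the requested profile.",
                    "validation")
    }
    nd <- avail[order(-pop$individuals$degree[avail])][1]
    res <- enroll(sim, nd, NULL, pop$individuals$degree[nd])
    sim$frontier <- c(sim$frontier, list(list(
      pid = res$participant_id, token = res$token, node = nd,
      cat = pop$individuals[[pvar]][nd], wave = 0L)))
  } else {
    ensure_samplers(sim)
    cat <- if (!is.null(attributes) && !is.null(attributes[[pvar]]))
      attributes[[pvar]]
    else sample(pop$config$traits[[1]]$labels, 1,
                prob = pop$config$traits[[1]]$prevalence)
    d <- sim$samplers[[cat]](1)
    res <- enroll(sim, NULL, cat, d)
    sim$frontier <- c(sim$frontier, list(list(
      pid = res$participant_id, token = res$token, node = NA_integer_,
      cat = cat, wave = 0L)))
  }
  invisible(res)
}

#' Remove a non-recruiting seed
#'
#' Seeds that never recruited can be dropped from the analysis set (field
#' practice when a chain never starts).  Refuses to remove a seed with
#' descendants.
#'
#' @param sim An `rds_simulation`.
#' @param seed_id Participant id of the seed to drop.
#' @return The simulation, invisibly.
#' @export
remove_seed <- function(sim, seed_id) {
  stopifnot(inherits(sim, "rds_simulation"))
  st <- sim$study
  i <- match(seed_id, st$id[seq_len(st$n)])
  if (is.na(i) || st$removed[i] || !st$is_seed[i])
    stop_webrds(sprintf("No active seed with id %s.", seed_id), "not_found")
  tok <- st$token[i]
  kids <- which(!is.na(st$token_used[seq_len(st$n)]) &
                st$token_used[seq_len(st$n)] == tok &
                !st$removed[seq_len(st$n)])
  if (length(kids))
    stop_webrds(sprintf("Seed %s has %d recruit(s); only non-recruiting seeds can be removed.",
                        seed_id, length(kids)), "validation")
  remove_participant(st, seed_id, "non-recruiting seed removed",
                     now = num_to_time(sim$clock))
  sim$frontier <- Filter(function(f) f$pid != seed_id, sim$frontier)
  sim$n_enrolled <- sim$n_enrolled - 1L
  invisible(sim)
}

#' @export
participants.rds_simulation <- function(x) participants(x$study)

#' @export
responses.rds_simulation <- function(x) responses(x$study)

#' Recruitment forest of a simulation
#'
#' @param sim An `rds_simulation`.
#' @return An `rds_forest` built from the simulation's tables.
#' @export
sim_forest <- function(sim) {
  stopifnot(inherits(sim, "rds_simulation"))
  build_forest(participants(sim), responses(sim))
}
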