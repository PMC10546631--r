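#' RDS-II (Volz-Heckathorn) proportion estimate
#'
#' Estimates population category proportions from a respondent-driven sample
#' by weighting each respondent inversely to their self-reported degree.  For
#' category A within the usable sample S,
#' \deqn{\hat p_A = \frac{\sum_{i \in A} 1/d_i}{\sum_{i \in S} 1/d_i},}
#' where \eqn{d_i} is the number of target-population members the respondent
#' could contact right now (`degree_contactable`).  Under the with-replacement
#' random-walk model of RDS, inclusion probability is proportional to degree,
#' which this weighting undoes.
#'
#' Respondents are excluded (and tallied in `n_excluded` with reasons) when
#' their category is missing, their degree is missing or zero (1/d undefined;
#' no imputation is attempted), or — by default — when they are seeds, who
#' were purposively chosen rather than sampled through the network.
#'
#' @param responses Response tibble ([responses()] / [read_responses()]).
#' @param forest Optional `rds_forest` used to identify seeds (wave 0); if
#'   `NULL`, rows with an empty inbound `token` are treated as seeds.
#' @param variable Name of the categorical attribute column to estimate.
#' @param exclude_seeds Drop seeds from estimation (default `TRUE`).
#' @param degree_var Degree column used for weighting; default
#'   `"degree_contactable"`. `"degree_known"` is accepted for sensitivity
#'   reruns.
#' @return An `rds_estimate`: list with `variable`, `estimates` (tibble
#'   `category`, `estimate`, `ci_low`, `ci_high` — CIs `NA` until
#'   [chain_bootstrap_ci()] fills them), `weights` (tibble `id`, `weight`
#'   with \eqn{w_i = 1/d_i}), `n_used`, `n_excluded`, `exclusion_reasons`.
#' @examples
#' resp <- tibble::tibble(
#'   id = 1:4, token = c("s1", "s1", "s2", "s2"),
#'   degree_contactable = c(2, 2, 4, 4),
#'   grp = c("a", "a", "b", "b"))
#' rds_ii_estimate(resp, variable = "grp", exclude_seeds = FALSE)
#' @export
rds_ii_estimate <- function(responses, forest = NULL, variable,
                            exclude_seeds = TRUE,
                            degree_var = c("degree_contactable", "degree_known")) {
  degree_var <- match.arg(degree_var)
  u <- usable_respondents(responses, forest, variable, exclude_seeds, degree_var)
  if (u$n_used == 0)
    stop_webrds(paste0("No usable responses for '", variable, "': ",
                       paste(names(u$reasons), u$reasons, sep = "=",
                             collapse = ", ")),
                "validation", reasons = u$reasons)
  w <- 1 / u$degree
  num <- tapply(w, u$category, sum)
  point <- as.numeric(num) / sum(w)
  structure(list(
    variable = variable,
    estimates = tibble(category = names(num), estimate = point,
                       ci_low = NA_real_, ci_high = NA_real_),
    weights = tibble(id = u$id, weight = w),
    n_used = u$n_used,
    n_excluded = sum(u$reasons),
    exclusion_reasons = u$reasons
  ), class = "rds_estimate")
}

# Shared exclusion logic.  Returns usable rows (id, category, degree, seed
# flag per original row) plus the exclusion tally.
usable_respondents <- function(responses, forest, variable, exclude_seeds,
                               degree_var = "degree_contactable") {
  if (!variable %in% names(responses))
    stop_webrds(sprintf("Variable '%s' not found in responses.", variable),
                "validation")
  if (!is.null(forest)) {
    stopifnot(inherits(forest, "rds_forest"))
    is_seed <- responses$id %in%
      forest$nodes$participant_id[forest$nodes$wave == 0L]
  } else {
    is_seed <- is_blank(responses$token)
  }
  cat_vals <- as.character(responses[[variable]])
  deg <- as.numeric(responses[[degree_var]])
  miss_cat <- is.na(cat_vals) | !nzchar(cat_vals)
  bad_deg <- is.na(deg) | deg <= 0
  seed_drop <- exclude_seeds & is_seed
  keep <- !miss_cat & !bad_deg & !seed_drop
  reasons <- c(seed = sum(seed_drop & !miss_cat & !bad_deg),
               missing_category = sum(miss_cat),
               zero_or_missing_degree = sum(bad_deg & !miss_cat))
  list(id = responses$id[keep], category = cat_vals[keep], degree = deg[keep],
       is_seed = is_seed, keep = keep, n_used = sum(keep), reasons = reasons)
}

#' @export
print.rds_estimate <- function(x, ...) {
  cat(sprintf("RDS-II estimate of '%s' (n used = %d, excluded = %d)\n",
              x$variable, x$n_used, x$n_excluded))
  est <- x$estimates
  for (i in seq_len(nrow(est))) {
    ci <- if (is.na(est$ci_low[i])) "" else
      sprintf("  [%.3f, %.3f]", est$ci_low[i], est$ci_high[i])
    cat(sprintf("  %-14s %.3f%s\n", est$category[i], est$estimate[i], ci))
  }
  invisible(x)
}

#' Tidy table of an RDS estimate
#'
#' @param x An `rds_estimate`.
#' @return A tibble `variable, category, estimate, ci_low, ci_high, n_used`.
#' @export
tidy_estimate <- function(x) {
  stopifnot(inherits(x, "rds_estimate"))
  out <- x$estimates
  out$variable <- x$variable
  out$n_used <- x$n_used
  out[, c("variable", "category", "estimate", "ci_low", "ci_high", "n_used")]
}

#' Chain-bootstrap confidence intervals for RDS-II estimates
#'
#' Salganik-style bootstrap that preserves the referral dependence of the
#' sample.  The category-to-category recruitment structure is taken from the
#' observed recruiter-to-recruit edges: for each category `k`, the pool of
#' respondents whose recruiter belongs to `k` is recorded.  Each replicate
#' starts from a uniformly drawn usable respondent and chains
#' `resample_size` draws; at every step the next respondent is drawn
#' uniformly, with replacement, from the pool keyed by the current
#' respondent's category (falling back to a uniform draw over all usable
#' respondents when that pool is empty).  The RDS-II estimate is recomputed
#' on every replicate and percentile intervals are reported.
#'
#' @inheritParams rds_ii_estimate
#' @param forest `rds_forest` giving the recruiter-to-recruit edges
#'   (required: the transition pools come from it).
#' @param replicates Number of bootstrap replicates B (default 1000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Integer RNG seed; identical seeds give identical intervals.
#'   `NULL` uses the current RNG state.
#' @param resample_size Draws per replicate; default the usable sample size.
#' @return An `rds_estimate` with `ci_low`/`ci_high` filled and fields
#'   `conf_level` and `replicates` added.
#' @export
chain_bootstrap_ci <- function(responses, forest, variable,
                               replicates = 1000, conf_level = 0.95,
                               seed = NULL, resample_size = NULL,
                               exclude_seeds = TRUE,
                               degree_var = c("degree_contactable", "degree_known")) {
  degree_var <- match.arg(degree_var)
  stopifnot(inherits(forest, "rds_forest"), replicates >= 1,
            conf_level > 0, conf_level < 1)
  est <- rds_ii_estimate(responses, forest, variable,
                         exclude_seeds = exclude_seeds, degree_var = degree_var)
  u <- usable_respondents(responses, forest, variable, exclude_seeds, degree_var)
  cats <- sort(unique(u$category))
  K <- length(cats)
  cat_idx <- match(u$category, cats)
  w <- 1 / u$degree
  n <- u$n_used
  resample_size <- resample_size %||% n

  # Transition pools: usable respondents whose recruiter's category is known.
  nd <- forest$nodes
  recruiter_of <- nd$recruiter_id[match(u$id, nd$participant_id)]
  rec_cat_all <- as.character(responses[[variable]])[match(recruiter_of, responses$id)]
  has_edge <- !is.na(recruiter_of) & !is.na(rec_cat_all) & nzchar(rec_cat_all)
  if (sum(has_edge) < 2)
    stop_webrds("Fewer than 2 usable recruiter-recruit edges; no transition structure to bootstrap.",
                "validation")
  pools <- lapply(cats, function(k) which(has_edge & rec_cat_all == k))

  run <- function() {
    B <- replicates
    acc <- matrix(0, B, K)            # per-replicate weight sums by category
    cur <- sample.int(n, B, replace = TRUE)   # starting respondents
    acc[cbind(seq_len(B), cat_idx[cur])] <- w[cur]
    cur_cat <- cat_idx[cur]
    for (step in seq_len(resample_size - 1L)) {
      nxt <- integer(B)
      for (k in seq_len(K)) {
        at_k <- which(cur_cat == k)
        if (!length(at_k)) next
        pool <- pools[[k]]
        if (length(pool)) {
          nxt[at_k] <- pool[sample.int(length(pool), length(at_k), replace = TRUE)]
        } else {
          nxt[at_k] <- sample.int(n, length(at_k), replace = TRUE)
        }
      }
      acc[cbind(seq_len(B), cat_idx[nxt])] <- acc[cbind(seq_len(B), cat_idx[nxt])] + w[nxt]
      cur_cat <- cat_idx[nxt]
    }
    acc / rowSums(acc)
  }
  props <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  alpha <- (1 - conf_level) / 2
  ci <- apply(props, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  m <- match(est$estimates$category, cats)
  est$estimates$ci_low <- ci[1, m]
  est$estimates$ci_high <- ci[2, m]
  est$conf_level <- conf_level
  est$replicates <- replicates
  est
}

#' Recruitment homophily
#'
#' Ratio of the observed number of recruiter-recruit pairs sharing a
#' category to the number expected under proportionate (random) mixing of
#' the observed margins: with `n_rk` (`n_ck`) the number of usable edges
#' whose recruiter (recruit) has category k,
#' \deqn{H = \frac{O}{E^*},\qquad E^* = \sum_k \frac{n_{rk}\, n_{ck}}{|E|}.}
#' H = 1 indicates no preference; H > 1 that participants tended to recruit
#' peers like themselves.
#'
#' @inheritParams rds_ii_estimate
#' @param forest `rds_forest` supplying the edges.
#' @param include_seed_edges Keep edges whose recruiter is a seed (default
#'   `TRUE`).
#' @return An `rds_homophily` list: `variable`, `observed_same`,
#'   `expected_same`, `ratio`, `n_edges`.
#' @export
recruitment_homophily <- function(responses, forest, variable,
                                  include_seed_edges = TRUE) {
  stopifnot(inherits(forest, "rds_forest"))
  if (!variable %in% names(responses))
    stop_webrds(sprintf("Variable '%s' not found in responses.", variable),
                "validation")
  nd <- forest$nodes
  ed <- nd[!is.na(nd$recruiter_id), ]
  if (!include_seed_edges) {
    seed_ids <- nd$participant_id[nd$wave == 0L]
    ed <- ed[!ed$recruiter_id %in% seed_ids, ]
  }
  cats <- as.character(responses[[variable]])
  rcat <- cats[match(ed$recruiter_id, responses$id)]
  ccat <- cats[match(ed$participant_id, responses$id)]
  ok <- !is.na(rcat) & nzchar(rcat) & !is.na(ccat) & nzchar(ccat)
  if (!any(ok))
    stop_webrds("No recruiter-recruit edge has both categories observed.",
                "validation")
  rcat <- rcat[ok]; ccat <- ccat[ok]
  nE <- length(rcat)
  observed <- sum(rcat == ccat)
  lev <- union(rcat, ccat)
  expected <- sum(tabulate(match(rcat, lev), length(lev)) *
                  tabulate(match(ccat, lev), length(lev))) / nE
  structure(list(variable = variable, observed_same = observed,
                 expected_same = expected, ratio = observed / expected,
                 n_edges = nE),
            class = "rds_homophily")
}

#' @export
print.rds_homophily <- function(x, ...) {
  cat(sprintf("Recruitment homophily of '%s': %.2f (observed %d vs expected %.1f same-category pairs over %d edges)\n",
              x$variable, x$ratio, x$observed_same, x$expected_same, x$n_edges))
  invisible(x)
}

#' Convergence series of the running RDS-II estimate
#'
#' Sorts respondents by submission time (ties broken by id) and recomputes
#' the RDS-II estimate on the first k respondents for every k from `min_n`
#' to n.  Plotted against k this is the convergence diagnostic: estimates
#' that have stabilised no longer depend on the (non-random) seeds.  The
#' final point equals the full-sample estimate by construction.
#'
#' @inheritParams rds_ii_estimate
#' @param min_n Smallest prefix size reported (>= 2).
#' @return A tibble `k, category, estimate` (one row per category per k;
#'   `estimate` is `NA` while no usable respondent of any category has
#'   accrued).
#' @export
convergence_series <- function(responses, forest = NULL, variable, min_n = 2,
                               exclude_seeds = TRUE,
                               degree_var = c("degree_contactable", "degree_known")) {
  degree_var <- match.arg(degree_var)
  stopifnot(min_n >= 2)
  if (!"submitdate" %in% names(responses) ||
      anyNA(as_time_num(responses$submitdate)))
    stop_webrds("Responses must carry sortable 'submitdate' timestamps.",
                "validation")
  ord <- order(as_time_num(responses$submitdate), responses$id)
  resp <- responses[ord, ]
  u <- usable_respondents(resp, forest, variable, exclude_seeds, degree_var)
  n <- nrow(resp)
  if (n < min_n)
    stop_webrds("Fewer responses than `min_n`.", "validation")
  cats <- sort(unique(u$category))
  if (!length(cats))
    stop_webrds("No usable responses to build a convergence series.", "validation")
  wrow <- rep(0, n)
  wrow[u$keep] <- 1 / u$degree
  wm <- matrix(0, n, length(cats))
  idx <- which(u$keep)
  wm[cbind(idx, match(u$category, cats))] <- wrow[idx]
  cum <- apply(wm, 2, cumsum)
  denom <- cumsum(wrow)
  ks <- min_n:n
  est <- cum[ks, , drop = FALSE] / denom[ks]
  tibble(
    k = rep(ks, times = length(cats)),
    category = rep(cats, each = length(ks)),
    estimate = as.vector(est)
  )
}

#' Per-seed-tree convergence (bottleneck) series
#'
#' Computes [convergence_series()] separately within each seed's tree.
#' Diverging per-tree trajectories reveal recruitment trapped in network
#' sub-communities (bottlenecks).  Trees with fewer than `min_n` respondents
#' are omitted with a notice; their seed ids are attached as the
#' `"omitted_trees"` attribute.
#'
#' @inheritParams convergence_series
#' @param forest `rds_forest` (required: defines tree membership).
#' @return A tibble `seed_id, k, category, estimate`.
#' @export
bottleneck_series <- function(responses, forest, variable, min_n = 2,
                              exclude_seeds = TRUE,
                              degree_var = c("degree_contactable", "degree_known")) {
  degree_var <- match.arg(degree_var)
  stopifnot(inherits(forest, "rds_forest"))
  nd <- forest$nodes
  seed_of <- nd$seed_id[match(responses$id, nd$participant_id)]
  out <- list()
  omitted <- integer(0)
  for (sid in sort(unique(nd$seed_id))) {
    sub <- responses[!is.na(seed_of) & seed_of == sid, ]
    if (nrow(sub) < min_n) {
      omitted <- c(omitted, sid)
      next
    }
    ser <- tryCatch(
      convergence_series(sub, forest, variable, min_n = min_n,
                         exclude_seeds = exclude_seeds, degree_var = degree_var),
      webrds_error = function(e) NULL)
    if (is.null(ser)) { omitted <- c(omitted, sid); next }
    ser$seed_id <- sid
    out[[length(out) + 1L]] <- ser
  }
  if (length(omitted))
    inform(sprintf("Omitting %d tree(s) with fewer than %d usable respondents: %s",
                   length(omitted), min_n, paste(omitted, collapse = ", ")))
  res <- if (length(out)) bind_rows(out)[, c("seed_id", "k", "category", "estimate")]
         else tibble(seed_id = integer(), k = integer(),
                     category = character(), estimate = numeric())
  attr(res, "omitted_trees") <- omitted
  res
}

#' Descriptive summary of the sampling-diagnostic questions
#'
#' Summarises the two diagnostic questions asked alongside the degree
#' questions: how many prior participants the respondent already knew
#' (finite-population diagnostic) and whether the recruiter would
#' reciprocally be among the respondent's own invitees (reciprocity
#' diagnostic).  Purely descriptive; no estimator adjustment is applied.
#'
#' @param responses Response tibble.
#' @return A list: `prior_known` (`n`, `mean`, `median`, `max`,
#'   `distribution` — a named count table) and `reciprocity` (`n_answered`,
#'   `n_yes`, `share_yes_pct`, half-up 1-decimal).
#' @export
diagnostics_descriptives <- function(responses) {
  pk <- responses$prior_known
  pk <- pk[!is.na(pk)]
  rec <- responses$reciprocity
  rec <- rec[!is.na(rec)]
  dist <- if (length(pk)) table(pk) else table(integer(0))
  list(
    prior_known = list(
      n = length(pk),
      mean = if (length(pk)) mean(pk) else NA_real_,
      median = if (length(pk)) as.numeric(median(pk)) else NA_real_,
      max = if (length(pk)) max(pk) else NA_real_,
      distribution = setNames(as.integer(dist), names(dist))
    ),
    reciprocity = list(
      n_answered = length(rec),
      n_yes = sum(rec),
      share_yes_pct = if (length(rec)) round_half_up(100 * mean(rec), 1) else NA_real_
    )
  )
}

#' Plot a convergence or bottleneck series
#'
#' Running RDS-II estimate against cumulative sample size, one line per
#' category (faceted by seed tree for bottleneck input).
#'
#' @param series Output of [convergence_series()] or [bottleneck_series()].
#' @return A ggplot object.
#' @export
plot_convergence <- function(series) {
  p <- ggplot2::ggplot(series,
         ggplot2::aes(x = .data$k, y = .data$estimate,
                      colour = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Cumulative sample size", y = "RDS-II estimate",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if ("seed_id" %in% names(series))
    p <- p + ggplot2::facet_wrap(~seed_id)
  p
}
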