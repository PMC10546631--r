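# Fixture builders and independent oracles used across the suite.

t0 <- as.POSIXct("2022-04-01 09:00:00", tz = "UTC")

# Build a study by replaying seeds and recruitments.  `edges` is a list of
# recruiter participant_id -> attributes for the recruit.
chain_study <- function(n_seeds = 1, budget = 3) {
  st <- rds_study(coupon_budget = budget)
  for (i in seq_len(n_seeds))
    register_seed(st, c(trait = "a"), 10, 5, now = t0 + i)
  st
}

recruit_into <- function(st, recruiter_id, trait = "b", dk = 8, dc = 4,
                         now = Sys.time()) {
  tok <- participants(st)$token[participants(st)$id == recruiter_id]
  r <- redeem_token(st, tok, now = now)
  complete_response(st, r, c(trait = trait), dk, dc, now = now)
}

# Hand-built response table (no ledger) for pure estimator tests.
response_table <- function(trait, degree, token = NULL, id = seq_along(trait),
                           submit = t0 + seq_along(trait)) {
  tibble::tibble(
    id = id,
    token = token %||% rep("tk", length(trait)),
    submitdate = submit,
    degree_known = degree,
    degree_contactable = degree,
    prior_known = 0L,
    reciprocity = NA,
    trait = trait,
    contact = NA_character_
  )
}

# A forest straight from an edge list (ids must be topologically safe).
forest_from_edges <- function(ids, parents) {
  part <- tibble::tibble(id = ids, token = paste0("t", ids))
  resp <- tibble::tibble(
    id = ids,
    token = ifelse(is.na(parents), NA_character_, paste0("t", parents)))
  build_forest(part, resp)
}

empty_forest <- function() {
  f <- forest_from_edges(1L, NA)
  f$nodes <- f$nodes[0, ]
  f
}

subset_forest <- function(forest, keep_ids) {
  out <- list(nodes = forest$nodes[forest$nodes$participant_id %in% keep_ids, ])
  class(out) <- "rds_forest"
  out
}

# Independent RDS-II oracle: plain loop over rows.
oracle_rds_ii <- function(category, degree) {
  cats <- sort(unique(category))
  num <- setNames(numeric(length(cats)), cats)
  den <- 0
  for (i in seq_along(category)) {
    num[category[i]] <- num[category[i]] + 1 / degree[i]
    den <- den + 1 / degree[i]
  }
  num / den
}

# Independent recount of performance metrics from a raw node table.
oracle_metrics <- function(nodes) {
  n <- nrow(nodes)
  outdeg <- vapply(nodes$participant_id, function(id)
    sum(!is.na(nodes$recruiter_id) & nodes$recruiter_id == id), integer(1))
  trees <- split(nodes, nodes$seed_id)
  chain <- vapply(trees, function(tr) max(tr$wave), integer(1))
  pct <- function(k) webrds:::round_half_up(100 * k / n, 1)
  list(n_total = n, n_seeds = sum(is.na(nodes$recruiter_id)),
       outdeg = outdeg,
       pct_ge1 = pct(sum(outdeg >= 1)), pct_ge2 = pct(sum(outdeg >= 2)),
       pct_3 = pct(sum(outdeg == 3)),
       chain_median = median(chain),
       largest = max(vapply(trees, nrow, integer(1))))
}

# Brute-force pairwise duplicate oracle (tables <= 50 rows): transitive
# closure of the pairwise match relation.
oracle_duplicates <- function(responses, fingerprint_vars) {
  n <- nrow(responses)
  norm <- gsub("[^a-z0-9]", "", tolower(
    ifelse(is.na(responses$contact), "", responses$contact)))
  fp <- responses[c(fingerprint_vars, "degree_known", "degree_contactable")]
  match_pair <- function(i, j) {
    contact <- nzchar(norm[i]) && norm[i] == norm[j]
    fng <- all(mapply(function(a, b) identical(as.character(a), as.character(b)),
                      fp[i, ], fp[j, ]))
    contact || fng
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    adj[i, j] <- match_pair(i, j)
  # transitive closure
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    members <- unique(c(i, which(adj[i, ])))
    comp[members] <- cid
  }
  groups <- split(responses$id, comp)
  Filter(function(g) length(g) >= 2, lapply(groups, sort))
}

default_pop <- function(prev_a = 0.3, mu = c(a = 8, b = 4), size = 2000) {
  population_config(size,
    traits = list(trait = list(labels = c("a", "b"),
                               prevalence = c(prev_a, 1 - prev_a))),
    degree_mu = mu)
}
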