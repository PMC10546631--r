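#' Deterministic benchmark recruitment forest
#'
#' Builds, by pure arithmetic construction (no randomness), a recruitment
#' forest that reproduces the published recruitment-performance summary of a
#' nationwide WebRDS survey of homecare workers: 337 respondents in 13 seed
#' trees; out-degree histogram 175 participants recruiting nobody, 59
#' recruiting exactly one, 44 exactly two and 59 exactly three (so
#' 59 + 2*44 + 3*59 = 324 = 337 - 13 recruits); per-tree chain lengths with
#' median 4 and range 1-10; and a largest tree of 123 nodes (36.5% of the
#' sample).  Useful as a reference input for [recruitment_metrics()], for
#' export round-trip tests and for exercising per-tree diagnostics at a
#' realistic scale.
#'
#' Construction: each tree follows a fixed plan (size, depth, out-degree
#' composition).  A spine of `depth + 1` nodes fixes the tree's chain
#' length; the largest planned out-degrees are assigned to the shallowest
#' spine nodes; remaining internal nodes and then leaves are attached
#' shallow-first to open coupon slots, never deeper than the planned depth.
#'
#' @return An `rds_forest` with 337 nodes and 13 roots.
#' @examples
#' recruitment_metrics(reference_forest())
#' @export
reference_forest <- function() {
  plan <- data.frame(
    size  = c(2, 2, 3, 3, 10, 12, 18, 20, 25, 30, 40, 49, 123),
    depth = c(1, 1, 2, 2, 3, 3, 4, 5, 6, 7, 8, 9, 10),
    n1    = c(1, 1, 2, 2, 0, 1, 2, 2, 3, 4, 6, 9, 26),
    n2    = c(0, 0, 0, 0, 3, 2, 3, 4, 3, 5, 6, 6, 12),
    n3    = c(0, 0, 0, 0, 1, 2, 3, 3, 5, 5, 7, 9, 24)
  )
  next_id <- 1L
  all_nodes <- vector("list", nrow(plan))
  for (t in seq_len(nrow(plan))) {
    p <- plan[t, ]
    tree <- build_fixture_tree(p$size, p$depth, p$n1, p$n2, p$n3, next_id)
    all_nodes[[t]] <- tree
    next_id <- next_id + p$size
  }
  nodes <- do.call(rbind, all_nodes)
  new_rds_forest(tibble(
    participant_id = nodes$id,
    recruiter_id = nodes$parent,
    seed_id = nodes$seed,
    wave = nodes$wave
  ))
}

# One tree of the fixture plan.  Degrees sorted descending; the spine
# (nodes at waves 0..depth) pins the chain length, extra internal nodes and
# leaves attach shallow-first.
build_fixture_tree <- function(size, depth, n1, n2, n3, id0) {
  degs <- sort(c(rep(1L, n1), rep(2L, n2), rep(3L, n3)), decreasing = TRUE)
  n_internal <- length(degs)
  stopifnot(n_internal >= depth, sum(degs) == size - 1L)
  id <- id0:(id0 + size - 1L)
  parent <- rep(NA_integer_, size)
  wave <- rep(NA_integer_, size)
  cap <- rep(0L, size)   # planned out-degree
  used <- rep(0L, size)  # children attached so far

  # spine: local indices 1..depth+1 at waves 0..depth
  wave[1:(depth + 1L)] <- 0:depth
  parent[2:(depth + 1L)] <- id[1:depth]
  cap[1:depth] <- degs[1:depth]
  used[1:depth] <- 1L
  extra_degs <- if (n_internal > depth) degs[(depth + 1L):n_internal] else integer(0)

  attach_to <- function(max_parent_wave) {
    open <- which(!is.na(wave) & used < cap & wave <= max_parent_wave)
    if (!length(open))
      stop_webrds("Fixture plan infeasible: no open slot.", "integrity")
    open[order(wave[open], open)][1]
  }
  nxt <- depth + 2L
  for (d in extra_degs) {  # internal nodes need room for their own children
    par <- attach_to(depth - 2L)
    parent[nxt] <- id[par]; wave[nxt] <- wave[par] + 1L
    cap[nxt] <- d; used[par] <- used[par] + 1L
    nxt <- nxt + 1L
  }
  while (nxt <= size) {    # leaves
    par <- attach_to(depth - 1L)
    parent[nxt] <- id[par]; wave[nxt] <- wave[par] + 1L
    used[par] <- used[par] + 1L
    nxt <- nxt + 1L
  }
  stopifnot(all(used == cap))
  data.frame(id = id, parent = parent, seed = id0, wave = wave)
}
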