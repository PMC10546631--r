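#' Reconstruct the recruiter-to-recruit forest from token linkage
#'
#' Each non-seed response carries the recruiter's token in its `token`
#' column; matching it against the participant table's own-token column
#' yields the recruiter-to-recruit edge set.  Waves are assigned by
#' breadth-first propagation from the seeds (wave 0) and every node is
#' labelled with the root (`seed_id`) of its tree.
#'
#' @param participants Participant tibble (see [participants()]).
#' @param responses Response tibble (see [responses()]); duplicates should be
#'   resolved first.
#' @return An `rds_forest`: a list with a `nodes` tibble
#'   (`participant_id`, `recruiter_id` — `NA` for seeds —, `seed_id`,
#'   `wave`), ordered by `participant_id`.
#' @section Errors: a non-seed `token` that resolves to no participant raises
#'   `webrds_error_orphan` (listing the offending ids); a cycle in the
#'   implied edge set raises `webrds_error_integrity`.
#' @examples
#' st <- rds_study()
#' seed <- register_seed(st, c(trait = "a"), 10, 5)
#' r <- redeem_token(st, seed$token)
#' complete_response(st, r, c(trait = "b"), 8, 4)
#' build_forest(participants(st), responses(st))
#' @export
build_forest <- function(participants, responses) {
  stopifnot(all(c("id", "token") %in% names(participants)),
            all(c("id", "token") %in% names(responses)))
  resp <- responses[order(responses$id), ]
  has_parent <- !is_blank(resp$token)
  recruiter_id <- rep(NA_integer_, nrow(resp))
  m <- match(resp$token[has_parent], participants$token)
  if (anyNA(m)) {
    bad <- resp$id[has_parent][is.na(m)]
    stop_webrds(
      sprintf("Orphan responses: token of id(s) %s resolves to no participant.",
              paste(bad, collapse = ", ")),
      "orphan", orphan_ids = bad)
  }
  recruiter_id[has_parent] <- as.integer(participants$id[m])
  ids <- as.integer(resp$id)
  parent_idx <- match(recruiter_id, ids)

  n <- length(ids)
  wave <- rep(NA_integer_, n)
  seed_idx <- rep(NA_integer_, n)
  roots <- which(!has_parent)
  wave[roots] <- 0L
  seed_idx[roots] <- roots
  frontier <- roots
  while (length(frontier)) {
    children <- which(parent_idx %in% frontier & is.na(wave))
    if (!length(children)) break
    wave[children] <- wave[parent_idx[children]] + 1L
    seed_idx[children] <- seed_idx[parent_idx[children]]
    frontier <- children
  }
  if (anyNA(wave)) {
    bad <- ids[is.na(wave)]
    stop_webrds(
      sprintf("Cycle detected: id(s) %s are not reachable from any seed.",
              paste(bad, collapse = ", ")),
      "integrity", cycle_ids = bad)
  }
  nodes <- tibble(
    participant_id = ids,
    recruiter_id = recruiter_id,
    seed_id = ids[seed_idx],
    wave = wave
  )
  new_rds_forest(nodes)
}

new_rds_forest <- function(nodes) {
  nodes$participant_id <- as.integer(nodes$participant_id)
  nodes$recruiter_id <- as.integer(nodes$recruiter_id)
  nodes$seed_id <- as.integer(nodes$seed_id)
  nodes$wave <- as.integer(nodes$wave)
  structure(list(nodes = nodes[order(nodes$participant_id), ]),
            class = "rds_forest")
}

#' @export
print.rds_forest <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<rds_forest> %d nodes, %d trees, max wave %s\n",
              nrow(nd), sum(is.na(nd$recruiter_id)),
              if (nrow(nd)) max(nd$wave) else "-"))
  invisible(x)
}

#' Recruitment performance summary of a forest
#'
#' Computes the descriptive performance measures of a chain-referral sample:
#' the out-degree histogram (how many people each participant recruited,
#' capped by the coupon budget), the shares who recruited at least one, at
#' least two, and exactly three peers, per-tree chain lengths (the maximum
#' wave reached in each seed's tree), and the size of the largest tree.
#' Percentages use the full sample (seeds included) as the base and are
#' rounded half-up to one decimal.
#'
#' @param forest An `rds_forest`.
#' @return An `rds_metrics` list: `n_total`, `n_seeds`,
#'   `n_after_seed_removal`, `out_degree_histogram` (named vector, degree 0
#'   up to the maximum), `pct_recruited_ge1`, `pct_recruited_ge2`,
#'   `pct_recruited_3`, `chain_lengths` (per tree, keyed by seed id),
#'   `chain_length_median`, `chain_length_min`, `chain_length_max`,
#'   `largest_tree_size`, `largest_tree_pct`.
#' @export
recruitment_metrics <- function(forest) {
  stopifnot(inherits(forest, "rds_forest"))
  nd <- forest$nodes
  if (nrow(nd) == 0) stop_webrds("Cannot summarise an empty forest.", "validation")
  n_total <- nrow(nd)
  n_seeds <- sum(is.na(nd$recruiter_id))
  outdeg <- table(factor(nd$recruiter_id, levels = nd$participant_id))
  outdeg <- as.integer(outdeg)  # per participant, in participant order
  hist <- table(factor(outdeg, levels = 0:max(outdeg, 0)))
  hist <- setNames(as.integer(hist), names(hist))
  pct <- function(count) round_half_up(100 * count / n_total, 1)
  tree_sizes <- table(nd$seed_id)
  chain <- tapply(nd$wave, nd$seed_id, max)
  chain <- setNames(as.integer(chain), names(chain))
  largest <- max(as.integer(tree_sizes))
  structure(list(
    n_total = n_total,
    n_seeds = n_seeds,
    n_after_seed_removal = n_total - n_seeds,
    out_degree_histogram = hist,
    pct_recruited_ge1 = pct(sum(outdeg >= 1)),
    pct_recruited_ge2 = pct(sum(outdeg >= 2)),
    pct_recruited_3 = pct(sum(outdeg == 3)),
    chain_lengths = chain,
    chain_length_median = as.numeric(median(chain)),
    chain_length_min = min(chain),
    chain_length_max = max(chain),
    largest_tree_size = largest,
    largest_tree_pct = pct(largest)
  ), class = "rds_metrics")
}

#' @export
print.rds_metrics <- function(x, ...) {
  cat("Recruitment performance\n")
  cat(sprintf("  respondents: %d (%d seeds; %d after seed removal)\n",
              x$n_total, x$n_seeds, x$n_after_seed_removal))
  cat(sprintf("  recruited >=1: %.1f%%   >=2: %.1f%%   exactly 3: %.1f%%\n",
              x$pct_recruited_ge1, x$pct_recruited_ge2, x$pct_recruited_3))
  cat(sprintf("  chain length (waves): median %s, range %d-%d\n",
              format(x$chain_length_median), x$chain_length_min,
              x$chain_length_max))
  cat(sprintf("  largest tree: %d nodes (%.1f%%)\n",
              x$largest_tree_size, x$largest_tree_pct))
  cat("  out-degree histogram: ",
      paste(sprintf("%s:%d", names(x$out_degree_histogram),
                    x$out_degree_histogram), collapse = "  "), "\n")
  invisible(x)
}

#' Convert a forest to an igraph object
#'
#' Directed recruiter-to-recruit graph with `wave` and `seed_id` vertex
#' attributes; useful for layout/plotting and for the GraphML/DOT exports.
#'
#' @param forest An `rds_forest`.
#' @return An [igraph::igraph] object.
#' @export
forest_igraph <- function(forest) {
  stopifnot(inherits(forest, "rds_forest"))
  nd <- forest$nodes
  verts <- data.frame(name = as.character(nd$participant_id),
                      wave = nd$wave, seed_id = nd$seed_id)
  ed <- nd[!is.na(nd$recruiter_id), c("recruiter_id", "participant_id")]
  edges <- data.frame(from = as.character(ed$recruiter_id),
                      to = as.character(ed$participant_id))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = verts)
}

#' Export / import a recruitment forest
#'
#' `export_forest()` writes the forest as an edge-list CSV
#' (`recruit_id,recruiter_id,seed_id,wave`; roots have an empty
#' `recruiter_id`), as GraphML, or as Graphviz DOT (the latter two carry
#' `wave` and `seed_id` as node attributes).  `import_forest()` reads the
#' edge-list CSV back; the CSV round-trip is lossless.
#'
#' @param forest An `rds_forest`.
#' @param path Output file path.
#' @param format One of `"edgelist"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly (`export_forest`); an `rds_forest`
#'   (`import_forest`).
#' @export
export_forest <- function(forest, path, format = c("edgelist", "graphml", "dot")) {
  stopifnot(inherits(forest, "rds_forest"))
  format <- match.arg(format)
  nd <- forest$nodes
  if (format == "edgelist") {
    out <- tibble(recruit_id = nd$participant_id,
                  recruiter_id = nd$recruiter_id,
                  seed_id = nd$seed_id, wave = nd$wave)
    readr::write_csv(out, path, na = "")
  } else {
    g <- forest_igraph(forest)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

#' @rdname export_forest
#' @export
import_forest <- function(path) {
  tb <- readr::read_csv(path, col_types = readr::cols(
    recruit_id = readr::col_integer(),
    recruiter_id = readr::col_integer(),
    seed_id = readr::col_integer(),
    wave = readr::col_integer()
  ))
  new_rds_forest(tibble(participant_id = tb$recruit_id,
                        recruiter_id = tb$recruiter_id,
                        seed_id = tb$seed_id, wave = tb$wave))
}
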