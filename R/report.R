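#' Build a monitoring report
#'
#' Snapshot used during fieldwork to track a running WebRDS study (in the
#' source deployment a similar report was produced every two days; cadence
#' is a usage pattern, not enforced here).  It combines sample
#' descriptives, recruitment performance, a reminder list of stalled tokens
#' (participants who completed at least `stall_days` ago, still have uses
#' left, and supplied contact information, so they can be nudged), a
#' convergence snapshot for tracked variables, and duplicate alerts.
#'
#' @param participants Participant tibble.
#' @param responses Response tibble.
#' @param forest `rds_forest` built from the same tables.
#' @param tracked_vars Character vector of attribute columns to track.
#' @param now Reference timestamp for stall computation.
#' @param stall_days Days since completion after which an unused link counts
#'   as stalled (default 5).
#' @return An `rds_report` list: `generated_at`, `sample_descriptives`
#'   (tibble `variable, category, n, pct` — percentages per variable over
#'   non-missing values, half-up 1 decimal), `performance`
#'   ([recruitment_metrics()] output), `stalled_tokens` (tibble
#'   `id, token, uses_left, days_since_completion, contact`),
#'   `convergence_snapshot` (tibble `variable, category, estimate` — the
#'   current full-sample RDS-II estimate), `duplicate_alerts`
#'   ([detect_duplicates()] output).
#' @export
build_report <- function(participants, responses, forest, tracked_vars,
                         now = Sys.time(), stall_days = 5) {
  stopifnot(inherits(forest, "rds_forest"))
  miss <- setdiff(tracked_vars, names(responses))
  if (length(miss))
    stop_webrds(sprintf("Tracked variable(s) not in responses: %s",
                        paste(miss, collapse = ", ")), "validation")

  desc <- bind_rows(lapply(tracked_vars, function(v) {
    x <- as.character(responses[[v]])
    x <- x[!is.na(x) & nzchar(x)]
    tab <- table(x)
    tibble(variable = v, category = names(tab), n = as.integer(tab),
           pct = round_half_up(100 * as.integer(tab) / length(x), 1))
  }))

  nownum <- as_time_num(now)
  sub <- as_time_num(responses$submitdate[match(participants$id, responses$id)])
  days_since <- (nownum - sub) / 86400
  stalled_idx <- which(participants$uses_left > 0 &
                         !is_blank(participants$contact) &
                         !is.na(days_since) & days_since >= stall_days)
  stalled <- tibble(
    id = participants$id[stalled_idx],
    token = participants$token[stalled_idx],
    uses_left = participants$uses_left[stalled_idx],
    days_since_completion = floor(days_since[stalled_idx]),
    contact = participants$contact[stalled_idx]
  )

  conv <- bind_rows(lapply(tracked_vars, function(v) {
    est <- tryCatch(rds_ii_estimate(responses, forest, v),
                    webrds_error = function(e) NULL)
    if (is.null(est)) return(tibble(variable = character(),
                                    category = character(),
                                    estimate = numeric()))
    tibble(variable = v, category = est$estimates$category,
           estimate = est$estimates$estimate)
  }))

  structure(list(
    generated_at = num_to_time(nownum),
    sample_descriptives = desc,
    performance = recruitment_metrics(forest),
    stalled_tokens = stalled,
    convergence_snapshot = conv,
    duplicate_alerts = detect_duplicates(responses)
  ), class = "rds_report")
}

#' @export
print.rds_report <- function(x, ...) {
  cat(sprintf("<rds_report> generated %s: %d stalled token(s), %d duplicate cluster(s)\n",
              format(x$generated_at, "%Y-%m-%d %H:%M", tz = "UTC"),
              nrow(x$stalled_tokens), nrow(x$duplicate_alerts)))
  invisible(x)
}

#' Serialise a monitoring report
#'
#' `report_json()` writes the report as JSON (schema shipped at
#' `system.file("schema", "monitoring-report.schema.json", package =
#' "webrds")`); `report_markdown()` renders a human-readable Markdown
#' version including a per-seed tree summary (ids optionally pseudonymised
#' by stable hashing, matching the practice of sharing anonymised trees
#' with seeds).
#'
#' @param report An `rds_report`.
#' @param path Output file.
#' @param forest Optional `rds_forest` for the per-seed tree summary.
#' @param anonymize Pseudonymise participant ids in the Markdown trees.
#' @return `path`, invisibly.
#' @export
report_json <- function(report, path) {
  stopifnot(inherits(report, "rds_report"))
  perf <- unclass(report$performance)
  perf$out_degree_histogram <- as.list(perf$out_degree_histogram)
  perf$chain_lengths <- as.list(perf$chain_lengths)
  dup <- report$duplicate_alerts
  obj <- list(
    generated_at = format(report$generated_at, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    sample_descriptives = report$sample_descriptives,
    performance = perf,
    stalled_tokens = report$stalled_tokens,
    convergence_snapshot = report$convergence_snapshot,
    duplicate_alerts = lapply(seq_len(nrow(dup)), function(i)
      list(member_ids = dup$member_ids[[i]], evidence = dup$evidence[i],
           kept_id = dup$kept_id[i]))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

pseudonym <- function(ids) {
  # stable, non-reversible-enough-for-a-report pseudonym
  vapply(ids, function(i) {
    h <- sum(utf8ToInt(paste0("webrds", i)) * seq_along(utf8ToInt(paste0("webrds", i))))
    sprintf("P%04d", h %% 10000L)
  }, character(1))
}

#' @rdname report_json
#' @export
report_markdown <- function(report, path, forest = NULL, anonymize = FALSE) {
  stopifnot(inherits(report, "rds_report"))
  p <- report$performance
  lines <- c(
    "# WebRDS monitoring report",
    sprintf("Generated: %s", format(report$generated_at, tz = "UTC")),
    "",
    "## Recruitment performance",
    sprintf("- Respondents: %d (%d seeds)", p$n_total, p$n_seeds),
    sprintf("- Recruited >=1: %.1f%%, >=2: %.1f%%, exactly 3: %.1f%%",
            p$pct_recruited_ge1, p$pct_recruited_ge2, p$pct_recruited_3),
    sprintf("- Chain length: median %s (range %d-%d); largest tree %d (%.1f%%)",
            format(p$chain_length_median), p$chain_length_min,
            p$chain_length_max, p$largest_tree_size, p$largest_tree_pct),
    "",
    "## Sample descriptives")
  d <- report$sample_descriptives
  for (v in unique(d$variable)) {
    lines <- c(lines, sprintf("### %s", v))
    sub <- d[d$variable == v, ]
    lines <- c(lines, sprintf("- %s: %d (%.1f%%)", sub$category, sub$n, sub$pct))
  }
  lines <- c(lines, "", "## Current RDS-II estimates")
  cs <- report$convergence_snapshot
  lines <- c(lines, sprintf("- %s = %s: %.3f", cs$variable, cs$category,
                            cs$estimate))
  lines <- c(lines, "", "## Stalled tokens (reminder list)")
  st <- report$stalled_tokens
  if (nrow(st) == 0) lines <- c(lines, "- none") else
    lines <- c(lines, sprintf("- id %d: %d use(s) left, completed %d day(s) ago",
                              st$id, st$uses_left, st$days_since_completion))
  lines <- c(lines, "", "## Duplicate alerts")
  da <- report$duplicate_alerts
  if (nrow(da) == 0) lines <- c(lines, "- none") else
    lines <- c(lines, vapply(seq_len(nrow(da)), function(i)
      sprintf("- cluster of %d (%s), keeping id %d",
              length(da$member_ids[[i]]), da$evidence[i], da$kept_id[i]),
      character(1)))
  if (!is.null(forest)) {
    lines <- c(lines, "", "## Recruitment trees")
    nd <- forest$nodes
    label <- if (anonymize) setNames(pseudonym(nd$participant_id),
                                     nd$participant_id)
             else setNames(as.character(nd$participant_id), nd$participant_id)
    for (sid in sort(unique(nd$seed_id))) {
      tree <- nd[nd$seed_id == sid, ]
      lines <- c(lines, sprintf("### Seed %s (%d nodes, depth %d)",
                                label[[as.character(sid)]], nrow(tree),
                                max(tree$wave)))
      tree <- tree[order(tree$wave, tree$participant_id), ]
      lines <- c(lines, vapply(seq_len(nrow(tree)), function(i)
        paste0(strrep("  ", tree$wave[i]), "- ",
               label[[as.character(tree$participant_id[i])]]),
        character(1)))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Check a report JSON file against the shipped schema
#'
#' Minimal structural validator: checks the required keys and value types
#' declared in `inst/schema/monitoring-report.schema.json` (recursively for
#' nested objects).  Not a full JSON-Schema engine — it covers the subset
#' the report schema uses.
#'
#' @param path JSON file to check.
#' @param schema_path Schema file; defaults to the shipped schema.
#' @return `TRUE` invisibly if valid, otherwise an error listing the first
#'   violation.
#' @export
validate_report_json <- function(path,
                                 schema_path = system.file(
                                   "schema", "monitoring-report.schema.json",
                                   package = "webrds")) {
  obj <- jsonlite::read_json(path)
  schema <- jsonlite::read_json(schema_path)
  check_node <- function(node, sch, where) {
    type <- sch$type
    ok <- switch(type,
      object = is.list(node) && (is.null(names(node)) == (length(node) == 0) ||
                                   !is.null(names(node))),
      array = is.list(node) || length(node) == 0,
      string = is.character(node) && length(node) == 1,
      number = is.numeric(node) && length(node) == 1,
      integer = is.numeric(node) && length(node) == 1,
      boolean = is.logical(node) && length(node) == 1,
      TRUE)
    if (!ok)
      stop_webrds(sprintf("Schema violation at %s: expected %s.", where, type),
                  "schema")
    if (type == "object") {
      for (req in unlist(sch$required)) {
        if (!req %in% names(node))
          stop_webrds(sprintf("Schema violation at %s: missing required key '%s'.",
                              where, req), "schema")
      }
      for (key in names(sch$properties)) {
        if (key %in% names(node))
          check_node(node[[key]], sch$properties[[key]],
                     paste0(where, ".", key))
      }
    }
    if (type == "array" && !is.null(sch$items)) {
      for (i in seq_along(node))
        check_node(node[[i]], sch$items, sprintf("%s[%d]", where, i))
    }
    invisible(TRUE)
  }
  check_node(obj, schema, "$")
  invisible(TRUE)
}
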