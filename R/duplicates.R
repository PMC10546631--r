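#' Detect probable duplicate responses
#'
#' Two-step screen for multiple participation, run on the response table.
#' Step 1 clusters responses whose normalised non-empty contact strings are
#' identical (lower-cased, whitespace and punctuation stripped; empty contact
#' never matches).  Step 2 clusters responses identical on every fingerprint
#' variable *and* on both network-size answers (`degree_known`,
#' `degree_contactable`).  Overlapping clusters from the two steps are
#' merged; singletons are never reported.
#'
#' @param responses Response tibble (see [responses()] /
#'   [read_responses()]); must contain `id`, `submitdate`, the degree columns
#'   and any fingerprint columns.
#' @param fingerprint_vars Character vector of attribute columns used by step
#'   2. Default: every column that is not one of the structural columns
#'   (`id`, `token`, `submitdate`, degree/diagnostic questions, `contact`).
#' @return A tibble with one row per duplicate cluster: `cluster_id`,
#'   `member_ids` (list-column of ids, >= 2), `evidence` (`"contact-match"`
#'   if any pair matched on contact, else `"answer-fingerprint-match"`), and
#'   `kept_id`, the member with the earliest `submitdate` (ties broken by
#'   lowest id) — the first response is the official one.
#' @export
detect_duplicates <- function(responses, fingerprint_vars = NULL) {
  structural <- c("id", "token", "submitdate", "degree_known",
                  "degree_contactable", "prior_known", "reciprocity", "contact")
  if (is.null(fingerprint_vars))
    fingerprint_vars <- setdiff(names(responses), structural)
  missing_vars <- setdiff(fingerprint_vars, names(responses))
  if (length(missing_vars))
    stop_webrds(sprintf("Unknown fingerprint variable(s): %s",
                        paste(missing_vars, collapse = ", ")), "validation")
  n <- nrow(responses)
  empty <- tibble(cluster_id = integer(), member_ids = list(),
                  evidence = character(), kept_id = integer())
  if (n < 2) return(empty)

  norm_contact <- tolower(gsub("[^a-z0-9]", "", tolower(
    ifelse(is.na(responses$contact), "", responses$contact))))
  key1 <- ifelse(nzchar(norm_contact), norm_contact, NA_character_)

  fp_cols <- c(fingerprint_vars, "degree_known", "degree_contactable")
  fp <- responses[fp_cols]
  key2 <- do.call(paste, c(lapply(fp, function(x) {
    x <- as.character(x)
    ifelse(is.na(x), "\x01NA", x)
  }), sep = "\x1f"))

  # Union-find over rows; an edge is "same contact key" or "same fingerprint".
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_grp <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  contact_hit <- logical(n)
  for (key in list(key1, key2)) {
    grp <- split(seq_len(n), key)
    for (g in grp) {
      if (length(g) >= 2) {
        for (j in g[-1]) union_grp(g[1], j)
        if (identical(key, key1)) contact_hit[g] <- TRUE
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  clusters <- split(seq_len(n), roots)
  clusters <- clusters[vapply(clusters, length, integer(1)) >= 2]
  if (!length(clusters)) return(empty)

  sub_num <- as_time_num(responses$submitdate)
  rows <- lapply(seq_along(clusters), function(ci) {
    g <- clusters[[ci]]
    ord <- order(sub_num[g], responses$id[g])
    tibble(
      cluster_id = ci,
      member_ids = list(sort(responses$id[g])),
      evidence = if (any(contact_hit[g])) "contact-match" else "answer-fingerprint-match",
      kept_id = responses$id[g][ord[1]]
    )
  })
  out <- bind_rows(rows)
  out[order(vapply(out$member_ids, min, numeric(1))), ]
}

#' Resolve duplicate clusters, keeping the first response
#'
#' For each cluster only the earliest response (`kept_id`) survives; the
#' removed rows are returned for the audit log, along with the recruiter
#' tokens their redemptions consumed — candidates for [grant_extra_uses()]
#' so the affected recruiters get their invitation uses back.
#'
#' @param responses Response tibble the clusters were detected on.
#' @param clusters Output of [detect_duplicates()] on the same table.
#' @return A list: `responses` (filtered table), `removed` (dropped rows),
#'   `refund_tokens` (character vector, one entry per removed non-seed row:
#'   the recruiter token whose use it consumed).
#' @export
resolve_duplicates <- function(responses, clusters) {
  if (nrow(clusters) == 0)
    return(list(responses = responses, removed = responses[0, ],
                refund_tokens = character(0)))
  all_members <- unlist(clusters$member_ids)
  unknown <- setdiff(all_members, responses$id)
  if (length(unknown))
    stop_webrds(sprintf("Cluster references unknown participant id(s): %s",
                        paste(unknown, collapse = ", ")), "validation")
  drop_ids <- setdiff(all_members, clusters$kept_id)
  removed <- responses[responses$id %in% drop_ids, ]
  refund <- removed$token[!is.na(removed$token) & nzchar(removed$token)]
  list(responses = responses[!responses$id %in% drop_ids, ],
       removed = removed,
       refund_tokens = refund)
}
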