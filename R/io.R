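#' Read and write the participant and response CSV dialects
#'
#' The package's table dialects mirror a LimeSurvey token/response export.
#' Participant CSV: `id,token,uses_left,is_seed,created_at,contact` (UTF-8,
#' ISO-8601 timestamps).  Response CSV:
#' `id,token,submitdate,degree_known,degree_contactable,prior_known,
#' reciprocity,<attribute columns...>,contact` — here `token` is the
#' *recruiter's* token the respondent redeemed (empty for seeds).
#'
#' Readers validate row by row: structurally broken rows (negative degrees,
#' `degree_contactable > degree_known`, missing id) are rejected and
#' reported with their line numbers in the `"rejected"` attribute of the
#' returned tibble; duplicate ids or duplicate tokens are a hard failure.
#'
#' @param path CSV file path.
#' @param table Tibble to write.
#' @return A validated tibble (readers); `path`, invisibly (writers).
#' @name table_io
NULL

check_header <- function(path, required, what) {
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(
                                    .default = readr::col_character())))
  miss <- setdiff(required, header)
  if (length(miss))
    stop_webrds(sprintf("%s CSV is missing required column(s): %s", what,
                        paste(miss, collapse = ", ")), "schema")
  invisible(TRUE)
}

#' @rdname table_io
#' @export
read_participants <- function(path) {
  if (!file.exists(path))
    stop_webrds(sprintf("File not found: %s", path), "not_found")
  required <- c("id", "token", "uses_left", "is_seed", "created_at")
  check_header(path, required, "Participant")
  tb <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(),
    token = readr::col_character(),
    uses_left = readr::col_integer(),
    is_seed = readr::col_logical(),
    created_at = readr::col_datetime(),
    contact = readr::col_character()
  ))
  bad <- is.na(tb$id) | is_blank(tb$token) | is.na(tb$uses_left) |
    tb$uses_left < 0 | is.na(tb$is_seed)
  bad[is.na(bad)] <- TRUE
  rejected <- tibble(line = which(bad) + 1L,
                     reason = "invalid id/token/uses_left/is_seed")
  tb <- tb[!bad, ]
  if (anyDuplicated(tb$id))
    stop_webrds("Duplicate participant ids in participant CSV.", "schema")
  if (anyDuplicated(tb$token))
    stop_webrds("Duplicate tokens in participant CSV.", "schema")
  attr(tb, "rejected") <- rejected
  tb
}

#' @rdname table_io
#' @export
read_responses <- function(path) {
  if (!file.exists(path))
    stop_webrds(sprintf("File not found: %s", path), "not_found")
  required <- c("id", "token", "submitdate", "degree_known",
                "degree_contactable", "prior_known", "reciprocity")
  check_header(path, required, "Response")
  tb <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_integer(),
    token = readr::col_character(),
    submitdate = readr::col_datetime(),
    degree_known = readr::col_integer(),
    degree_contactable = readr::col_integer(),
    prior_known = readr::col_integer(),
    reciprocity = readr::col_logical(),
    contact = readr::col_character(),
    .default = readr::col_character()
  ))
  neg <- function(x) !is.na(x) & x < 0
  bad_id <- is.na(tb$id)
  bad_deg <- neg(tb$degree_known) | neg(tb$degree_contactable) |
    neg(tb$prior_known) |
    (!is.na(tb$degree_known) & !is.na(tb$degree_contactable) &
       tb$degree_contactable > tb$degree_known)
  bad <- bad_id | bad_deg
  rejected <- tibble(
    line = which(bad) + 1L,
    reason = ifelse(bad_id[bad], "missing id", "invalid degree answers"))
  tb <- tb[!bad, ]
  if (anyDuplicated(tb$id))
    stop_webrds("Duplicate response ids in response CSV (resolve duplicates first).",
                "schema")
  attr(tb, "rejected") <- rejected
  tb
}

#' @rdname table_io
#' @export
write_participants <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' @rdname table_io
#' @export
write_responses <- function(table, path) {
  readr::write_csv(table, path, na = "")
  invisible(path)
}

#' Read a simulation configuration from YAML
#'
#' The YAML file may carry two top-level blocks, `population` and
#' `recruitment`, whose keys are the arguments of [population_config()] and
#' [sim_config()].
#'
#' @param path YAML file.
#' @return A list with elements `population` (`population_config`) and
#'   `recruitment` (`sim_config`).
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path))
    stop_webrds(sprintf("File not found: %s", path), "not_found")
  raw <- yaml::read_yaml(path)
  popargs <- raw$population %||% list()
  if (!is.null(popargs$traits)) {
    popargs$traits <- lapply(popargs$traits, function(tr)
      list(labels = as.character(tr$labels),
           prevalence = as.numeric(tr$prevalence)))
  }
  if (!is.null(popargs$degree_mu)) popargs$degree_mu <- unlist(popargs$degree_mu)
  list(population = do.call(population_config, popargs),
       recruitment = do.call(sim_config, raw$recruitment %||% list()))
}

#' Category percentage table from printed counts
#'
#' Recomputes per-variable sample percentages from a table of category
#' counts, using each variable's answered total as the denominator and
#' half-up one-decimal rounding — the convention used in published RDS
#' sample-description tables.
#'
#' @param counts Tibble/data frame with columns `variable`, `category`,
#'   `count`.
#' @return The input with a `pct` column added.
#' @examples
#' counts <- readr::read_csv(
#'   system.file("extdata", "homecare_sample_counts.csv", package = "webrds"),
#'   show_col_types = FALSE)
#' sample_percentages(counts)
#' @export
sample_percentages <- function(counts) {
  stopifnot(all(c("variable", "category", "count") %in% names(counts)))
  out <- as_tibble(counts)
  tot <- tapply(out$count, out$variable, sum)
  out$pct <- round_half_up(100 * out$count / as.numeric(tot[out$variable]), 1)
  out
}
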