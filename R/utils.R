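#' @importFrom rlang abort inform warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr arrange bind_rows filter group_by left_join mutate n
#'   rename select summarise ungroup
#' @importFrom stats median quantile rbinom rnbinom rnorm runif setNames
#' @importFrom utils head modifyList tail
NULL

# Half-up decimal rounding (round() in R rounds half to even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

stop_webrds <- function(message, class, ...) {
  abort(message, class = c(paste0("webrds_error_", class), "webrds_error"), ...)
}

# URL-safe opaque invitation tokens.  `existing` is a hashed environment used
# as a set, so uniqueness is enforced at creation.
new_token <- function(existing, nchar = 12) {
  alphabet <- c(letters, LETTERS, as.character(0:9), "-", "_")
  repeat {
    tok <- paste(sample(alphabet, nchar, replace = TRUE), collapse = "")
    if (is.null(existing[[tok]])) return(tok)
  }
}

as_time_num <- function(x) {
  if (inherits(x, "POSIXt")) return(as.numeric(x))
  if (is.character(x)) return(as.numeric(as.POSIXct(x, tz = "UTC")))
  as.numeric(x)
}

num_to_time <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

is_blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))
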