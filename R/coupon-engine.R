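#' Create an empty WebRDS study ledger
#'
#' An `rds_study` is the mutable ledger behind a chained-invitation (coupon)
#' recruitment survey.  Every participant who completes the survey receives a
#' fresh personal invitation token with a fixed use budget (three in the
#' default design); the token redeemed by each recruit records who invited
#' them, so the recruiter-to-recruit forest is recoverable from token linkage
#' alone.  The ledger also keeps an append-only audit log of administrative
#' events (extra-use grants, duplicate removals, seed removals).
#'
#' The object is environment-backed and modified in place by the verbs
#' [register_seed()], [redeem_token()], [complete_response()] and
#' [grant_extra_uses()], in the style of a connection or an R environment.
#' Each verb validates its inputs before touching any state, so a failed call
#' leaves the ledger untouched.
#'
#' @param coupon_budget Number of uses granted to every freshly issued
#'   invitation token (the per-recruiter coupon limit). Default 3.
#' @param token_nchar Length of generated tokens (URL-safe alphabet). Must be
#'   at least 12.
#' @param receipt_ttl Seconds after which an unconverted redemption receipt
#'   may be expired and its use refunded by [expire_receipts()]. Default `Inf`
#'   (never refund automatically; field practice is to reconcile by manual
#'   grants).
#' @return An object of class `rds_study`.
#' @seealso [participants()], [responses()], [audit_log()],
#'   [coupon_conservation()]
#' @examples
#' st <- rds_study()
#' register_seed(st, attributes = c(gender = "woman"),
#'               degree_known = 12, degree_contactable = 5)
#' participants(st)
#' @export
rds_study <- function(coupon_budget = 3, token_nchar = 12, receipt_ttl = Inf) {
  stopifnot(coupon_budget >= 1, token_nchar >= 12)
  s <- new.env(parent = emptyenv())
  s$coupon_budget <- as.integer(coupon_budget)
  s$token_nchar <- as.integer(token_nchar)
  s$receipt_ttl <- receipt_ttl
  s$n <- 0L
  s$cap <- 64L
  s$id <- integer(64L)
  s$token <- character(64L)
  s$uses_left <- integer(64L)
  s$lifetime <- integer(64L)      # initial budget + administrative grants
  s$is_seed <- logical(64L)
  s$removed <- logical(64L)
  s$created_at <- numeric(64L)
  s$submitted_at <- numeric(64L)
  s$token_used <- character(64L)  # NA for seeds
  s$degree_known <- integer(64L)
  s$degree_contactable <- integer(64L)
  s$prior_known <- integer(64L)
  s$reciprocity <- logical(64L)
  s$contact <- character(64L)
  s$attr_names <- character(0)
  s$attrs <- list()
  s$token_index <- new.env(hash = TRUE, parent = emptyenv())
  s$redeemed_total <- 0L
  s$audit <- vector("list", 32L)
  s$audit_n <- 0L
  s$receipts <- new.env(hash = TRUE, parent = emptyenv())
  s$receipt_seq <- 0L
  class(s) <- "rds_study"
  s
}

#' @export
print.rds_study <- function(x, ...) {
  cat(sprintf(
    "<rds_study> %d participants (%d seeds), coupon budget %d, %d audit events\n",
    sum(!x$removed[seq_len(x$n)]),
    sum(x$is_seed[seq_len(x$n)] & !x$removed[seq_len(x$n)]),
    x$coupon_budget, x$audit_n))
  invisible(x)
}

grow_study <- function(s, need) {
  while (s$n + need > s$cap) {
    newcap <- s$cap * 2L
    for (f in c("id", "token", "uses_left", "lifetime", "is_seed", "removed",
                "created_at", "submitted_at", "token_used", "degree_known",
                "degree_contactable", "prior_known", "reciprocity", "contact")) {
      v <- s[[f]]
      length(v) <- newcap
      s[[f]] <- v
    }
    s$attrs <- lapply(s$attrs, function(v) { length(v) <- newcap; v })
    s$cap <- newcap
  }
}

audit_append <- function(s, event, token, delta, reason, at) {
  s$audit_n <- s$audit_n + 1L
  if (s$audit_n > length(s$audit)) length(s$audit) <- 2L * length(s$audit)
  s$audit[[s$audit_n]] <- list(event = event, token = token,
                               delta = as.integer(delta), reason = reason,
                               at = as_time_num(at))
  invisible(s)
}

validate_answers <- function(degree_known, degree_contactable, prior_known,
                             reciprocity, attributes) {
  dk <- degree_known; dc <- degree_contactable; pk <- prior_known
  if (!is.null(attributes)) {
    if (length(attributes) == 0 || is.null(names(attributes)) ||
        any(!nzchar(names(attributes))))
      stop_webrds("`attributes` must be a non-empty named vector or list.",
                  "validation")
  }
  for (v in list(dk = dk, dc = dc, pk = pk)) {
    if (length(v) != 1 || (!is.na(v) && (!is.numeric(v) || v < 0 || v != floor(v))))
      stop_webrds("Degree questions must be single non-negative integers or NA.",
                  "validation")
  }
  if (!is.na(dk) && !is.na(dc) && dc > dk)
    stop_webrds(
      sprintf("degree_contactable (%d) cannot exceed degree_known (%d).", dc, dk),
      "validation")
  if (length(reciprocity) != 1 || !(is.logical(reciprocity) || is.na(reciprocity)))
    stop_webrds("`reciprocity` must be TRUE, FALSE or NA.", "validation")
  invisible(TRUE)
}

add_participant <- function(s, is_seed, token_used, attributes,
                            degree_known, degree_contactable, prior_known,
                            reciprocity, contact, now) {
  grow_study(s, 1L)
  i <- s$n + 1L
  tok <- new_token(s$token_index, s$token_nchar)
  s$n <- i
  s$id[i] <- i
  s$token[i] <- tok
  s$uses_left[i] <- s$coupon_budget
  s$lifetime[i] <- s$coupon_budget
  s$is_seed[i] <- is_seed
  s$removed[i] <- FALSE
  s$created_at[i] <- as_time_num(now)
  s$submitted_at[i] <- as_time_num(now)
  s$token_used[i] <- if (is.null(token_used)) NA_character_ else token_used
  s$degree_known[i] <- as.integer(degree_known)
  s$degree_contactable[i] <- as.integer(degree_contactable)
  s$prior_known[i] <- as.integer(prior_known)
  s$reciprocity[i] <- as.logical(reciprocity)
  s$contact[i] <- if (is.null(contact)) NA_character_ else as.character(contact)
  attributes <- lapply(attributes, as.character)
  newvars <- setdiff(names(attributes), s$attr_names)
  for (v in newvars) {
    s$attr_names <- c(s$attr_names, v)
    s$attrs[[v]] <- rep(NA_character_, s$cap)
  }
  for (v in s$attr_names) {
    s$attrs[[v]][i] <- if (v %in% names(attributes)) attributes[[v]] else NA_character_
  }
  assign(tok, i, envir = s$token_index)
  i
}

#' Register a seed participant
#'
#' Seeds are the researcher-chosen wave-0 respondents: they are enrolled
#' without redeeming anyone's token and receive a fresh invitation token with
#' the full coupon budget.
#'
#' @param study An [rds_study()] ledger (modified in place).
#' @param attributes Named character vector or list of categorical attributes
#'   (e.g. gender, age band, working-area size). Must be non-empty.
#' @param degree_known Self-reported number of target-population members the
#'   respondent knows (network-size question 1).
#' @param degree_contactable Of those, the number contactable right now
#'   (question 2); this is the degree used by the RDS-II estimator. Cannot
#'   exceed `degree_known`.
#' @param prior_known Number of prior study participants known besides the
#'   recruiter (finite-population diagnostic, question 3). Default 0.
#' @param reciprocity Would the recruiter be among the respondent's own
#'   invitees (reciprocity diagnostic, question 4)? `TRUE`/`FALSE`/`NA`.
#' @param contact Optional free-text contact information.
#' @param now Timestamp of the registration (injectable for determinism).
#' @return Invisibly, a list with the new `participant_id` and `token`.
#' @export
register_seed <- function(study, attributes, degree_known, degree_contactable,
                          prior_known = 0, reciprocity = NA, contact = NULL,
                          now = Sys.time()) {
  stopifnot(inherits(study, "rds_study"))
  validate_answers(degree_known, degree_contactable, prior_known, reciprocity,
                   attributes)
  i <- add_participant(study, TRUE, NULL, attributes, degree_known,
                       degree_contactable, prior_known, reciprocity, contact, now)
  audit_append(study, "seed_registered", study$token[i], study$coupon_budget,
               "seed", now)
  invisible(list(participant_id = study$id[i], token = study$token[i]))
}

#' Redeem an invitation token
#'
#' Decrements the token's remaining use budget by one and returns a one-shot
#' redemption receipt identifying the recruiter.  The receipt must be handed
#' to [complete_response()] to enroll the recruit; an abandoned receipt (link
#' clicked, survey never finished) can later be expired and refunded with
#' [expire_receipts()].
#'
#' @param study An [rds_study()] ledger (modified in place).
#' @param token The token string being redeemed.
#' @param now Timestamp of the redemption.
#' @return A receipt (class `rds_receipt`) with `receipt_id`, `recruiter_id`,
#'   `token` and `at`.
#' @section Errors: an unknown token raises a `webrds_error_not_found`
#'   condition; an exhausted token (zero uses left) raises
#'   `webrds_error_already_used` — the two cases are distinguishable, matching
#'   the "invite link has already been used" situation handled in the field.
#' @export
redeem_token <- function(study, token, now = Sys.time()) {
  stopifnot(inherits(study, "rds_study"))
  i <- study$token_index[[token]]
  if (is.null(i) || study$removed[i])
    stop_webrds(sprintf("Token '%s' does not exist.", token), "not_found")
  if (study$uses_left[i] <= 0L)
    stop_webrds(sprintf("Invite link '%s' has already been used (no uses left).",
                        token), "already_used")
  study$uses_left[i] <- study$uses_left[i] - 1L
  study$redeemed_total <- study$redeemed_total + 1L
  study$receipt_seq <- study$receipt_seq + 1L
  rid <- study$receipt_seq
  receipt <- list(receipt_id = rid, recruiter_id = study$id[i], token = token,
                  at = as_time_num(now))
  assign(as.character(rid),
         list(recruiter_id = study$id[i], token = token,
              at = as_time_num(now), used = FALSE),
         envir = study$receipts)
  audit_append(study, "redeemed", token, -1L, "redemption", now)
  structure(receipt, class = "rds_receipt")
}

#' Complete a survey response and enroll the recruit
#'
#' Consumes a redemption receipt from [redeem_token()] and creates the new
#' participant: their identity becomes the access code of a fresh personal
#' invitation token carrying the full coupon budget, and the response stores
#' the recruiter's token, which establishes the recruiter-to-recruit edge.
#'
#' @inheritParams register_seed
#' @param receipt A receipt returned by [redeem_token()]. Each receipt can be
#'   consumed exactly once, so one redemption can never spawn two respondents.
#' @return Invisibly, a list with the new `participant_id` and `token`.
#' @export
complete_response <- function(study, receipt, attributes, degree_known,
                              degree_contactable, prior_known = 0,
                              reciprocity = NA, contact = NULL,
                              now = Sys.time()) {
  stopifnot(inherits(study, "rds_study"))
  if (!inherits(receipt, "rds_receipt"))
    stop_webrds("`receipt` must come from redeem_token().", "receipt")
  rec <- study$receipts[[as.character(receipt$receipt_id)]]
  if (is.null(rec))
    stop_webrds("Unknown or expired redemption receipt.", "receipt")
  if (rec$used)
    stop_webrds("Redemption receipt has already been consumed.", "receipt")
  validate_answers(degree_known, degree_contactable, prior_known, reciprocity,
                   attributes)
  rec$used <- TRUE
  assign(as.character(receipt$receipt_id), rec, envir = study$receipts)
  i <- add_participant(study, FALSE, rec$token, attributes, degree_known,
                       degree_contactable, prior_known, reciprocity, contact, now)
  audit_append(study, "completed", study$token[i], study$coupon_budget,
               sprintf("recruited via %s", rec$token), now)
  invisible(list(participant_id = study$id[i], token = study$token[i]))
}

#' Grant extra uses to a token
#'
#' Administrative correction used when a link was misused (e.g. a participant
#' shared their inbound link instead of their own) or uses were consumed by
#' duplicate responses: the affected token is topped up and the action is
#' recorded in the study log.
#'
#' @param study An [rds_study()] ledger (modified in place).
#' @param token Token to top up.
#' @param n Number of extra uses (>= 1).
#' @param reason Free-text justification recorded in the audit log.
#' @param now Timestamp.
#' @return Invisibly, the updated uses-left count.
#' @export
grant_extra_uses <- function(study, token, n, reason, now = Sys.time()) {
  stopifnot(inherits(study, "rds_study"))
  if (length(n) != 1 || !is.numeric(n) || n < 1 || n != floor(n))
    stop_webrds("`n` must be a positive integer.", "validation")
  i <- study$token_index[[token]]
  if (is.null(i) || study$removed[i])
    stop_webrds(sprintf("Token '%s' does not exist.", token), "not_found")
  study$uses_left[i] <- study$uses_left[i] + as.integer(n)
  study$lifetime[i] <- study$lifetime[i] + as.integer(n)
  audit_append(study, "grant", token, as.integer(n), reason, now)
  invisible(study$uses_left[i])
}

#' Expire stale redemption receipts and refund their uses
#'
#' A redemption decrements the token's budget immediately; if the recruit
#' never completes the survey the use is lost.  When the study is created
#' with a finite `receipt_ttl`, this verb refunds every unconsumed receipt
#' older than the TTL.  Off by default (`receipt_ttl = Inf`).
#'
#' @param study An [rds_study()] ledger (modified in place).
#' @param now Current timestamp.
#' @return Invisibly, the number of receipts refunded.
#' @export
expire_receipts <- function(study, now = Sys.time()) {
  stopifnot(inherits(study, "rds_study"))
  nownum <- as_time_num(now)
  refunded <- 0L
  for (rid in ls(study$receipts)) {
    rec <- study$receipts[[rid]]
    if (!rec$used && (nownum - rec$at) >= study$receipt_ttl) {
      i <- study$token_index[[rec$token]]
      study$uses_left[i] <- study$uses_left[i] + 1L
      study$redeemed_total <- study$redeemed_total - 1L
      rm(list = rid, envir = study$receipts)
      audit_append(study, "receipt_expired", rec$token, 1L, "TTL refund", now)
      refunded <- refunded + 1L
    }
  }
  invisible(refunded)
}

# Tombstone a participant (duplicate resolution, seed removal).
remove_participant <- function(study, id, reason, now = Sys.time()) {
  i <- match(id, study$id[seq_len(study$n)])
  if (is.na(i) || study$removed[i])
    stop_webrds(sprintf("Participant %s not found.", id), "not_found")
  study$removed[i] <- TRUE
  audit_append(study, "participant_removed", study$token[i], 0L, reason, now)
  invisible(study)
}

#' Participant and response tables of a study ledger
#'
#' `participants()` returns the token table (one row per enrolled
#' participant: own token, remaining uses, seed flag); `responses()` returns
#' the survey-response table (inbound `token` used, the four network
#' questions, categorical attributes).  Column layout matches the package's
#' CSV dialects (see [read_participants()]).
#'
#' @param x An `rds_study` or an `rds_simulation`.
#' @return A tibble.
#' @export
participants <- function(x) UseMethod("participants")

#' @rdname participants
#' @export
responses <- function(x) UseMethod("responses")

#' @export
participants.rds_study <- function(x) {
  k <- which(!x$removed[seq_len(x$n)])
  tibble(
    id = x$id[k],
    token = x$token[k],
    uses_left = x$uses_left[k],
    is_seed = x$is_seed[k],
    created_at = num_to_time(x$created_at[k]),
    contact = x$contact[k]
  )
}

#' @export
responses.rds_study <- function(x) {
  k <- which(!x$removed[seq_len(x$n)])
  out <- tibble(
    id = x$id[k],
    token = x$token_used[k],
    submitdate = num_to_time(x$submitted_at[k]),
    degree_known = x$degree_known[k],
    degree_contactable = x$degree_contactable[k],
    prior_known = x$prior_known[k],
    reciprocity = x$reciprocity[k]
  )
  for (v in x$attr_names) out[[v]] <- x$attrs[[v]][k]
  out$contact <- x$contact[k]
  out
}

#' Audit log of administrative events
#'
#' @param study An [rds_study()].
#' @return A tibble with columns `event`, `token`, `delta`, `reason`, `at`
#'   (append-only; one row per ledger event).
#' @export
audit_log <- function(study) {
  stopifnot(inherits(study, "rds_study"))
  entries <- study$audit[seq_len(study$audit_n)]
  tibble(
    event = vapply(entries, `[[`, character(1), "event"),
    token = vapply(entries, `[[`, character(1), "token"),
    delta = vapply(entries, `[[`, integer(1), "delta"),
    reason = vapply(entries, `[[`, character(1), "reason"),
    at = num_to_time(vapply(entries, `[[`, numeric(1), "at"))
  )
}

#' Coupon-use conservation check
#'
#' For any sequence of ledger events, total lifetime grants (initial budgets
#' plus administrative top-ups) minus successful redemptions must equal the
#' total remaining uses across all tokens.  Exposed so monitoring and tests
#' can assert the ledger never leaks or invents coupon uses.
#'
#' @param study An [rds_study()].
#' @return A list with `granted`, `redeemed`, `uses_left_total` and the
#'   logical `balanced`.
#' @export
coupon_conservation <- function(study) {
  stopifnot(inherits(study, "rds_study"))
  k <- seq_len(study$n)  # tombstoned rows keep their grant history
  granted <- sum(study$lifetime[k])
  left <- sum(study$uses_left[k])
  list(granted = granted, redeemed = study$redeemed_total,
       uses_left_total = left,
       balanced = granted - study$redeemed_total == left)
}
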