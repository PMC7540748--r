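# Long-format trial data: loading, validation, missing-response scoring,
# accuracy, and participant exclusion.

.default_roles <- c("animal", "object", "location")
.responses <- c("correct", "incorrect", "missing")

#' Study-level analysis configuration
#'
#' Bundles the design constants and exclusion rules used throughout an
#' analysis: the number of events per condition, the forced-choice chance
#' level, and the ceiling/floor accuracy thresholds at which participants
#' are excluded.
#'
#' Both thresholds are inclusive: a participant at exactly the ceiling
#' (or floor) is excluded. The ceiling rule exists because at very high
#' accuracy the observed proportion of joint retrieval cannot exceed the
#' independent model, so the dependency statistic is bounded towards zero;
#' the floor rule removes participants performing at or near chance.
#'
#' @param n_events Number of events per condition (typically 15 or 30).
#' @param chance_level Chance success probability of the forced-choice
#'   test; 0.25 for four-alternative forced choice.
#' @param ceiling_threshold Accuracy at or above which a participant is
#'   excluded (default 0.95).
#' @param floor_threshold Accuracy at or below which a participant is
#'   excluded, or `NULL` to disable the floor rule (default 0.30 in the
#'   single-condition designs; `NULL` mirrors designs with no floor rule).
#' @param exclusion_scope `"average"` applies the thresholds to the
#'   unweighted mean of per-condition accuracies (the within-subject
#'   two-condition regime); `"overall"` applies them to accuracy pooled
#'   over all trials (the single-condition regime).
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config(n_events = 15, floor_threshold = 0.30)
#' @export
study_config <- function(n_events = 15, chance_level = 0.25,
                         ceiling_threshold = 0.95, floor_threshold = NULL,
                         exclusion_scope = c("average", "overall")) {
  exclusion_scope <- match.arg(exclusion_scope)
  stopifnot(is.numeric(n_events), length(n_events) == 1L, n_events >= 1,
            n_events == round(n_events),
            is.numeric(chance_level), chance_level > 0, chance_level < 1,
            is.numeric(ceiling_threshold),
            ceiling_threshold > 0, ceiling_threshold <= 1)
  if (!is.null(floor_threshold)) {
    stopifnot(is.numeric(floor_threshold), floor_threshold > 0)
    if (floor_threshold >= ceiling_threshold)
      stop("`floor_threshold` must be strictly below `ceiling_threshold`")
  }
  structure(list(n_events = as.integer(n_events),
                 chance_level = chance_level,
                 ceiling_threshold = ceiling_threshold,
                 floor_threshold = floor_threshold,
                 exclusion_scope = exclusion_scope),
            class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat("  events per condition:", x$n_events, "\n")
  cat("  chance level:        ", x$chance_level, "\n")
  cat("  ceiling exclusion:    >= ", x$ceiling_threshold, "\n", sep = "")
  cat("  floor exclusion:     ",
      if (is.null(x$floor_threshold)) "none"
      else paste0("<= ", x$floor_threshold), "\n", sep = "")
  cat("  exclusion scope:     ", x$exclusion_scope, "\n", sep = "")
  invisible(x)
}

# The six directed cue -> target pairs over an ordered role triple, in
# canonical order: (1,2) (1,3) (2,1) (2,3) (3,1) (3,2).
directed_pairs <- function(roles = .default_roles) {
  stopifnot(length(roles) == 3L, !anyDuplicated(roles))
  idx <- cbind(cue = rep(1:3, each = 2L),
               target = c(2L, 3L, 1L, 3L, 1L, 2L))
  idx <- idx[idx[, 1] != idx[, 2], , drop = FALSE]
  data.frame(cue_role = roles[idx[, 1]], target_role = roles[idx[, 2]],
             stringsAsFactors = FALSE)
}

infer_roles <- function(trials, roles = NULL) {
  if (!is.null(roles)) {
    stopifnot(length(roles) == 3L, !anyDuplicated(roles))
    return(roles)
  }
  seen <- unique(c(trials$cue_role, trials$target_role))
  if (setequal(seen, .default_roles)) return(.default_roles)
  if (length(seen) != 3L)
    stop("expected exactly three element roles, found: ",
         paste(seen, collapse = ", "))
  sort(seen)
}

required_columns <- c("participant_id", "condition_id", "event_id",
                      "cue_role", "target_role", "response")

# Validates structure: vocabulary, cue != target, no duplicate directed
# pairs, and completeness (exactly the six directed pairs per
# participant/condition/event).
validate_trials <- function(trials, roles = NULL) {
  miss <- setdiff(required_columns, names(trials))
  if (length(miss))
    stop("trial table is missing required columns: ",
         paste(miss, collapse = ", "))
  roles <- infer_roles(trials, roles)

  bad_role <- which(!(trials$cue_role %in% roles) |
                    !(trials$target_role %in% roles))
  if (length(bad_role))
    stop("row ", bad_role[1], ": cue_role/target_role '",
         trials$cue_role[bad_role[1]], "'/'", trials$target_role[bad_role[1]],
         "' not in the configured roles (", paste(roles, collapse = ", "), ")")

  bad_resp <- which(!(trials$response %in% .responses))
  if (length(bad_resp))
    stop("row ", bad_resp[1], ": field 'response' has value '",
         trials$response[bad_resp[1]], "', expected one of ",
         paste(.responses, collapse = "/"))

  same <- which(trials$cue_role == trials$target_role)
  if (length(same))
    stop("row ", same[1], ": cue_role equals target_role ('",
         trials$cue_role[same[1]], "')")

  key <- paste(trials$participant_id, trials$condition_id, trials$event_id,
               trials$cue_role, trials$target_role, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("row ", dup[1], ": duplicate trial for participant '",
         trials$participant_id[dup[1]], "', condition '",
         trials$condition_id[dup[1]], "', event ",
         trials$event_id[dup[1]], ", pair ", trials$cue_role[dup[1]],
         " -> ", trials$target_role[dup[1]])

  pairs <- directed_pairs(roles)
  pair_lab <- paste0(pairs$cue_role, "->", pairs$target_role)
  ekey <- paste(trials$participant_id, trials$condition_id, trials$event_id,
                sep = "\r")
  for (k in split(seq_len(nrow(trials)), ekey)) {
    if (length(k) == 6L) next
    have <- paste0(trials$cue_role[k], "->", trials$target_role[k])
    missing_pairs <- setdiff(pair_lab, have)
    stop("incomplete event: participant '", trials$participant_id[k[1]],
         "', condition '", trials$condition_id[k[1]], "', event ",
         trials$event_id[k[1]], " has ", length(k),
         " trials; missing pair(s): ",
         paste(missing_pairs, collapse = ", "))
  }
  invisible(roles)
}

#' Load long-format retrieval-trial data
#'
#' Reads a comma-separated UTF-8 file with one row per retrieval trial and
#' header columns `participant_id`, `condition_id`, `event_id`, `cue_role`,
#' `target_role`, `response` (plus optional `block` and `trial_index`).
#' Responses must be `correct`, `incorrect` or `missing`, or values mapped
#' onto those via `response_map` (e.g. `c("1" = "correct", "0" =
#' "incorrect", "NA" = "missing")` for 1/0/NA exports).
#'
#' Validation is strict: unknown roles or responses, duplicated directed
#' pairs, and incomplete events (anything other than the six directed
#' cue -> target pairs per participant/condition/event) are errors naming
#' the offending row or event.
#'
#' @param path Path to the CSV file.
#' @param response_map Optional named character vector mapping file values
#'   to `correct`/`incorrect`/`missing`.
#' @param roles Optional ordered character triple of element roles;
#'   inferred from the data when omitted.
#' @return A tibble of validated trials.
#' @seealso [save_trials()], [score_missing()]
#' @export
load_trials <- function(path, response_map = NULL, roles = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L) stop("empty trial file: ", path)
  miss <- setdiff(required_columns, names(raw))
  if (length(miss))
    stop("header is missing required columns: ", paste(miss, collapse = ", "))

  if (!is.null(response_map)) {
    key <- raw$response
    key[is.na(key) | key == ""] <- "NA"  # blank cells are missing responses
    mapped <- unname(response_map[key])
    bad <- which(is.na(mapped))
    if (length(bad))
      stop("row ", bad[1], ": field 'response' has unmapped value '",
           raw$response[bad[1]], "'")
    raw$response <- mapped
  }

  ev <- suppressWarnings(as.integer(raw$event_id))
  bad_ev <- which(is.na(ev) | ev < 1L)
  if (length(bad_ev))
    stop("row ", bad_ev[1], ": field 'event_id' has value '",
         raw$event_id[bad_ev[1]], "', expected a positive integer")

  trials <- tibble::tibble(
    participant_id = raw$participant_id,
    condition_id   = raw$condition_id,
    event_id       = ev,
    cue_role       = raw$cue_role,
    target_role    = raw$target_role,
    response       = raw$response,
    block          = if ("block" %in% names(raw))
      suppressWarnings(as.integer(raw$block)) else NA_integer_,
    trial_index    = if ("trial_index" %in% names(raw))
      suppressWarnings(as.integer(raw$trial_index)) else NA_integer_)
  validate_trials(trials, roles)
  trials
}

#' Write trials to CSV
#'
#' Inverse of [load_trials()]: writes the canonical comma-separated
#' long-format dialect, so that a save/load round trip reproduces the
#' trial table field for field.
#'
#' @param trials A trial tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Score missing responses as incorrect
#'
#' Retrieval trials that timed out carry no response; for analysis they
#' are counted as incorrect. The pre-scoring missing proportion per
#' participant is retained in the `missing_rates` attribute (see
#' [missing_rates()]) for reporting.
#'
#' @param trials A trial tibble with responses in
#'   `correct`/`incorrect`/`missing`.
#' @return The trial tibble with every `missing` replaced by `incorrect`;
#'   the number of rows never changes.
#' @export
score_missing <- function(trials) {
  rates <- missing_rates(trials)
  trials$response[trials$response == "missing"] <- "incorrect"
  attr(trials, "missing_rates") <- rates
  trials
}

#' Per-participant missing-response proportions
#'
#' @param trials A trial tibble (scored or unscored; for a scored table
#'   the rates recorded by [score_missing()] are returned).
#' @return A tibble with `participant_id`, `n_missing`, `n_trials`,
#'   `prop_missing`.
#' @export
missing_rates <- function(trials) {
  pre <- attr(trials, "missing_rates")
  if (!is.null(pre)) return(pre)
  n <- tapply(trials$response, trials$participant_id, length)
  m <- tapply(trials$response == "missing", trials$participant_id, sum)
  tibble::tibble(participant_id = names(n),
                 n_missing = as.integer(m),
                 n_trials = as.integer(n),
                 prop_missing = as.numeric(m / n))
}

#' Retrieval accuracy
#'
#' Proportion of correct trials, at the requested grain. Missing
#' responses must already have been scored (see [score_missing()]).
#'
#' @param trials A scored trial tibble.
#' @param by One of `"participant"` (one row per participant, pooled over
#'   conditions), `"participant_condition"`, `"condition"`, or
#'   `"overall"`.
#' @return A tibble with an `accuracy` column, or a single number for
#'   `by = "overall"`.
#' @export
accuracy <- function(trials, by = c("participant", "participant_condition",
                                    "condition", "overall")) {
  by <- match.arg(by)
  if (nrow(trials) == 0L) stop("no trials in scope: cannot compute accuracy")
  if (any(trials$response == "missing"))
    stop("trials contain missing responses; run score_missing() first")
  correct <- trials$response == "correct"
  if (by == "overall") return(mean(correct))
  key <- switch(by,
    participant = list(participant_id = trials$participant_id),
    condition = list(condition_id = trials$condition_id),
    participant_condition = list(participant_id = trials$participant_id,
                                 condition_id = trials$condition_id))
  agg <- stats::aggregate(correct, by = key, FUN = mean)
  names(agg)[ncol(agg)] <- "accuracy"
  tibble::as_tibble(agg[do.call(order, unname(agg[-ncol(agg)])), ,
                        drop = FALSE])
}

#' Apply ceiling/floor participant exclusions
#'
#' Partitions participants into included and excluded sets according to
#' the inclusive accuracy thresholds in a [study_config()]. With scope
#' `"average"` the thresholds are applied to the unweighted mean of a
#' participant's per-condition accuracies; with `"overall"` to accuracy
#' pooled over all their trials. A participant at or above the ceiling is
#' excluded with reason `"ceiling"`; at or below the floor (when a floor
#' rule is configured) with reason `"floor"`.
#'
#' The operation is idempotent and a true partition: every input trial
#' appears in exactly one of `included` and `excluded`.
#'
#' @param trials A scored trial tibble.
#' @param config A [study_config()].
#' @return A list with `included` and `excluded` trial tibbles and a
#'   `report` tibble (`participant_id`, `accuracy`, `reason`) for the
#'   excluded participants.
#' @export
apply_exclusions <- function(trials, config) {
  stopifnot(inherits(config, "study_config"))
  acc <- if (config$exclusion_scope == "average") {
    pc <- accuracy(trials, by = "participant_condition")
    agg <- stats::aggregate(pc$accuracy, list(participant_id = pc$participant_id),
                            FUN = mean)
    stats::setNames(agg$x, agg$participant_id)
  } else {
    p <- accuracy(trials, by = "participant")
    stats::setNames(p$accuracy, p$participant_id)
  }
  eps <- 1e-12  # inclusive thresholds, robust to float representation
  reason <- rep(NA_character_, length(acc))
  reason[acc >= config$ceiling_threshold - eps] <- "ceiling"
  if (!is.null(config$floor_threshold))
    reason[is.na(reason) & acc <= config$floor_threshold + eps] <- "floor"
  out <- !is.na(reason)
  excluded_ids <- names(acc)[out]
  list(
    included = trials[!(trials$participant_id %in% excluded_ids), ,
                      drop = FALSE],
    excluded = trials[trials$participant_id %in% excluded_ids, ,
                      drop = FALSE],
    report = tibble::tibble(participant_id = excluded_ids,
                            accuracy = unname(acc[out]),
                            reason = reason[out]))
}
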