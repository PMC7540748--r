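# Retrieval dependency: six contingency tables per participant/condition
# (common cue and common target), observed joint retrieval vs. the
# independent model built from participant-level marginal accuracies.

# Table layout over the canonical directed-pair order
# (1,2) (1,3) (2,1) (2,3) (3,1) (3,2): for each role k, the common-cue
# table pairs the two trials cued by k, and the common-target table pairs
# the two trials whose target is k. Every directed pair enters exactly
# one common-cue and one common-target table.
contingency_layout <- function(roles = .default_roles) {
  pairs <- directed_pairs(roles)
  pair_lab <- paste0(pairs$cue_role, "->", pairs$target_role)
  cue_idx <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L))
  tgt_idx <- list(c(3L, 5L), c(1L, 6L), c(2L, 4L))
  data.frame(
    table_id = 1:6,
    kind = rep(c("common_cue", "common_target"), each = 3L),
    shared_role = rep(roles, 2L),
    i1 = c(vapply(cue_idx, `[`, integer(1), 1L),
           vapply(tgt_idx, `[`, integer(1), 1L)),
    i2 = c(vapply(cue_idx, `[`, integer(1), 2L),
           vapply(tgt_idx, `[`, integer(1), 2L)),
    pair_1 = pair_lab[c(1L, 3L, 5L, 3L, 1L, 2L)],
    pair_2 = pair_lab[c(2L, 4L, 6L, 5L, 6L, 4L)],
    stringsAsFactors = FALSE)
}

# n_events x 6 logical matrix of trial outcomes for a single
# participant/condition, columns in canonical directed-pair order.
outcome_matrix <- function(trials, roles = NULL) {
  roles <- infer_roles(trials, roles)
  if (any(trials$response == "missing"))
    stop("trials contain missing responses; run score_missing() first")
  pairs <- directed_pairs(roles)
  pidx <- match(paste(trials$cue_role, trials$target_role),
                paste(pairs$cue_role, pairs$target_role))
  if (anyNA(pidx)) stop("unknown cue/target role combination")
  events <- sort(unique(trials$event_id))
  eidx <- match(trials$event_id, events)
  M <- matrix(NA, nrow = length(events), ncol = 6L)
  M[cbind(eidx, pidx)] <- trials$response == "correct"
  if (anyNA(M)) {
    bad <- events[which(rowSums(is.na(M)) > 0L)]
    stop("incomplete event(s): ", paste(bad, collapse = ", "),
         " (each event needs all six directed retrieval trials)")
  }
  rownames(M) <- events
  colnames(M) <- paste0(pairs$cue_role, "->", pairs$target_role)
  M
}

single_group <- function(trials, participant = NULL, condition = NULL) {
  if (!is.null(participant))
    trials <- trials[trials$participant_id %in% participant, , drop = FALSE]
  if (!is.null(condition))
    trials <- trials[trials$condition_id %in% condition, , drop = FALSE]
  if (nrow(trials) == 0L) stop("no trials selected")
  if (length(unique(trials$participant_id)) > 1L ||
      length(unique(trials$condition_id)) > 1L)
    stop("trials span multiple participants/conditions; ",
         "select one with `participant` and `condition`, ",
         "or use dependency_scores() for all of them")
  trials
}

#' Build the six contingency tables for one participant and condition
#'
#' For each of the three element roles, one 2x2 table classifies every
#' event by the joint outcome of the two retrieval trials that share that
#' role as cue (`common_cue`), and one by the joint outcome of the two
#' trials that share it as target (`common_target`). Cell counts are
#' `cc` (both correct), `ci`, `ic`, and `ii` (both incorrect), and sum to
#' the number of events.
#'
#' @param trials A scored trial tibble.
#' @param participant,condition Selectors when `trials` holds more than
#'   one participant or condition.
#' @param roles Optional ordered role triple.
#' @return A tibble with one row per table: `table_id`, `kind`,
#'   `shared_role`, `pair_1`, `pair_2`, `cc`, `ci`, `ic`, `ii`,
#'   `n_events`.
#' @examples
#' cfg <- generator_config(n_participants = 1, seed = 42)
#' trials <- simulate_trials(cfg)
#' build_contingency_tables(trials)
#' @export
build_contingency_tables <- function(trials, participant = NULL,
                                     condition = NULL, roles = NULL) {
  trials <- single_group(trials, participant, condition)
  roles <- infer_roles(trials, roles)
  M <- outcome_matrix(trials, roles)
  lay <- contingency_layout(roles)
  n <- nrow(M)
  cc <- ci <- ic <- ii <- integer(6)
  for (t in 1:6) {
    a <- M[, lay$i1[t]]; b <- M[, lay$i2[t]]
    cc[t] <- sum(a & b); ci[t] <- sum(a & !b)
    ic[t] <- sum(!a & b); ii[t] <- sum(!a & !b)
  }
  tibble::tibble(table_id = lay$table_id, kind = lay$kind,
                 shared_role = lay$shared_role,
                 pair_1 = lay$pair_1, pair_2 = lay$pair_2,
                 cc = cc, ci = ci, ic = ic, ii = ii, n_events = n)
}

#' Observed proportion of joint retrieval
#'
#' The proportion of events showing contingent accuracy in a contingency
#' table: both trials correct or both incorrect, `(cc + ii) / n_events`.
#'
#' @param tables A contingency-table tibble from
#'   [build_contingency_tables()] (any number of rows).
#' @return A numeric vector, one proportion per table.
#' @export
joint_retrieval_data <- function(tables) {
  if (any(tables$n_events == 0L)) stop("n_events must be positive")
  (tables$cc + tables$ii) / tables$n_events
}

#' Independent-model joint retrieval
#'
#' Expected proportion of jointly correct or jointly incorrect outcomes
#' if the two trials of a table were independent given the participant's
#' marginal accuracies `p1` and `p2` on the two directed pairs:
#' `p1 * p2 + (1 - p1) * (1 - p2)`.
#'
#' @param p1,p2 Marginal accuracies in `[0, 1]` (vectorized).
#' @return Numeric vector of expected joint proportions.
#' @export
independent_model_joint <- function(p1, p2) {
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1))
    stop("marginal accuracies must lie in [0, 1]")
  p1 * p2 + (1 - p1) * (1 - p2)
}

# Core statistic from an outcome matrix; `lay` from contingency_layout().
dep_from_matrix <- function(M, lay) {
  cm <- colMeans(M)
  p_dat <- p_ind <- numeric(6)
  for (t in 1:6) {
    p_dat[t] <- mean(M[, lay$i1[t]] == M[, lay$i2[t]])
    p_ind[t] <- cm[lay$i1[t]] * cm[lay$i2[t]] +
      (1 - cm[lay$i1[t]]) * (1 - cm[lay$i2[t]])
  }
  list(p_joint_data = mean(p_dat), p_joint_indep = mean(p_ind),
       dependency = mean(p_dat) - mean(p_ind),
       p_data_tables = p_dat, p_indep_tables = p_ind,
       p1 = cm[lay$i1], p2 = cm[lay$i2], accuracy = mean(cm))
}

#' Retrieval dependency for one participant and condition
#'
#' Averages the observed proportion of joint retrieval over the six
#' contingency tables, averages the independent-model proportion (each
#' table's marginals being the participant's accuracies on its two
#' directed pairs across events), and takes the difference. Positive
#' values indicate holistic (all-or-none) retrieval; the statistic is
#' scaled for overall accuracy by construction.
#'
#' @inheritParams build_contingency_tables
#' @return An object of class `dependency_result`: `p_joint_data`,
#'   `p_joint_indep`, `dependency`, `accuracy`, and a `tables` tibble
#'   with per-table proportions and marginals.
#' @examples
#' cfg <- generator_config(n_participants = 1, model = "holistic",
#'                         a_h = 0.5, guess = 0, hetero_sd = 0, seed = 7)
#' dependency(simulate_trials(cfg))
#' @export
dependency <- function(trials, participant = NULL, condition = NULL,
                       roles = NULL) {
  trials <- single_group(trials, participant, condition)
  roles <- infer_roles(trials, roles)
  lay <- contingency_layout(roles)
  M <- outcome_matrix(trials, roles)
  d <- dep_from_matrix(M, lay)
  structure(list(
    participant_id = trials$participant_id[1],
    condition_id = trials$condition_id[1],
    n_events = nrow(M),
    p_joint_data = d$p_joint_data,
    p_joint_indep = d$p_joint_indep,
    dependency = d$dependency,
    accuracy = d$accuracy,
    tables = tibble::tibble(table_id = lay$table_id, kind = lay$kind,
                            shared_role = lay$shared_role,
                            pair_1 = lay$pair_1, pair_2 = lay$pair_2,
                            p_data = d$p_data_tables,
                            p_indep = d$p_indep_tables,
                            p1 = d$p1, p2 = d$p2)),
    class = "dependency_result")
}

#' @export
print.dependency_result <- function(x, digits = 3, ...) {
  cat("Retrieval dependency: participant ", x$participant_id,
      ", condition ", x$condition_id, " (", x$n_events, " events)\n",
      sep = "")
  cat("  joint retrieval (data):       ", round(x$p_joint_data, digits), "\n")
  cat("  joint retrieval (ind. model): ", round(x$p_joint_indep, digits), "\n")
  cat("  dependency:                   ", round(x$dependency, digits), "\n")
  cat("  accuracy:                     ", round(x$accuracy, digits), "\n")
  invisible(x)
}

#' Dependency scores for every participant and condition
#'
#' Vectorized driver for [dependency()]: computes the per-participant,
#' per-condition dependency table that feeds the group-level inference.
#'
#' @param trials A scored trial tibble.
#' @param roles Optional ordered role triple.
#' @return A tibble with one row per participant x condition:
#'   `participant_id`, `condition_id`, `n_events`, `accuracy`,
#'   `p_joint_data`, `p_joint_indep`, `dependency`.
#' @export
dependency_scores <- function(trials, roles = NULL) {
  roles <- infer_roles(trials, roles)
  if (any(trials$response == "missing"))
    stop("trials contain missing responses; run score_missing() first")
  pairs <- directed_pairs(roles)
  lay <- contingency_layout(roles)
  pidx <- match(paste(trials$cue_role, trials$target_role),
                paste(pairs$cue_role, pairs$target_role))
  if (anyNA(pidx)) stop("unknown cue/target role combination")
  correct <- trials$response == "correct"
  gkey <- paste(trials$participant_id, trials$condition_id, sep = "\r")
  groups <- split(seq_len(nrow(trials)), gkey)

  res <- lapply(groups, function(k) {
    events <- sort(unique(trials$event_id[k]))
    eidx <- match(trials$event_id[k], events)
    M <- matrix(NA, nrow = length(events), ncol = 6L)
    M[cbind(eidx, pidx[k])] <- correct[k]
    if (anyNA(M))
      stop("incomplete event(s) for participant '",
           trials$participant_id[k[1]], "', condition '",
           trials$condition_id[k[1]], "'")
    d <- dep_from_matrix(M, lay)
    c(n_events = length(events), accuracy = d$accuracy,
      p_joint_data = d$p_joint_data, p_joint_indep = d$p_joint_indep,
      dependency = d$dependency)
  })
  first <- unname(vapply(groups, `[`, integer(1), 1L))
  col <- function(nm) unname(vapply(res, `[[`, numeric(1), nm))
  out <- tibble::tibble(
    participant_id = trials$participant_id[first],
    condition_id = trials$condition_id[first],
    n_events = col("n_events"),
    accuracy = col("accuracy"),
    p_joint_data = col("p_joint_data"),
    p_joint_indep = col("p_joint_indep"),
    dependency = col("dependency"))
  out[order(out$participant_id, out$condition_id), , drop = FALSE]
}
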