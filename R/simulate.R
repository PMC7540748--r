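# Seeded synthetic trial data with the statistical structure the
# dependency analysis assumes: a latent mixture of holistic (event-level,
# all-or-none) and independent (trial-level) retrieval success, with
# forced-choice guessing, participant heterogeneity, and counterbalanced
# trial schedules.

#' Generator configuration
#'
#' Parameters of the latent retrieval model and the design layout.
#'
#' Each simulated event is encoded either holistically (with probability
#' `h` in the `"mixture"` model; always for `"holistic"`, never for
#' `"independent"`) or independently. For a holistic event a single
#' memory draw with success probability `a_h` decides all six of its
#' retrieval trials at once — the all-or-none signature of pattern
#' completion; for an independent event each trial succeeds independently
#' with probability `a_i`. Any trial whose memory draw failed still
#' succeeds by guessing with probability `guess` (0.25 for
#' four-alternative forced choice), independently across trials.
#' Participant heterogeneity shifts `a_h` and `a_i` jointly on the
#' log-odds scale by a normal draw with standard deviation `hetero_sd`.
#'
#' The latent model is a validation device for the analysis pipeline, not
#' an estimate fitted to any dataset: its parameters are design choices.
#'
#' @param n_participants Number of participants.
#' @param n_events Events per condition (15 or 30 in the designs this
#'   mirrors); must be divisible by 3 for block balance.
#' @param model `"mixture"`, `"holistic"`, or `"independent"`.
#' @param h Probability an event is encoded holistically (mixture only).
#' @param a_h Memory success probability for holistic events.
#' @param a_i Per-trial memory success probability for independent events.
#' @param guess Chance success probability after memory failure.
#' @param hetero_sd SD of the per-participant logit shift of `a_h`/`a_i`;
#'   0 disables heterogeneity.
#' @param condition_id Condition label stamped on generated trials.
#' @param roles Ordered character triple of element roles.
#' @param seed Master seed; identical `(config, seed)` reproduce the
#'   dataset exactly, and participant `i`'s data do not depend on
#'   `n_participants` (per-participant substreams).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 20, n_events = 15,
                             model = c("mixture", "holistic", "independent"),
                             h = 0.4, a_h = 0.75, a_i = 0.55, guess = 0.25,
                             hetero_sd = 0.5, condition_id = "separated",
                             roles = .default_roles, seed = 1) {
  model <- match.arg(model)
  stopifnot(n_participants >= 0, n_participants == round(n_participants),
            n_events >= 3, n_events == round(n_events),
            h >= 0, h <= 1, a_h >= 0, a_h <= 1, a_i >= 0, a_i <= 1,
            guess >= 0, guess <= 1, hetero_sd >= 0,
            length(roles) == 3L, !anyDuplicated(roles),
            length(seed) == 1L, is.finite(seed))
  if (n_events %% 3 != 0)
    stop("n_events must be divisible by 3 for balanced blocks")
  ok <- switch(model,
               mixture = a_h >= a_i && a_i >= guess,
               holistic = a_h >= guess,
               independent = a_i >= guess)
  if (!ok)
    warning("recommended ordering a_h >= a_i >= guess does not hold")
  structure(list(n_participants = as.integer(n_participants),
                 n_events = as.integer(n_events), model = model,
                 h = h, a_h = a_h, a_i = a_i, guess = guess,
                 hetero_sd = hetero_sd, condition_id = condition_id,
                 roles = roles, seed = as.integer(seed)),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Generator configuration (", x$model, " model)\n", sep = "")
  cat("  participants: ", x$n_participants, ", events: ", x$n_events,
      ", condition: ", x$condition_id, "\n", sep = "")
  cat("  h = ", x$h, ", a_h = ", x$a_h, ", a_i = ", x$a_i,
      ", guess = ", x$guess, ", hetero_sd = ", x$hetero_sd, "\n", sep = "")
  cat("  seed: ", x$seed, "\n", sep = "")
  invisible(x)
}

# Deterministic per-participant substream seed, kept below 2^31.
participant_seed <- function(seed, i) {
  (((seed %% 2147483647) * 48271) %% 2147483647 + i * 1299721) %% 2147483647
}

# Evaluate `expr` under a local RNG stream without disturbing the
# caller's .Random.seed.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Counterbalanced trial schedule
#'
#' Builds the deterministic design scaffold for one participant: three
#' encoding blocks (separated encoding, one pairwise association per
#' event per block, balanced so each block holds `n_events / 3` of each
#' of the three pair types) and two retrieval sets, each testing every
#' association once — the second set in the opposite cue -> target
#' direction — in three blocks likewise balanced across association
#' types. The block order within a retrieval set follows a reduced latin
#' square row selected by the counterbalancing index; indices 4-6 swap
#' which test direction comes first.
#'
#' @param n_events Number of events, divisible by 3.
#' @param counterbalance Counterbalancing index in 1..6.
#' @param roles Ordered role triple.
#' @return A tibble with columns `phase` (`encoding`/`retrieval`),
#'   `set` (retrieval direction set, NA for encoding), `block`,
#'   `trial_index` (within phase), `event_id`, `assoc` (unordered pair
#'   type), `cue_role`, `target_role` (encoding rows list the pair in
#'   role order).
#' @export
generate_design <- function(n_events, counterbalance = 1,
                            roles = .default_roles) {
  stopifnot(n_events >= 3, n_events == round(n_events),
            counterbalance %in% 1:6, length(roles) == 3L)
  if (n_events %% 3 != 0)
    stop("n_events must be divisible by 3 for balanced blocks")
  # deterministic in its arguments, and rebuilt for every simulated
  # participant, so cache by argument key
  key <- paste(n_events, counterbalance, paste(roles, collapse = ","))
  cached <- .design_cache[[key]]
  if (!is.null(cached)) return(cached)
  # unordered pair types over the ordered triple
  types <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  type_lab <- vapply(types, function(p) paste(roles[p], collapse = "-"),
                     character(1))
  group <- ((seq_len(n_events) - 1L) %% 3L) + 1L  # balance across events
  type_in_block <- function(b) ((group + b - 2L) %% 3L) + 1L
  latin <- list(c(1L, 2L, 3L), c(2L, 3L, 1L), c(3L, 1L, 2L))
  block_order <- latin[[((counterbalance - 1L) %% 3L) + 1L]]
  forward_first <- counterbalance <= 3L

  enc <- do.call(rbind, lapply(1:3, function(b) {
    tp <- type_in_block(b)
    data.frame(phase = "encoding", set = NA_integer_, block = b,
               event_id = seq_len(n_events), assoc = type_lab[tp],
               cue_role = roles[vapply(types[tp], `[`, integer(1), 1L)],
               target_role = roles[vapply(types[tp], `[`, integer(1), 2L)],
               stringsAsFactors = FALSE)
  }))
  enc$trial_index <- seq_len(nrow(enc))

  ret <- do.call(rbind, lapply(1:2, function(s) {
    forward <- if (forward_first) s == 1L else s == 2L
    do.call(rbind, lapply(seq_along(block_order), function(bp) {
      b <- block_order[bp]
      tp <- type_in_block(b)
      el1 <- vapply(types[tp], `[`, integer(1), 1L)
      el2 <- vapply(types[tp], `[`, integer(1), 2L)
      data.frame(phase = "retrieval", set = s, block = (s - 1L) * 3L + bp,
                 event_id = seq_len(n_events), assoc = type_lab[tp],
                 cue_role = roles[if (forward) el1 else el2],
                 target_role = roles[if (forward) el2 else el1],
                 stringsAsFactors = FALSE)
    }))
  }))
  ret$trial_index <- seq_len(nrow(ret))
  out <- tibble::as_tibble(rbind(enc, ret)[, c("phase", "set", "block",
                                               "trial_index", "event_id",
                                               "assoc", "cue_role",
                                               "target_role")])
  .design_cache[[key]] <- out
  out
}

.design_cache <- new.env(parent = emptyenv())

# Latent-model outcome matrix (n_events x 6 logical, canonical pair
# order) for one participant. Draw order is fixed so streams are stable.
draw_outcomes <- function(config, ah, ai) {
  n <- config$n_events
  hol <- switch(config$model,
                holistic = rep(1L, n),
                independent = rep(0L, n),
                mixture = stats::rbinom(n, 1L, config$h))
  m_event <- stats::rbinom(n, 1L, ah)                       # holistic draw
  m_trial <- matrix(stats::rbinom(n * 6L, 1L, ai), n, 6L)   # trial draws
  g_draw <- matrix(stats::rbinom(n * 6L, 1L, config$guess), n, 6L)
  mem <- ifelse(matrix(hol == 1L, n, 6L), matrix(m_event, n, 6L), m_trial)
  (mem | g_draw)
}

#' Simulate one participant's trials
#'
#' Draws trial outcomes from the latent holistic/independent mixture (see
#' [generator_config()]) and lays them on the counterbalanced retrieval
#' schedule from [generate_design()] (counterbalancing index cycling over
#' participants). Uses a per-participant substream of the master seed, so
#' participant `i` is reproducible regardless of how many others are
#' generated, and leaves the caller's RNG state untouched.
#'
#' @param config A [generator_config()].
#' @param i Participant index (1-based).
#' @return A trial tibble (retrieval trials only), as for [load_trials()].
#' @export
simulate_participant <- function(config, i) {
  stopifnot(inherits(config, "generator_config"), i >= 1)
  tibble::as_tibble(simulate_participant_raw(config, i))
}

# Column-list version of simulate_participant; one tibble is assembled
# per dataset rather than per participant.
simulate_participant_raw <- function(config, i) {
  with_local_seed(participant_seed(config$seed, i), {
    z <- if (config$hetero_sd > 0) stats::rnorm(1, 0, config$hetero_sd) else 0
    shift <- function(p) if (p <= 0 || p >= 1) p
      else stats::plogis(stats::qlogis(p) + z)
    M <- draw_outcomes(config, shift(config$a_h), shift(config$a_i))
    design <- generate_design(config$n_events, ((i - 1L) %% 6L) + 1L,
                              config$roles)
    ret <- design[design$phase == "retrieval", , drop = FALSE]
    pairs <- directed_pairs(config$roles)
    pidx <- match(paste(ret$cue_role, ret$target_role),
                  paste(pairs$cue_role, pairs$target_role))
    n <- nrow(ret)
    list(
      participant_id = rep(sprintf("p%03d", i), n),
      condition_id = rep(config$condition_id, n),
      event_id = ret$event_id,
      cue_role = ret$cue_role,
      target_role = ret$target_role,
      response = ifelse(M[cbind(ret$event_id, pidx)], "correct", "incorrect"),
      block = ret$block,
      trial_index = ret$trial_index)
  })
}

#' Simulate a full dataset
#'
#' @param config A [generator_config()].
#' @return A trial tibble over all `n_participants` participants;
#'   deterministic given `(config, seed)`.
#' @export
simulate_trials <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$n_participants == 0L)
    return(tibble::tibble(participant_id = character(),
                          condition_id = character(),
                          event_id = integer(), cue_role = character(),
                          target_role = character(), response = character(),
                          block = integer(), trial_index = integer()))
  parts <- lapply(seq_len(config$n_participants),
                  function(i) simulate_participant_raw(config, i))
  cols <- lapply(names(parts[[1]]), function(nm)
    unlist(lapply(parts, `[[`, nm), use.names = FALSE))
  names(cols) <- names(parts[[1]])
  tibble::as_tibble(cols)
}

#' Expected dependency under the latent model
#'
#' Closed-form expectation of the dependency statistic under a
#' homogeneous configuration (`hetero_sd = 0`), by exact enumeration of
#' the joint outcome distribution of the two trials entering each
#' contingency table. By symmetry all six tables share one joint law:
#' for a holistic event both trials succeed together with probability
#' `a_h`, otherwise each guesses; for an independent event both succeed
#' independently with probability `a_i + (1 - a_i) * guess`. The
#' independent model is evaluated at the population marginal, so the
#' value is the large-`n_events` expectation (finite-sample estimates of
#' the marginals add O(1/n_events) bias).
#'
#' @param config A [generator_config()] with `hetero_sd = 0`.
#' @return The expected dependency (a single number); exactly 0 for the
#'   independent model.
#' @examples
#' expected_dependency_oracle(generator_config(model = "holistic",
#'   a_h = 0.5, guess = 0, hetero_sd = 0))  # 0.5
#' @export
expected_dependency_oracle <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (config$hetero_sd != 0)
    stop("oracle requires a homogeneous configuration (hetero_sd = 0)")
  g <- config$guess
  h <- switch(config$model, holistic = 1, independent = 0,
              mixture = config$h)
  q_i <- config$a_i + (1 - config$a_i) * g     # marginal, independent event
  q_h <- config$a_h + (1 - config$a_h) * g     # marginal, holistic event
  joint_h <- config$a_h + (1 - config$a_h) * (g^2 + (1 - g)^2)
  joint_i <- q_i^2 + (1 - q_i)^2
  p_data <- h * joint_h + (1 - h) * joint_i
  q <- h * q_h + (1 - h) * q_i
  p_data - (q^2 + (1 - q)^2)
}

#' Simulate and analyse an experiment end to end
#'
#' Generates trials, scores missing responses, optionally applies
#' participant exclusions, computes per-participant dependency, and runs
#' the one-sample t test (with JZS Bayes factor) on the dependency
#' scores. Deterministic under a fixed `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @param study A [study_config()] to apply exclusions, or `NULL` for
#'   none.
#' @param r Cauchy prior scale for the Bayes factor.
#' @return A list with `trials`, `dependency` (per-participant tibble),
#'   `inference` (an `inference_result`, or `NULL` if fewer than two
#'   participants remain), `excluded` (exclusion report), and
#'   `n_analysed`. With `n_participants = 0`, empty components and no
#'   error.
#' @export
simulate_experiment <- function(config, study = NULL, r = sqrt(2) / 2) {
  trials <- simulate_trials(config)
  if (nrow(trials) == 0L)
    return(list(trials = trials, dependency = NULL, inference = NULL,
                excluded = NULL, n_analysed = 0L))
  trials <- score_missing(trials)
  excluded <- NULL
  if (!is.null(study)) {
    part <- apply_exclusions(trials, study)
    trials <- part$included
    excluded <- part$report
  }
  if (nrow(trials) == 0L)
    return(list(trials = trials, dependency = NULL, inference = NULL,
                excluded = excluded, n_analysed = 0L))
  dep <- dependency_scores(trials, config$roles)
  inf <- if (nrow(dep) >= 2L && stats::sd(dep$dependency) > 0)
    one_sample_t(dep$dependency, r = r) else NULL
  list(trials = trials, dependency = dep, inference = inf,
       excluded = excluded, n_analysed = nrow(dep))
}
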