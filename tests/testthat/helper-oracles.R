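# Independent oracles, deliberately naive and separate from the package
# implementation.

test_roles <- c("animal", "object", "location")

# All six directed pairs in the package's canonical order.
test_pairs <- data.frame(
  cue = rep(test_roles, each = 2L),
  target = c("object", "location", "animal", "location", "animal", "object"),
  stringsAsFactors = FALSE)

# Expand an n_events x 6 logical outcome matrix (canonical pair order)
# into a long-format trial tibble.
trials_from_matrix <- function(M, participant = "p1", condition = "c1") {
  n <- nrow(M)
  tibble::tibble(
    participant_id = participant,
    condition_id = condition,
    event_id = rep(seq_len(n), times = 6L),
    cue_role = rep(test_pairs$cue, each = n),
    target_role = rep(test_pairs$target, each = n),
    response = ifelse(as.vector(M), "correct", "incorrect"),
    block = NA_integer_, trial_index = NA_integer_)
}

# Brute-force dependency for a single participant/condition: loops over
# roles and events, tallying each contingency table cell by cell.
brute_force_dependency <- function(trials) {
  stopifnot(length(unique(trials$participant_id)) == 1L,
            length(unique(trials$condition_id)) == 1L)
  events <- sort(unique(trials$event_id))
  outcome <- function(cue, target) vapply(events, function(e) {
    r <- trials$response[trials$event_id == e & trials$cue_role == cue &
                           trials$target_role == target]
    stopifnot(length(r) == 1L)
    r == "correct"
  }, logical(1))
  tabs <- list()
  for (x in test_roles) {  # three common-cue tables
    others <- setdiff(test_roles, x)
    tabs <- c(tabs, list(list(outcome(x, others[1]), outcome(x, others[2]))))
  }
  for (x in test_roles) {  # three common-target tables
    others <- setdiff(test_roles, x)
    tabs <- c(tabs, list(list(outcome(others[1], x), outcome(others[2], x))))
  }
  p_dat <- p_ind <- numeric(0)
  for (tab in tabs) {
    a <- tab[[1]]; b <- tab[[2]]
    cc <- sum(a & b); ii <- sum(!a & !b)
    p_dat <- c(p_dat, (cc + ii) / length(events))
    p1 <- mean(a); p2 <- mean(b)
    p_ind <- c(p_ind, p1 * p2 + (1 - p1) * (1 - p2))
  }
  list(p_joint_data = mean(p_dat), p_joint_indep = mean(p_ind),
       dependency = mean(p_dat) - mean(p_ind))
}

# JZS Bayes factor via the inverse-gamma g-mixture representation of the
# Cauchy prior -- an algebraically different route from the package's
# quadrature over the standardized effect.
bf01_g_mixture <- function(t, n, r = sqrt(2) / 2, df = n - 1) {
  null_lik <- (1 + t^2 / df)^(-(df + 1) / 2)
  integrand <- function(g) {
    k <- 1 + n * g * r^2
    k^(-1 / 2) * (1 + t^2 / (k * df))^(-(df + 1) / 2) *
      g^(-3 / 2) * exp(-1 / (2 * g)) / sqrt(2 * pi)
  }
  alt <- stats::integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  null_lik / alt
}

# Random complete outcome matrix with no degenerate columns where
# possible (plain Bernoulli draws).
random_outcome_matrix <- function(n_events, p = 0.6) {
  matrix(stats::runif(n_events * 6L) < p, n_events, 6L)
}
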