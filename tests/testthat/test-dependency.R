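test_that("six tables are built, using every directed pair once per kind", {
  trials <- trials_from_matrix(matrix(TRUE, 1L, 6L))
  tabs <- build_contingency_tables(trials)
  expect_equal(nrow(tabs), 6L)
  expect_equal(sort(unique(tabs$kind)), c("common_cue", "common_target"))
  for (k in c("common_cue", "common_target")) {
    used <- c(tabs$pair_1[tabs$kind == k], tabs$pair_2[tabs$kind == k])
    expect_setequal(used, paste0(test_pairs$cue, "->", test_pairs$target))
    expect_false(anyDuplicated(used) > 0L)
  }
  # tables share exactly the cue (common_cue) or the target (common_target)
  split_pair <- function(p) strsplit(p, "->", fixed = TRUE)[[1]]
  for (i in seq_len(6L)) {
    a <- split_pair(tabs$pair_1[i]); b <- split_pair(tabs$pair_2[i])
    if (tabs$kind[i] == "common_cue") {
      expect_equal(a[1], tabs$shared_role[i])
      expect_equal(b[1], tabs$shared_role[i])
      expect_false(a[2] == b[2])
    } else {
      expect_equal(a[2], tabs$shared_role[i])
      expect_equal(b[2], tabs$shared_role[i])
      expect_false(a[1] == b[1])
    }
  }
  # all six trials correct -> everything in the correct-correct cell
  expect_true(all(tabs$cc == 1L & tabs$ci == 0L & tabs$ic == 0L &
                    tabs$ii == 0L))
})

test_that("cell counts match a hand tally on a constructed 4-event dataset", {
  # events: all correct; all incorrect; animal-cued correct only;
  # forward direction correct only
  M <- rbind(rep(TRUE, 6L),
             rep(FALSE, 6L),
             c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
             c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE))
  tabs <- build_contingency_tables(trials_from_matrix(M))
  expect_true(all(tabs$cc + tabs$ci + tabs$ic + tabs$ii == 4L))
  # common-cue animal table pairs columns 1 and 2: events 1, 3, 4 are CC
  cue_animal <- tabs[tabs$kind == "common_cue" & tabs$shared_role == "animal", ]
  expect_equal(c(cue_animal$cc, cue_animal$ci, cue_animal$ic, cue_animal$ii),
               c(3L, 0L, 0L, 1L))
  # common-target location table pairs animal->location (col 2) and
  # object->location (col 4): event 1 CC, event 4 CC, event 3 CI, event 2 II
  tgt_loc <- tabs[tabs$kind == "common_target" &
                    tabs$shared_role == "location", ]
  expect_equal(c(tgt_loc$cc, tgt_loc$ci, tgt_loc$ic, tgt_loc$ii),
               c(2L, 1L, 0L, 1L))
})

test_that("table counts always sum to the number of events", {
  set.seed(41)
  for (n_events in c(3L, 15L, 30L)) {
    tabs <- build_contingency_tables(
      trials_from_matrix(random_outcome_matrix(n_events)))
    expect_true(all(tabs$cc + tabs$ci + tabs$ic + tabs$ii == n_events))
    expect_true(all(tabs$n_events == n_events))
  }
})

test_that("joint retrieval proportions follow (cc + ii) / n", {
  tabs <- tibble::tibble(cc = c(10L, 0L, 6L), ci = c(0L, 8L, 3L),
                         ic = c(0L, 7L, 2L), ii = c(5L, 0L, 4L),
                         n_events = 15L)
  expect_equal(joint_retrieval_data(tabs), c(1, 0, 10 / 15))
  expect_error(joint_retrieval_data(tibble::tibble(cc = 0L, ci = 0L,
                                                   ic = 0L, ii = 0L,
                                                   n_events = 0L)),
               "positive")
})

test_that("independent model joint proportion is p1 p2 + (1-p1)(1-p2)", {
  expect_equal(independent_model_joint(1, 1), 1)
  expect_equal(independent_model_joint(0.5, 0.5), 0.5)
  expect_equal(independent_model_joint(0.8, 0.6), 0.56)
  expect_equal(independent_model_joint(c(0, 1), c(1, 0)), c(0, 0))
  expect_error(independent_model_joint(1.2, 0.5), "\\[0, 1\\]")
})

test_that("degenerate participants have zero dependency", {
  all_correct <- dependency(trials_from_matrix(matrix(TRUE, 15L, 6L)))
  expect_equal(all_correct$p_joint_data, 1)
  expect_equal(all_correct$p_joint_indep, 1)
  expect_equal(all_correct$dependency, 0)

  none_correct <- dependency(trials_from_matrix(matrix(FALSE, 15L, 6L)))
  expect_equal(none_correct$p_joint_data, 1)  # jointly incorrect everywhere
  expect_equal(none_correct$dependency, 0)
})

test_that("a perfectly all-or-none participant at 50% accuracy scores 0.5", {
  M <- rbind(matrix(TRUE, 8L, 6L), matrix(FALSE, 8L, 6L))
  res <- dependency(trials_from_matrix(M))
  expect_equal(res$accuracy, 0.5)
  expect_equal(res$p_joint_data, 1)
  expect_equal(res$p_joint_indep, 0.5)
  expect_equal(res$dependency, 0.5)
})

test_that("dependency equals the brute-force enumeration on constructed data", {
  set.seed(73)
  for (rep in 1:8) {
    M <- random_outcome_matrix(sample(c(4L, 7L, 10L), 1L),
                               p = stats::runif(1, 0.3, 0.8))
    trials <- trials_from_matrix(M)
    got <- dependency(trials)
    want <- brute_force_dependency(trials)
    expect_identical(got$p_joint_data, want$p_joint_data)
    expect_identical(got$p_joint_indep, want$p_joint_indep)
    expect_identical(got$dependency, want$dependency)
  }
})

test_that("dependency is invariant to event relabelling and trial order", {
  set.seed(5)
  M <- random_outcome_matrix(9L)
  trials <- trials_from_matrix(M)
  base <- dependency(trials)$dependency

  relabelled <- trials
  perm <- sample(9L)
  relabelled$event_id <- perm[relabelled$event_id]
  expect_equal(dependency(relabelled)$dependency, base)

  shuffled <- trials[sample.int(nrow(trials)), ]
  expect_equal(dependency(shuffled)$dependency, base)
})

test_that("dependency identity p_data - p_indep holds on simulated data", {
  cfg <- generator_config(n_participants = 8, seed = 21)
  dep <- dependency_scores(score_missing(simulate_trials(cfg)))
  expect_equal(dep$dependency, dep$p_joint_data - dep$p_joint_indep)
  expect_true(all(dep$p_joint_data >= 0 & dep$p_joint_data <= 1))
  expect_true(all(dep$p_joint_indep >= 0 & dep$p_joint_indep <= 1))
  expect_true(all(abs(dep$dependency) <= 1))
})

test_that("dependency_scores agrees with per-participant dependency()", {
  cfg <- generator_config(n_participants = 4, seed = 31)
  trials <- score_missing(simulate_trials(cfg))
  dep <- dependency_scores(trials)
  for (p in unique(trials$participant_id)) {
    one <- dependency(trials, participant = p)
    expect_equal(dep$dependency[dep$participant_id == p], one$dependency)
  }
})

test_that("incomplete events are rejected", {
  trials <- trials_from_matrix(matrix(TRUE, 2L, 6L))
  expect_error(dependency(trials[-1L, ]), "incomplete")
  expect_error(dependency_scores(trials[-1L, ]), "incomplete")
})

test_that("null simulation is centred on zero dependency", {
  cfg <- generator_config(n_participants = 400, model = "independent",
                          a_i = 0.55, hetero_sd = 0.5, seed = 61)
  dep <- dependency_scores(score_missing(simulate_trials(cfg)))$dependency
  se <- stats::sd(dep) / sqrt(length(dep))
  expect_lt(abs(mean(dep)), 3 * se)
})

test_that("holistic mixture simulation produces positive mean dependency", {
  cfg <- generator_config(n_participants = 100, model = "mixture", h = 0.4,
                          a_h = 0.75, a_i = 0.55, hetero_sd = 0.5, seed = 62)
  dep <- dependency_scores(score_missing(simulate_trials(cfg)))$dependency
  expect_gt(mean(dep), 0.03)
})
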