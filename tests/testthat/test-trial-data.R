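test_that("save/load round trip reproduces generated datasets exactly", {
  cfg <- generator_config(n_participants = 45, n_events = 15, seed = 11)
  trials <- simulate_trials(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  save_trials(trials, path)
  reloaded <- load_trials(path)
  expect_equal(as.data.frame(reloaded), as.data.frame(trials))
})

test_that("a minimal complete event loads as one participant dataset", {
  M <- matrix(TRUE, 1L, 6L)
  path <- withr::local_tempfile(fileext = ".csv")
  save_trials(trials_from_matrix(M), path)
  trials <- load_trials(path)
  expect_equal(nrow(trials), 6L)
  expect_equal(unique(trials$participant_id), "p1")
  expect_equal(length(unique(trials$event_id)), 1L)
})

test_that("incomplete events are rejected naming the missing pair", {
  M <- matrix(TRUE, 1L, 6L)
  trials <- trials_from_matrix(M)[-2L, ]  # drop animal->location
  path <- withr::local_tempfile(fileext = ".csv")
  save_trials(trials, path)
  expect_error(load_trials(path), "animal->location")
  expect_error(load_trials(path), "incomplete event")
})

test_that("duplicate and malformed rows are rejected with row context", {
  trials <- trials_from_matrix(matrix(TRUE, 2L, 6L))
  path <- withr::local_tempfile(fileext = ".csv")
  save_trials(rbind(trials, trials[1L, ]), path)
  expect_error(load_trials(path), "duplicate trial")

  bad <- trials
  bad$response[5L] <- "maybe"
  save_trials(bad, path)
  expect_error(load_trials(path), "row 5.*response")
})

test_that("numeric response dialects load through a response map", {
  trials <- trials_from_matrix(matrix(c(TRUE, FALSE), 1L, 6L))
  raw <- as.data.frame(trials)
  raw$response <- ifelse(raw$response == "correct", "1", "0")
  raw$response[6L] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path, row.names = FALSE, na = "")
  got <- load_trials(path, response_map = c("1" = "correct",
                                            "0" = "incorrect",
                                            "NA" = "missing"))
  expect_equal(sum(got$response == "missing"), 1L)
  expect_error(load_trials(path), "response")
})

test_that("missing scoring converts to incorrect and reports proportions", {
  trials <- trials_from_matrix(matrix(TRUE, 15L, 6L))  # 90 trials
  trials$response[1:9] <- "missing"
  scored <- score_missing(trials)
  expect_equal(nrow(scored), nrow(trials))
  expect_false(any(scored$response == "missing"))
  expect_equal(sum(scored$response == "incorrect"), 9L)
  rates <- missing_rates(scored)
  expect_equal(rates$prop_missing, 0.10)

  none <- score_missing(trials_from_matrix(matrix(TRUE, 15L, 6L)))
  expect_equal(missing_rates(none)$prop_missing, 0)

  all_miss <- trials
  all_miss$response <- "missing"
  s <- score_missing(all_miss)
  expect_true(all(s$response == "incorrect"))
  expect_equal(missing_rates(s)$prop_missing, 1.0)
})

test_that("accuracy after scoring missing is never above accuracy ignoring them", {
  trials <- trials_from_matrix(matrix(rep(c(TRUE, FALSE), 45L), 15L, 6L))
  trials$response[sample.int(90L, 20L)] <- "missing"
  scored <- score_missing(trials)
  acc_scored <- accuracy(scored, by = "overall")
  ignoring <- trials[trials$response != "missing", ]
  expect_lte(acc_scored, mean(ignoring$response == "correct"))
})

test_that("accuracy matches hand counts per scope", {
  M1 <- matrix(c(rep(TRUE, 3L), rep(FALSE, 3L)), 1L, 6L)
  t1 <- trials_from_matrix(M1, condition = "c1")
  t2 <- trials_from_matrix(matrix(TRUE, 1L, 6L), condition = "c2")
  trials <- rbind(t1, t2)
  expect_equal(accuracy(t1, by = "overall"), 0.5)
  percond <- accuracy(trials, by = "participant_condition")
  expect_equal(percond$accuracy[percond$condition_id == "c1"], 0.5)
  expect_equal(percond$accuracy[percond$condition_id == "c2"], 1.0)
  expect_equal(accuracy(trials, by = "participant")$accuracy, 0.75)
  expect_error(accuracy(trials[0L, ]), "no trials")
})

# 20 events = 120 trials per condition lets exact 95% / 30% accuracies be
# constructed (114/120 and 36/120).
make_participant <- function(id, n_correct, n_events = 20L, condition = "c1") {
  resp <- rep(FALSE, n_events * 6L)
  resp[seq_len(n_correct)] <- TRUE
  trials_from_matrix(matrix(resp, n_events, 6L), participant = id,
                     condition = condition)
}

test_that("exclusion thresholds are inclusive and interior scores are kept", {
  trials <- rbind(make_participant("at_ceiling", 114L),   # exactly 0.95
                  make_participant("at_floor", 36L),      # exactly 0.30
                  make_participant("interior_hi", 113L),  # ~0.94
                  make_participant("interior_lo", 37L))   # ~0.31
  cfg <- study_config(n_events = 20, floor_threshold = 0.30,
                      exclusion_scope = "overall")
  part <- apply_exclusions(trials, cfg)
  expect_setequal(part$report$participant_id, c("at_ceiling", "at_floor"))
  expect_equal(part$report$reason[part$report$participant_id == "at_ceiling"],
               "ceiling")
  expect_equal(part$report$reason[part$report$participant_id == "at_floor"],
               "floor")
  expect_setequal(unique(part$included$participant_id),
                  c("interior_hi", "interior_lo"))
})

test_that("exclusion is an idempotent partition of the input", {
  cfg_gen <- generator_config(n_participants = 12, a_h = 0.95, a_i = 0.9,
                              seed = 5)
  trials <- score_missing(simulate_trials(cfg_gen))
  cfg <- study_config(floor_threshold = 0.30, exclusion_scope = "overall")
  part <- apply_exclusions(trials, cfg)
  expect_equal(nrow(part$included) + nrow(part$excluded), nrow(trials))
  expect_length(intersect(unique(part$included$participant_id),
                          unique(part$excluded$participant_id)), 0L)
  again <- apply_exclusions(part$included, cfg)
  expect_equal(as.data.frame(again$included), as.data.frame(part$included))
  expect_equal(nrow(again$report), 0L)
})

test_that("average scope excludes on the mean across conditions", {
  # 0.96 and 0.94 per condition -> mean 0.95 -> excluded under "average"
  trials <- rbind(
    make_participant("p_avg", round(0.96 * 120), condition = "c1"),
    {
      t2 <- make_participant("p_avg", round(0.94 * 120), condition = "c2")
      t2
    })
  cfg_avg <- study_config(exclusion_scope = "average")
  expect_equal(apply_exclusions(trials, cfg_avg)$report$reason, "ceiling")
  # overall accuracy pooled is also 0.95 here; use unequal trial counts
  # per condition to separate the scopes
  trials2 <- rbind(
    make_participant("q", 120L, n_events = 20L, condition = "c1"),   # 1.00
    make_participant("q", round(0.88 * 60), n_events = 10L,
                     condition = "c2"))                              # 0.88
  # average = 0.94 -> kept; pooled = (120 + 53) / 180 = 0.96 -> excluded
  expect_equal(nrow(apply_exclusions(trials2, cfg_avg)$report), 0L)
  cfg_all <- study_config(exclusion_scope = "overall")
  expect_equal(apply_exclusions(trials2, cfg_all)$report$reason, "ceiling")
})
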