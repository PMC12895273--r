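# Synthetic cohort generator: reproducibility, structure, linking.

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(0), "n_participants")
  expect_error(cohort_config(5, target_r = 1), "target_r")
  expect_error(cohort_config(5, facilitation_gain = -1))
})

test_that("generation is reproducible and extensible by participant substreams", {
  c1 <- generate_cohort(cohort_config(2, seed = 7))
  c2 <- generate_cohort(cohort_config(2, seed = 7))
  expect_equal(c1, c2)

  # extending the cohort replays nothing: first participants are unchanged
  c4 <- generate_cohort(cohort_config(4, seed = 7))
  expect_equal(c1$profiles, c4$profiles[1:2, ])
  expect_equal(c1$mep_trials$amplitude,
               c4$mep_trials$amplitude[c4$mep_trials$participant_id %in%
                                         c("P001", "P002")])
})

test_that("per-participant stream sizes match the session design", {
  coh <- toy_cohort(3)
  m <- coh$mep_trials[coh$mep_trials$participant_id == "P001", ]
  expect_equal(nrow(m), 360L)  # 180 stimulations x 2 muscles
  expect_true(all(table(m$condition, m$protocol, m$muscle) == 30L))
  expect_equal(sum(coh$miqrs$participant_id == "P002"), 14L)
  cr <- coh$crft_trials[coh$crft_trials$participant_id == "P003", ]
  expect_equal(nrow(cr), 200L)  # 40 trials x 5 reaches
  expect_equal(length(unique(cr$trial)), 40L)
  expect_true(all(table(cr$condition) == 100L))
  hl <- coh$hljt_trials[coh$hljt_trials$participant_id == "P001", ]
  expect_equal(sum(hl$phase == "test"), 288L)
  expect_equal(sum(hl$phase == "practice"), 32L)
  expect_equal(sum(coh$vividness$participant_id == "P001"), 3L)

  expect_true(all(coh$mep_trials$amplitude > 0))
  expect_true(all(coh$crft_trials$reach_time > 0))
  expect_true(all(coh$hljt_trials$rt > 0))
  expect_true(all(coh$miqrs$rating %in% 1:7))
  expect_true(all(coh$vividness$rating %in% 0:10))
})

test_that("null-effect construction: zero gains centre the measures", {
  coh <- generate_cohort(cohort_config(300, seed = 42, facilitation_gain = 0,
                                       disinhibition_gain = 0))
  neuro <- derive_neuro_outcomes(coh$mep_trials)
  expect_lt(abs(mean(neuro$pct_mep_change) - 100), 2)
  expect_lt(abs(mean(neuro$delta_inh)), 1.5)
})

test_that("facilitation gain monotonically raises the population %MEP change", {
  means <- vapply(c(0, 0.2, 0.4), function(g) {
    coh <- generate_cohort(cohort_config(2000, seed = 10, facilitation_gain = g))
    mean(derive_neuro_outcomes(coh$mep_trials)$pct_mep_change)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cross-measure calibration and sign structure at large n", {
  coh <- generate_cohort(cohort_config(5000, seed = 11))
  neuro <- derive_neuro_outcomes(qc_filter(coh$mep_trials)$retained)
  hl <- coh$hljt_trials[phase == "test" & correct == TRUE,
                        .(hljt_rt = mean(rt)), by = participant_id]
  kin <- coh$miqrs[modality == "kinaesthetic", .(kin = sum(rating)),
                   by = participant_id]
  m <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
              list(neuro, hl, kin))

  # the generator's one calibrated correlation: within +-0.03 of target
  expect_lt(abs(cor(m$pct_mep_change, m$hljt_rt) - (-0.3)), 0.03)

  # emergent correlations carry the hypothesized signs
  expect_lt(cor(m$pct_mep_change, m$hljt_rt), 0)
  expect_gt(cor(m$pct_mep_change, m$kin), 0)
  expect_lt(cor(m$delta_inh, m$hljt_rt), 0)

  # |slope difference| declines with facilitation (checked on a subset:
  # per-participant Gamma fits are the expensive step)
  sub <- m$participant_id[1:400]
  ab <- derive_ability_scores(coh$miqrs[participant_id %in% sub],
                              coh$crft_trials[participant_id %in% sub],
                              coh$hljt_trials[participant_id %in% sub],
                              coh$vividness[participant_id %in% sub])
  mm <- merge(m, ab, by = "participant_id")
  expect_lt(cor(mm$pct_mep_change, mm$crft_slope_diff), 0)

  # execution-condition mean reach time is affine in ID with positive slope
  ex <- coh$crft_trials[condition == "execution",
                        .(mt = mean(reach_time)), by = id_bits]
  fitl <- lm(mt ~ id_bits, data = ex)
  expect_gt(coef(fitl)[2], 0)
  expect_gt(summary(fitl)$r.squared, 0.98)
})

test_that("generate_bivariate hits its correlation and validates inputs", {
  xy0 <- generate_bivariate(1e5, 0, seed = 1)
  expect_lt(abs(cor(xy0[, 1], xy0[, 2])), 0.01)
  xy3 <- generate_bivariate(1e5, 0.3, seed = 2)
  expect_lt(abs(cor(xy3[, 1], xy3[, 2]) - 0.3), 0.01)
  xy9 <- generate_bivariate(50, 0.999, seed = 3)
  expect_gt(cor(xy9[, 1], xy9[, 2]), 0.9)
  expect_error(generate_bivariate(3, 0.5), ">= 4")
  expect_error(generate_bivariate(100, 1), "< 1")
})

test_that("an unattainable target correlation errors out with a clear message", {
  expect_error(generate_cohort(cohort_config(5, target_r = -0.95)),
               "unattainable")
})

test_that("cohort round-trips through the delimited text tables", {
  coh <- toy_cohort(3)
  dir <- file.path(tempdir(), "coh_rt")
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "mep_trials.tsv")))
  back <- read_cohort(dir)
  for (nm in names(coh)) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(coh[[nm]]),
                 tolerance = 1e-12, label = nm)
  }
  unlink(dir, recursive = TRUE)
})
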