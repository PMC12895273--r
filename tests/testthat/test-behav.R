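# Behavioural instrument scoring.

miqrs_form <- function(kin, vis = rep(4, 7)) {
  data.frame(modality = rep(c("visual", "kinaesthetic"), each = 7),
             rating = c(vis, kin))
}

test_that("MIQ-RS scoring: bounds, midpoint, validation", {
  expect_equal(score_miqrs(miqrs_form(rep(1, 7)))$kin_score, 0)
  expect_equal(score_miqrs(miqrs_form(rep(1, 7)))$kin_sum, 7)
  expect_equal(score_miqrs(miqrs_form(rep(7, 7)))$kin_score, 100)
  expect_equal(score_miqrs(miqrs_form(rep(4, 7)))$kin_score, 50)  # sum 28
  f <- score_miqrs(miqrs_form(c(1, 2, 3, 4, 5, 6, 7)))
  expect_equal(f$total, f$kin_sum + f$vis_sum)

  expect_error(score_miqrs(miqrs_form(rep(8, 7))), "1..7")
  expect_error(score_miqrs(miqrs_form(rep(4, 7))[1:10, ]), "14 items")
  bad <- miqrs_form(rep(4, 7)); bad$modality <- rep("visual", 14)
  expect_error(score_miqrs(bad), "7 items per modality")
})

crft_data <- function(times_exec, times_imag, ids = rep(c(2.47, 3.38, 4.3, 5.35, 6.34), each = 4)) {
  rbind(data.frame(condition = "execution", id_bits = ids, reach_time = times_exec),
        data.frame(condition = "imagery", id_bits = ids, reach_time = times_imag))
}

test_that("fit_crft: exact recovery on noiseless data, identical conditions", {
  ids <- rep(c(2.47, 3.38, 4.3, 5.35, 6.34), each = 4)
  exact <- 200 + 40 * ids
  # perfect fit makes the Gamma AIC produce harmless NaN warnings
  fit <- suppressWarnings(fit_crft(crft_data(exact, exact)))
  expect_equal(unname(fit$slopes), c(40, 40), tolerance = 1e-8)
  expect_equal(fit$slope_diff, 0, tolerance = 1e-8)
  expect_equal(fit$intercept_diff, 0, tolerance = 1e-8)

  expect_error(fit_crft(crft_data(exact, exact, ids = rep(4.3, 20))),
               "degenerate")
})

test_that("fit_crft matches an independent Gamma IRLS oracle on noisy data", {
  set.seed(21)
  ids <- rep(c(2.47, 3.38, 4.3, 5.35, 6.34), each = 20)
  mk <- function(slope) (250 + slope * ids) * rgamma(length(ids), 25, 25)  # CV 0.2
  d <- crft_data(mk(44), mk(38), ids = ids)
  fit <- fit_crft(d)
  for (cc in c("execution", "imagery")) {
    dd <- d[d$condition == cc, ]
    ob <- unname(oracle_gamma_irls(dd$id_bits, dd$reach_time))
    expect_equal(unname(fit$intercepts[cc]), ob[1], tolerance = 1e-6)
    expect_equal(unname(fit$slopes[cc]), ob[2], tolerance = 1e-6)
  }
  # truth recovered within ~3 SE at this design (slope SE about 6.5 ms/bit)
  expect_lt(abs(fit$slopes["execution"] - 44), 20)
  expect_lt(abs(fit$slopes["imagery"] - 38), 20)

  # log link also runs and back-transforms to a slope in ms
  fit_log <- fit_crft(d, link = "log")
  expect_lt(abs(fit_log$slopes["execution"] - 44), 20)
})

test_that("slope difference vanishes as noise vanishes on equal-slope data", {
  ids <- rep(c(2.47, 3.38, 4.3, 5.35, 6.34), each = 8)
  set.seed(5)
  diffs <- vapply(c(0.2, 0.05, 0.005), function(cv) {
    sh <- 1 / cv^2
    d <- crft_data((250 + 40 * ids) * rgamma(length(ids), sh, sh),
                   (250 + 40 * ids) * rgamma(length(ids), sh, sh),
                   ids = ids)
    fit_crft(d)$slope_diff
  }, numeric(1))
  expect_lt(diffs[3], diffs[1])
  expect_lt(diffs[3], 1)
})

hljt_data <- function(rt, correct = TRUE, direction = "medial", phase = "test") {
  data.frame(rt = rt, correct = correct, direction = direction, phase = phase)
}

test_that("score_hljt: constant input, direct difference, correct-trial filter", {
  s <- score_hljt(hljt_data(rep(600, 40),
                            direction = rep(c("medial", "lateral"), 20)))
  expect_equal(s$hljt_rt, 600)
  expect_equal(s$bce, 0)
  expect_equal(s$accuracy, 100)

  d <- rbind(hljt_data(rep(500, 10), direction = "medial"),
             hljt_data(rep(700, 10), direction = "lateral"))
  expect_equal(score_hljt(d)$bce, 200)

  # mixed 20-trial toy with 4 errors: mean over the 16 correct trials only
  set.seed(12)
  rt <- round(runif(20, 400, 1200))
  ok <- rep(TRUE, 20); ok[c(3, 8, 13, 19)] <- FALSE
  d2 <- hljt_data(rt, correct = ok,
                  direction = rep(c("medial", "lateral"), 10))
  s2 <- score_hljt(d2)
  expect_equal(s2$hljt_rt, mean(rt[ok]))
  expect_equal(s2$accuracy, 80)
  expect_equal(s2$bce,
               mean(rt[ok & rep(c(FALSE, TRUE), 10)]) -
                 mean(rt[ok & rep(c(TRUE, FALSE), 10)]))

  # injecting incorrect trials with extreme RTs leaves hljt_rt unchanged
  d3 <- rbind(d2, hljt_data(rep(99999, 5), correct = FALSE))
  expect_equal(score_hljt(d3)$hljt_rt, s2$hljt_rt)

  # practice trials are excluded when a phase column is present
  d4 <- rbind(d2, hljt_data(rep(99999, 5), phase = "practice"))
  expect_equal(score_hljt(d4)$hljt_rt, s2$hljt_rt)

  # zero correct trials: undefined-measure flag, not an error
  s0 <- score_hljt(hljt_data(rep(500, 10), correct = FALSE))
  expect_true(is.na(s0$hljt_rt))
  expect_equal(s0$n_correct, 0L)
})

test_that("vividness summary and validation", {
  expect_equal(summarize_vividness(c(5, 5, 5)), 5)
  expect_equal(summarize_vividness(c(0, 10, 5)), 5)
  expect_equal(summarize_vividness(c(10, 5, 0)), 5)
  expect_error(summarize_vividness(c(5, 11)), "0, 10")
})

test_that("derive_ability_scores assembles one coherent row per participant", {
  coh <- toy_cohort(6)
  ab <- derive_ability_scores(coh$miqrs, coh$crft_trials, coh$hljt_trials,
                              coh$vividness)
  expect_equal(nrow(ab), 6L)
  expect_true(all(ab$kin_score >= 0 & ab$kin_score <= 100))
  expect_true(all(ab$crft_slope_diff >= 0))
  expect_true(all(ab$hljt_rt > 0))
  # spot-check one participant against the scalar scorers
  id <- ab$participant_id[3]
  mi <- score_miqrs(as.data.frame(coh$miqrs[coh$miqrs$participant_id == id, ]))
  expect_equal(ab$kin_score[3], mi$kin_score)
})
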