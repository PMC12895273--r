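# Scoring of the behavioural imagery-ability instruments: MIQ-RS
# questionnaire, chronometric radial Fitts task, hand-laterality judgement
# task, and the per-block vividness ratings.

#' Score a 14-item MIQ-RS form
#'
#' Subscale sum-scores (7 items each, range 7-49), the total (14-98), and
#' the normalized kinaesthetic score
#' `100 * (kin_sum - 7) / 42` used as the imagery-generation measure.
#'
#' @param form data.frame with columns `modality` ("visual"/"kinaesthetic")
#'   and `rating` (integers 1-7), 14 rows with exactly 7 per modality.
#' @return list with `kin_sum`, `vis_sum`, `total`, `kin_score`.
#' @export
#' @examples
#' f <- data.frame(modality = rep(c("visual", "kinaesthetic"), each = 7),
#'                 rating = rep(4, 14))
#' score_miqrs(f)$kin_score  # 50
score_miqrs <- function(form) {
  stopifnot(all(c("modality", "rating") %in% names(form)))
  if (nrow(form) != 14L) stop("MIQ-RS form must have 14 items")
  if (any(form$rating < 1 | form$rating > 7 | form$rating != round(form$rating)))
    stop("ratings must be integers in 1..7")
  kin <- form$rating[form$modality == "kinaesthetic"]
  vis <- form$rating[form$modality == "visual"]
  if (length(kin) != 7L || length(vis) != 7L)
    stop("form must contain exactly 7 items per modality")
  kin_sum <- sum(kin)
  vis_sum <- sum(vis)
  list(kin_sum = kin_sum, vis_sum = vis_sum, total = kin_sum + vis_sum,
       kin_score = 100 * (kin_sum - 7) / 42)
}

# Gamma GLM of reach time on index of difficulty for one condition.
# identity link keeps the slope natively in ms/bit; for the log link the
# slope is back-transformed as the average marginal effect dmu/dID.
fit_crft_condition <- function(d, link) {
  start <- coef(lm(reach_time ~ id_bits, data = d))
  if (link == "identity") {
    fit <- glm(reach_time ~ id_bits, data = d,
               family = Gamma(link = "identity"), start = start)
    b <- coef(fit)
    c(intercept = unname(b[1]), slope = unname(b[2]))
  } else {
    fit <- glm(reach_time ~ id_bits, data = d, family = Gamma(link = "log"))
    b <- coef(fit)
    mu <- exp(b[1] + b[2] * d$id_bits)
    c(intercept = unname(exp(b[1])), slope = unname(mean(b[2] * mu)))
  }
}

#' Fit per-condition Fitts slopes for one participant
#'
#' Gamma regressions of reach time on index of difficulty, fitted per
#' condition, accounting for the right skew of movement times. The
#' imagery-ability measures are the absolute execution-minus-imagery slope
#' and intercept differences (ms), values near 0 indicating well-preserved
#' temporal structure during imagery.
#'
#' @param trials data.frame with columns `condition`
#'   ("execution"/"imagery"), `id_bits`, `reach_time` (ms, > 0) for a single
#'   participant.
#' @param link `"identity"` (default; slopes natively in ms/bit) or `"log"`
#'   (slope back-transformed as an average marginal effect).
#' @return list with `slopes` and `intercepts` (named per condition, ms),
#'   `slope_diff`, `intercept_diff` (absolute values), and `link`.
#' @export
fit_crft <- function(trials, link = c("identity", "log")) {
  link <- match.arg(link)
  stopifnot(all(c("condition", "id_bits", "reach_time") %in% names(trials)))
  if (any(trials$reach_time <= 0)) stop("reach times must be > 0")
  conds <- c("execution", "imagery")
  if (!all(conds %in% trials$condition))
    stop("need trials in both execution and imagery conditions")
  fits <- lapply(conds, function(cc) {
    d <- trials[trials$condition == cc, , drop = FALSE]
    if (length(unique(d$id_bits)) < 2L)
      stop("degenerate design: fewer than 2 distinct IDs in ", cc)
    fit_crft_condition(d, link)
  })
  names(fits) <- conds
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  intercepts <- vapply(fits, `[[`, numeric(1), "intercept")
  list(slopes = slopes, intercepts = intercepts,
       slope_diff = abs(slopes["execution"] - slopes["imagery"]) |> unname(),
       intercept_diff = abs(intercepts["execution"] - intercepts["imagery"]) |> unname(),
       link = link)
}

#' Score the hand-laterality judgement task for one participant
#'
#' The confirmatory measure is the mean reaction time over correct test
#' trials across all angles, views and directions; accuracy is reported
#' descriptively. The biomechanical-constraints effect (`bce`) is the mean
#' correct-trial RT for lateral minus medial rotations (neutral angles 0 and
#' 180 degrees excluded), expected positive.
#'
#' @param trials data.frame with columns `rt` (ms), `correct` (logical),
#'   `direction`; practice trials are dropped automatically when a `phase`
#'   column is present, otherwise all rows are treated as test trials.
#' @param rt_bounds optional length-2 numeric; when given, correct trials
#'   with RT outside the bounds are excluded (off by default).
#' @return list with `hljt_rt` (ms), `accuracy` (%), `bce` (ms) and
#'   `n_correct`. With zero correct trials the RT measures are NA and
#'   `n_correct` is 0 (undefined-measure flag rather than an error).
#' @export
score_hljt <- function(trials, rt_bounds = NULL) {
  stopifnot(all(c("rt", "correct", "direction") %in% names(trials)))
  if ("phase" %in% names(trials))
    trials <- trials[trials$phase == "test", , drop = FALSE]
  if (any(trials$rt <= 0)) stop("reaction times must be > 0")
  acc <- 100 * mean(trials$correct)
  ok <- trials$correct
  if (!is.null(rt_bounds))
    ok <- ok & trials$rt >= rt_bounds[1] & trials$rt <= rt_bounds[2]
  cc <- trials[ok, , drop = FALSE]
  if (nrow(cc) == 0L)
    return(list(hljt_rt = NA_real_, accuracy = acc, bce = NA_real_,
                n_correct = 0L))
  bce <- mean(cc$rt[cc$direction == "lateral"]) -
    mean(cc$rt[cc$direction == "medial"])
  list(hljt_rt = mean(cc$rt), accuracy = acc, bce = bce,
       n_correct = nrow(cc))
}

#' Mean of the per-block vividness ratings
#'
#' @param ratings numeric vector of 0-10 kinaesthetic-vividness ratings
#'   (one per TMS block).
#' @return arithmetic mean.
#' @export
summarize_vividness <- function(ratings) {
  if (any(ratings < 0 | ratings > 10)) stop("ratings must lie in [0, 10]")
  mean(ratings)
}

#' Derive all behavioural ability scores for a cohort
#'
#' Applies [score_miqrs], [fit_crft], [score_hljt] and
#' [summarize_vividness] per participant.
#'
#' @param miqrs,crft_trials,hljt_trials,vividness cohort data streams as
#'   produced by [generate_cohort] (or read from their tsv tables).
#' @param link passed to [fit_crft].
#' @return data.table, one row per participant, with columns `kin_sum`,
#'   `kin_score`, `vis_sum`, `crft_slope_execution`, `crft_slope_imagery`,
#'   `crft_slope_diff`, `crft_intercept_diff`, `hljt_rt`, `hljt_accuracy`,
#'   `bce`, `vividness_mean`.
#' @export
derive_ability_scores <- function(miqrs, crft_trials, hljt_trials, vividness,
                                  link = "identity") {
  ids <- sort(unique(as.character(miqrs$participant_id)))
  rows <- lapply(ids, function(id) {
    mi <- score_miqrs(as.data.frame(miqrs[miqrs$participant_id == id, ]))
    cf <- fit_crft(as.data.frame(crft_trials[crft_trials$participant_id == id, ]),
                   link = link)
    hl <- score_hljt(as.data.frame(hljt_trials[hljt_trials$participant_id == id, ]))
    vv <- summarize_vividness(vividness$rating[vividness$participant_id == id])
    data.table::data.table(
      participant_id = id,
      kin_sum = mi$kin_sum, kin_score = mi$kin_score, vis_sum = mi$vis_sum,
      crft_slope_execution = unname(cf$slopes["execution"]),
      crft_slope_imagery = unname(cf$slopes["imagery"]),
      crft_slope_diff = cf$slope_diff,
      crft_intercept_diff = cf$intercept_diff,
      hljt_rt = hl$hljt_rt, hljt_accuracy = hl$accuracy, bce = hl$bce,
      vividness_mean = vv
    )
  })
  out <- data.table::rbindlist(rows)
  data.table::setkey(out, participant_id)
  out[]
}
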