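# Synthetic cohort generator: every data stream of the study, linked
# through a latent imagery-ability factor.

#' Configuration for the synthetic cohort generator
#'
#' Collects every tunable of the generator with defaults chosen to emulate
#' the study's stated world: 30 MEP trials per condition x protocol cell
#' recorded from two muscles, 14 MIQ-RS items, 40 Fitts-task trials of 5
#' reaches, 288 hand-laterality test trials (plus 32 practice), 3 vividness
#' ratings, and a cross-measure correlation between the percentage MEP
#' change and the hand-laterality reaction time calibrated to `target_r`
#' (default -0.3, the planning hypothesis).
#'
#' @param n_participants cohort size (>= 1).
#' @param target_r signed population correlation between the combined %MEP
#'   change and mean HLJT reaction time, in (-1, 1). The measure-specific
#'   noise variances are solved so the generated correlation matches it.
#' @param facilitation_gain how strongly latent ability scales the
#'   muscle-specific log MEP facilitation (0 switches the effect off and
#'   centres %MEP change at 100).
#' @param disinhibition_gain how strongly ability raises the conditioned/
#'   unconditioned ratio in the active condition (0 centres the inhibition
#'   difference at 0).
#' @param facilitation_shift,disinhibition_shift population-mean offsets of
#'   the two effects in ability units (so the mean effect also vanishes when
#'   the corresponding gain is 0).
#' @param nonactive_facilitation multiplicative, non-muscle-specific MEP
#'   facilitation applied to both imagery conditions relative to rest.
#' @param mep_cv trial-to-trial lognormal coefficient of variation of MEP
#'   amplitudes.
#' @param mep_baseline_median,mep_baseline_sdlog participant-level resting
#'   single-pulse MEP amplitude distribution (micro-volts, lognormal).
#' @param adm_scale amplitude scale of the ADM muscle relative to FDI.
#' @param sici_mean_logit,sici_sdlog participant-level baseline conditioned/
#'   unconditioned ratio, logit-normal.
#' @param hljt_rt_median median hand-laterality reaction time (ms).
#' @param hljt_rt_gain log-scale effect of one ability SD on reaction time.
#' @param hljt_trial_cv trial-level lognormal CV of reaction times.
#' @param hljt_angle_slope proportional RT increase per degree of rotation
#'   from upright.
#' @param hljt_lateral_mult RT multiplier for lateral vs medial rotations
#'   (the biomechanical-constraints effect).
#' @param hljt_acc_logit,hljt_acc_gain,hljt_acc_angle accuracy model:
#'   logit(P(correct)) = `hljt_acc_logit + hljt_acc_gain * ability -
#'   hljt_acc_angle * rotation`, keeping accuracy near its ~90% ceiling.
#' @param miqrs_centre,miqrs_kin_loading,miqrs_vis_loading,miqrs_item_sd
#'   ordinal questionnaire model: item rating = round(centre + loading *
#'   ability + noise) clamped to 1..7.
#' @param crft_exec_slope,crft_exec_slope_sd population mean and SD of the
#'   execution-condition Fitts slope (ms/bit), calibrated to the pilot
#'   estimate 43.9 ms.
#' @param crft_imag_offset mean imagery-minus-execution slope difference
#'   (ms/bit); pilot group slopes 43.9 vs 38 give -5.9.
#' @param crft_imag_dev_sd,crft_imag_dev_gain SD of the individual
#'   imagery-slope deviation and its exponential shrinkage per ability SD
#'   (higher ability, smaller |slope difference|).
#' @param crft_intercept,crft_intercept_sd per-reach time at ID = 0 (ms).
#' @param crft_intercept_dev_sd SD of the imagery-intercept deviation (ms),
#'   shrunk with ability like the slope deviation.
#' @param crft_trial_cv multiplicative Gamma noise CV of reach times.
#' @param vividness_centre,vividness_gain,vividness_sd 0-10 block-rating
#'   model.
#' @param coil_dev_sd,rms_meanlog,rms_sdlog quality-control covariates:
#'   half-normal coil deviations (mm / degrees) and lognormal pre-stimulus
#'   RMS (micro-volts).
#' @param n_mep_per_cell MEP trials per condition x protocol cell.
#' @param seed root seed; per-participant substreams are derived from it so
#'   a cohort can be extended without replaying earlier participants.
#' @return object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_participants,
                          target_r = -0.3,
                          facilitation_gain = 0.2,
                          disinhibition_gain = 0.3,
                          facilitation_shift = 1.0,
                          disinhibition_shift = 0.2,
                          nonactive_facilitation = 1.05,
                          mep_cv = 0.4,
                          mep_baseline_median = 500,
                          mep_baseline_sdlog = 0.5,
                          adm_scale = 0.8,
                          sici_mean_logit = 0,
                          sici_sdlog = 0.4,
                          hljt_rt_median = 900,
                          hljt_rt_gain = 0.12,
                          hljt_trial_cv = 0.25,
                          hljt_angle_slope = 0.0008,
                          hljt_lateral_mult = 1.05,
                          hljt_acc_logit = qlogis(0.93),
                          hljt_acc_gain = 0.4,
                          hljt_acc_angle = 0.006,
                          miqrs_centre = 4.5,
                          miqrs_kin_loading = 1.2,
                          miqrs_vis_loading = 0.6,
                          miqrs_item_sd = 1.0,
                          crft_exec_slope = 43.9,
                          crft_exec_slope_sd = 12,
                          crft_imag_offset = -5.9,
                          crft_imag_dev_sd = 15,
                          crft_imag_dev_gain = 0.5,
                          crft_intercept = 300,
                          crft_intercept_sd = 50,
                          crft_intercept_dev_sd = 40,
                          crft_trial_cv = 0.2,
                          vividness_centre = 5.5,
                          vividness_gain = 1.5,
                          vividness_sd = 1.0,
                          coil_dev_sd = 1.2,
                          rms_meanlog = log(3),
                          rms_sdlog = 0.5,
                          n_mep_per_cell = 30L,
                          seed = 1L) {
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (abs(target_r) >= 1) stop("target_r must lie in (-1, 1)")
  stopifnot(facilitation_gain >= 0, disinhibition_gain >= 0,
            mep_cv > 0, hljt_trial_cv > 0, crft_trial_cv > 0,
            n_mep_per_cell >= 1)
  cfg <- as.list(environment())
  cfg$n_participants <- as.integer(n_participants)
  cfg$n_mep_per_cell <- as.integer(n_mep_per_cell)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

# ---------------------------------------------------------------------------
# Noise calibration.
#
# On the log scale the two linked measures are approximately
#   log X (%MEP, combined) = const + g_f * A + e_f + sampling noise (v0x)
#   log Y (HLJT mean RT)   = const - s * g_rt * A + e_rt + sampling (v0y)
# with A ~ N(0,1), s = sign(-target_r). Writing R for the common
# reliability (signal variance over total variance) of both measures, the
# log-scale correlation is -s * R and the raw-scale (lognormal) correlation
# follows the bivariate-lognormal identity. solve_linking() finds R so the
# raw-scale correlation equals target_r, then returns the participant-level
# noise SDs (e_f, e_rt) that realize it after subtracting the analytic
# trial-sampling variances.
# ---------------------------------------------------------------------------
solve_linking <- function(cfg) {
  # trial-sampling log-variance of the combined %MEP measure: each muscle's
  # ratio of two 30-trial means has log-var ~ 2 cv^2 / k; averaging the two
  # muscles (independent sampling noise, shared signal) halves it
  v0x <- cfg$mep_cv^2 / cfg$n_mep_per_cell
  # sampling log-variance of the mean over ~0.9 * 288 correct RT trials
  v0y <- cfg$hljt_trial_cv^2 / (288 * 0.9)

  g_f <- cfg$facilitation_gain
  g_rt <- cfg$hljt_rt_gain
  fallback <- list(s_f = if (g_f > 0) 0.25 else 0, s_rt = 0.15,
                   calibrated = FALSE)
  if (cfg$target_r == 0 || g_f == 0 || g_rt == 0) return(fallback)

  tgt <- abs(cfg$target_r)
  raw_corr <- function(R) {
    sx2 <- g_f^2 / R
    sy2 <- g_rt^2 / R
    (exp(g_f * g_rt) - 1) / sqrt(expm1(sx2) * expm1(sy2))
  }
  R_max <- min(g_f^2 / (g_f^2 + v0x), g_rt^2 / (g_rt^2 + v0y), 0.999)
  if (raw_corr(R_max) < tgt)
    stop(sprintf(
      "target_r = %.3g unattainable: max |correlation| %.3f with current gains",
      cfg$target_r, raw_corr(R_max)))
  R <- uniroot(function(R) raw_corr(R) - tgt,
               lower = 1e-6, upper = R_max, tol = 1e-10)$root
  list(s_f = sqrt(max(g_f^2 * (1 - R) / R - v0x, 0)),
       s_rt = sqrt(max(g_rt^2 * (1 - R) / R - v0y, 0)),
       calibrated = TRUE, reliability = R)
}

# deterministic per-participant substream seed below 2^31
substream_seed <- function(root, i) {
  as.integer((as.numeric(root %% 65011) * 30011 + as.numeric(i) * 7919 +
                104729) %% 2147483629) + 1L
}

# mean-preserving lognormal multiplicative noise with coefficient of
# variation cv
rlnorm_cv <- function(n, cv) {
  s2 <- log(1 + cv^2)
  exp(rnorm(n, -s2 / 2, sqrt(s2)))
}

# mean-one multiplicative Gamma noise with coefficient of variation cv
rgamma_cv <- function(n, cv) {
  sh <- 1 / cv^2
  rgamma(n, shape = sh, rate = sh)
}

clamp_int <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Generate a complete synthetic study cohort
#'
#' Draws one latent imagery-ability value per participant and emits all five
#' data streams of the study with the dependency structure the analysis
#' assumes: muscle-specific MEP facilitation and active-condition
#' disinhibition increase with ability; hand-laterality reaction time
#' decreases with ability; kinaesthetic questionnaire scores and vividness
#' ratings increase with ability; and the imagery-vs-execution Fitts slope
#' difference shrinks with ability. Participant-level noise variances are
#' solved so the population correlation between the combined %MEP change and
#' mean HLJT reaction time equals `target_r`; the remaining pairwise
#' correlations are emergent.
#'
#' Trial rows appear in a fixed systematic order; use [build_tms_schedule]
#' and [build_hljt_schedule] for realistic session orderings.
#'
#' @param config a [cohort_config] object.
#' @return object of class `imcor_cohort`: list of data.tables `profiles`,
#'   `mep_trials` (360 rows per participant: 180 stimulations x 2 muscles),
#'   `miqrs` (14 items), `crft_trials` (40 trials x 5 reaches), `hljt_trials`
#'   (32 practice + 288 test), `vividness` (3 block ratings), plus the
#'   config and the solved linking in attributes.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(5, seed = 7))
#' names(coh)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  link <- solve_linking(cfg)
  n <- cfg$n_participants

  # fixed per-participant trial templates -----------------------------------
  mep_cells <- expand.grid(rep = seq_len(cfg$n_mep_per_cell),
                           protocol = TMS_PROTOCOLS,
                           condition = TMS_CONDITIONS,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_stim <- nrow(mep_cells)                       # 180 stimulation events
  mep_long <- mep_cells[rep(seq_len(n_stim), each = 2L), ]
  mep_long$muscle <- rep(c("FDI", "ADM"), times = n_stim)

  crft_tpl <- expand.grid(reach = 1:5,
                          id_bits = CRFT_IDS,
                          rep = seq_len(4L),
                          condition = c("execution", "imagery"),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  crft_tpl$trial <- rep(seq_len(nrow(crft_tpl) / 5L), each = 5L)

  stim <- hljt_stimuli()
  hljt_tpl <- rbind(
    cbind(phase = "practice", block = 0L, stim),
    do.call(rbind, lapply(1:3, function(b) cbind(phase = "test", block = b,
                                                 stim[rep(1:32, 3L), ])))
  )
  hljt_tpl$angle_dev <- pmin(hljt_tpl$angle, 360L - hljt_tpl$angle)

  one <- function(i) {
    set.seed(substream_seed(cfg$seed, i))
    A <- rnorm(1)
    e_f <- rnorm(1, 0, link$s_f)
    baseline_mep <- cfg$mep_baseline_median * exp(rnorm(1, 0, cfg$mep_baseline_sdlog))
    baseline_rt <- cfg$hljt_rt_median * exp(rnorm(1, 0, link$s_rt))
    sici_base <- plogis(rnorm(1, cfg$sici_mean_logit, cfg$sici_sdlog))

    rt_sign <- if (cfg$target_r > 0) 1 else -1
    fac <- exp(cfg$facilitation_gain * (A + cfg$facilitation_shift) + e_f)
    sici_active <- plogis(qlogis(sici_base) +
                            cfg$disinhibition_gain * (A + cfg$disinhibition_shift))

    # MEP trials ------------------------------------------------------------
    musc_scale <- c(FDI = 1, ADM = cfg$adm_scale)[mep_long$muscle]
    active <- (mep_long$condition == "imagery_FDI" & mep_long$muscle == "FDI") |
      (mep_long$condition == "imagery_ADM" & mep_long$muscle == "ADM")
    imagery <- mep_long$condition != "rest"
    mu <- baseline_mep * musc_scale *
      ifelse(imagery, cfg$nonactive_facilitation, 1) *
      ifelse(active, fac, 1)
    ratio <- ifelse(active, sici_active, sici_base)
    mu <- mu * ifelse(mep_long$protocol == "paired", ratio, 1)
    amplitude <- mu * rlnorm_cv(length(mu), cfg$mep_cv)

    coil <- matrix(abs(rnorm(3L * n_stim, 0, cfg$coil_dev_sd)), ncol = 3L)
    rms <- rlnorm(n_stim, cfg$rms_meanlog, cfg$rms_sdlog)
    pulse <- rtrunc_gauss(n_stim)

    # MIQ-RS ----------------------------------------------------------------
    modality <- rep(c("visual", "kinaesthetic"), times = 7L)
    loading <- ifelse(modality == "kinaesthetic",
                      cfg$miqrs_kin_loading, cfg$miqrs_vis_loading)
    rating <- clamp_int(cfg$miqrs_centre + loading * A +
                          rnorm(14L, 0, cfg$miqrs_item_sd), 1L, 7L)

    # CRFT ------------------------------------------------------------------
    slope_exec <- max(5, cfg$crft_exec_slope + rnorm(1, 0, cfg$crft_exec_slope_sd))
    dev_scale <- exp(-cfg$crft_imag_dev_gain * A)
    slope_imag <- max(5, slope_exec + cfg$crft_imag_offset +
                        rnorm(1, 0, cfg$crft_imag_dev_sd * dev_scale))
    int_exec <- max(100, cfg$crft_intercept + rnorm(1, 0, cfg$crft_intercept_sd))
    int_imag <- max(100, int_exec + rnorm(1, 0, cfg$crft_intercept_dev_sd * dev_scale))
    slope_i <- ifelse(crft_tpl$condition == "execution", slope_exec, slope_imag)
    int_i <- ifelse(crft_tpl$condition == "execution", int_exec, int_imag)
    reach_time <- (int_i + slope_i * crft_tpl$id_bits) *
      rgamma_cv(nrow(crft_tpl), cfg$crft_trial_cv)

    # HLJT ------------------------------------------------------------------
    mu_rt <- baseline_rt * exp(rt_sign * cfg$hljt_rt_gain * A) *
      (1 + cfg$hljt_angle_slope * hljt_tpl$angle_dev) *
      ifelse(hljt_tpl$direction == "lateral", cfg$hljt_lateral_mult, 1)
    rt <- mu_rt * rlnorm_cv(nrow(hljt_tpl), cfg$hljt_trial_cv)
    p_corr <- plogis(cfg$hljt_acc_logit + cfg$hljt_acc_gain * A -
                       cfg$hljt_acc_angle * hljt_tpl$angle_dev)
    correct <- rbinom(nrow(hljt_tpl), 1L, p_corr) == 1L

    # vividness -------------------------------------------------------------
    vivid <- clamp_int(cfg$vividness_centre + cfg$vividness_gain * A +
                         rnorm(3L, 0, cfg$vividness_sd), 0L, 10L)

    list(A = A, baseline_mep = baseline_mep, baseline_rt = baseline_rt,
         sici_base = sici_base, slope_exec = slope_exec, slope_imag = slope_imag,
         amplitude = amplitude, coil = coil, rms = rms, pulse = pulse,
         rating = rating, reach_time = reach_time, rt = rt, correct = correct,
         vivid = vivid)
  }

  parts <- lapply(seq_len(n), one)
  ids <- sprintf("P%03d", seq_len(n))

  profiles <- data.table::data.table(
    participant_id = ids,
    ability = vapply(parts, `[[`, numeric(1), "A"),
    baseline_mep = vapply(parts, `[[`, numeric(1), "baseline_mep"),
    baseline_rt = vapply(parts, `[[`, numeric(1), "baseline_rt"),
    crft_exec_slope = vapply(parts, `[[`, numeric(1), "slope_exec"),
    crft_imag_slope = vapply(parts, `[[`, numeric(1), "slope_imag"),
    sici_base = vapply(parts, `[[`, numeric(1), "sici_base")
  )

  n_stim_rows <- 2L * n_stim
  mep_trials <- data.table::data.table(
    participant_id = rep(ids, each = n_stim_rows),
    trial = rep(rep(seq_len(n_stim), each = 2L), times = n),
    condition = rep(mep_long$condition, times = n),
    protocol = rep(mep_long$protocol, times = n),
    muscle = rep(mep_long$muscle, times = n),
    amplitude = unlist(lapply(parts, `[[`, "amplitude"), use.names = FALSE),
    pre_stim_rms = unlist(lapply(parts, function(p) rep(p$rms, each = 2L)),
                          use.names = FALSE),
    coil_distance = unlist(lapply(parts, function(p) rep(p$coil[, 1L], each = 2L)),
                           use.names = FALSE),
    coil_tilt = unlist(lapply(parts, function(p) rep(p$coil[, 2L], each = 2L)),
                       use.names = FALSE),
    coil_rotation = unlist(lapply(parts, function(p) rep(p$coil[, 3L], each = 2L)),
                           use.names = FALSE),
    pulse_time = unlist(lapply(parts, function(p) rep(p$pulse, each = 2L)),
                        use.names = FALSE)
  )

  miqrs <- data.table::data.table(
    participant_id = rep(ids, each = 14L),
    item = rep(1:14, times = n),
    modality = rep(rep(c("visual", "kinaesthetic"), times = 7L), times = n),
    rating = unlist(lapply(parts, `[[`, "rating"), use.names = FALSE)
  )

  crft_trials <- data.table::data.table(
    participant_id = rep(ids, each = nrow(crft_tpl)),
    condition = rep(crft_tpl$condition, times = n),
    trial = rep(crft_tpl$trial, times = n),
    id_bits = rep(crft_tpl$id_bits, times = n),
    reach = rep(crft_tpl$reach, times = n),
    reach_time = unlist(lapply(parts, `[[`, "reach_time"), use.names = FALSE)
  )

  hljt_trials <- data.table::data.table(
    participant_id = rep(ids, each = nrow(hljt_tpl)),
    phase = rep(hljt_tpl$phase, times = n),
    block = rep(hljt_tpl$block, times = n),
    hand = rep(hljt_tpl$hand, times = n),
    view = rep(hljt_tpl$view, times = n),
    angle = rep(hljt_tpl$angle, times = n),
    direction = rep(hljt_tpl$direction, times = n),
    rt = unlist(lapply(parts, `[[`, "rt"), use.names = FALSE),
    correct = unlist(lapply(parts, `[[`, "correct"), use.names = FALSE)
  )

  vividness <- data.table::data.table(
    participant_id = rep(ids, each = 3L),
    block = rep(1:3, times = n),
    rating = unlist(lapply(parts, `[[`, "vivid"), use.names = FALSE)
  )

  structure(
    list(profiles = profiles, mep_trials = mep_trials, miqrs = miqrs,
         crft_trials = crft_trials, hljt_trials = hljt_trials,
         vividness = vividness),
    class = "imcor_cohort", config = cfg, linking = link
  )
}

#' Draw paired samples from a bivariate normal with a given correlation
#'
#' The sampling model of the planning power analysis: standardized pairs
#' with population correlation `rho`.
#'
#' @param n number of pairs (>= 4).
#' @param rho population correlation, |rho| < 1.
#' @param seed optional integer seed (omit to use the current RNG state).
#' @return an `n` x 2 matrix with columns `x`, `y`.
#' @export
#' @examples
#' xy <- generate_bivariate(1000, 0.3, seed = 1)
#' cor(xy[, 1], xy[, 2])
generate_bivariate <- function(n, rho, seed = NULL) {
  if (n < 4) stop("n must be >= 4")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(x = z1, y = rho * z1 + sqrt(1 - rho^2) * z2)
}

#' Write the data streams of a cohort as delimited text tables
#'
#' @param cohort an `imcor_cohort`.
#' @param dir output directory (created if missing). Files:
#'   `profiles.tsv`, `mep_trials.tsv`, `miqrs.tsv`, `crft_trials.tsv`,
#'   `hljt_trials.tsv`, `vividness.tsv`, and `config.json`.
#' @return invisibly, the vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "imcor_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(cohort)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(cohort[[nm]], p, sep = "\t")
    paths <- c(paths, p)
  }
  cfgp <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(attr(cohort, "config")), cfgp,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, cfgp))
}

#' Read a cohort previously written by [write_cohort]
#'
#' @param dir directory containing the tsv tables.
#' @return an `imcor_cohort` (config attribute restored from `config.json`
#'   when present).
#' @export
read_cohort <- function(dir) {
  nms <- c("profiles", "mep_trials", "miqrs", "crft_trials",
           "hljt_trials", "vividness")
  out <- lapply(nms, function(nm) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(p)) stop("missing table: ", p)
    data.table::fread(p, sep = "\t")
  })
  names(out) <- nms
  cfgp <- file.path(dir, "config.json")
  cfg <- if (file.exists(cfgp)) {
    raw <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
    do.call(cohort_config, raw[names(raw) %in% names(formals(cohort_config))])
  } else NULL
  structure(out, class = "imcor_cohort", config = cfg)
}
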