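# Quality control of MEP trials and derivation of the per-participant
# corticospinal facilitation and disinhibition measures.

#' Peak-to-peak amplitude of an EMG trace segment
#'
#' @param samples numeric vector of EMG samples (micro-volts).
#' @param window integer indices of the analysis window (e.g. the segment
#'   after the stimulus artefact); may be given as a length-2 range
#'   `c(from, to)` or as an index vector.
#' @return max minus min over the window (micro-volts).
#' @export
#' @examples
#' peak_to_peak(c(0, 120, -80, 10), c(1, 4))  # 200
peak_to_peak <- function(samples, window = c(1L, length(samples))) {
  if (length(window) == 2L && window[2] >= window[1]) {
    idx <- window[1]:window[2]
  } else {
    idx <- window
  }
  if (length(idx) == 0L) stop("empty analysis window")
  if (min(idx) < 1L || max(idx) > length(samples))
    stop("window outside the sample sequence")
  w <- samples[idx]
  max(w) - min(w)
}

#' Simulate a toy EMG trace around a TMS pulse
#'
#' Minimal waveform generator whose only purpose is to exercise
#' [peak_to_peak]: a flat pre-stimulus baseline, a large brief stimulus
#' artefact, then a biphasic MEP deflection whose peak-to-peak amplitude
#' equals `amplitude` (plus additive noise, if any). Amplitudes in the
#' cohort generator are drawn directly; this mode is optional.
#'
#' @param amplitude target MEP peak-to-peak amplitude (micro-volts).
#' @param fs sampling rate (Hz).
#' @param pre_ms baseline duration before the artefact (ms).
#' @param mep_onset_ms latency from artefact to MEP onset (ms).
#' @param mep_ms MEP duration (ms).
#' @param noise_sd additive Gaussian noise SD (micro-volts; 0 for an exact
#'   trace).
#' @return list with `samples` (the trace) and `window` (index range after
#'   the artefact, suitable for [peak_to_peak]).
#' @export
#' @examples
#' tr <- simulate_emg_trace(200, noise_sd = 0)
#' peak_to_peak(tr$samples, tr$window)  # 200
simulate_emg_trace <- function(amplitude, fs = 4000, pre_ms = 10,
                               mep_onset_ms = 20, mep_ms = 15,
                               noise_sd = 0) {
  stopifnot(amplitude >= 0, fs > 0)
  ms <- function(t) round(t * fs / 1000)
  n_pre <- ms(pre_ms)
  n_art <- ms(2)
  n_gap <- ms(mep_onset_ms)
  n_mep <- ms(mep_ms)
  s1 <- sin(seq(0, pi, length.out = n_mep %/% 2))
  s2 <- sin(seq(0, pi, length.out = n_mep - n_mep %/% 2))
  # rescale so the discrete grid attains the peaks exactly
  mep <- c(amplitude * 0.55 * s1 / max(s1), -amplitude * 0.45 * s2 / max(s2))
  samples <- c(rep(0, n_pre), rep(5 * max(amplitude, 50), n_art),
               rep(0, n_gap), mep, rep(0, ms(10)))
  if (noise_sd > 0) samples <- samples + rnorm(length(samples), 0, noise_sd)
  list(samples = samples,
       window = c(n_pre + n_art + 1L, length(samples)))
}

#' Quality-control thresholds for MEP trials
#'
#' Defaults: every coil deviation strictly below 3 (mm for distance,
#' degrees for tilt and rotation) and pre-stimulus RMS strictly below
#' 10 micro-volts. The RMS ceiling stands in for the study's supplementary
#' rejection rules, which are not available; it is configurable.
#'
#' @param coil_distance,coil_tilt,coil_rotation coil deviation thresholds.
#' @param rms_ceiling pre-stimulus RMS ceiling (micro-volts).
#' @return named list of thresholds.
#' @export
qc_limits <- function(coil_distance = 3, coil_tilt = 3, coil_rotation = 3,
                      rms_ceiling = 10) {
  stopifnot(coil_distance > 0, coil_tilt > 0, coil_rotation > 0,
            rms_ceiling > 0)
  list(coil_distance = coil_distance, coil_tilt = coil_tilt,
       coil_rotation = coil_rotation, rms_ceiling = rms_ceiling)
}

#' Filter MEP trials on coil placement and background EMG
#'
#' Retains trials whose three coil deviations are each strictly below their
#' thresholds and whose pre-stimulus RMS is strictly below the ceiling. The
#' rejection log records one reason per rejected trial (the first breached
#' limit, checked in the order distance, tilt, rotation, RMS).
#'
#' @param trials data.frame of MEP trials with columns `coil_distance`,
#'   `coil_tilt`, `coil_rotation`, `pre_stim_rms`.
#' @param limits a [qc_limits] list.
#' @return list with `retained` (the passing rows) and `rejected` (the
#'   failing rows plus a `reason` column).
#' @export
qc_filter <- function(trials, limits = qc_limits()) {
  need <- c("coil_distance", "coil_tilt", "coil_rotation", "pre_stim_rms")
  if (!all(need %in% names(trials)))
    stop("trials must have columns: ", paste(need, collapse = ", "))
  reason <- rep(NA_character_, nrow(trials))
  reason[is.na(reason) & !(trials$coil_distance < limits$coil_distance)] <- "coil_distance"
  reason[is.na(reason) & !(trials$coil_tilt < limits$coil_tilt)] <- "coil_tilt"
  reason[is.na(reason) & !(trials$coil_rotation < limits$coil_rotation)] <- "coil_rotation"
  reason[is.na(reason) & !(trials$pre_stim_rms < limits$rms_ceiling)] <- "pre_stim_rms"
  ok <- is.na(reason)
  rejected <- trials[!ok, , drop = FALSE]
  if (nrow(rejected) > 0L) rejected$reason <- reason[!ok]
  else rejected$reason <- character(0)
  list(retained = trials[ok, , drop = FALSE], rejected = rejected)
}

#' Percentage MEP change (muscle-specific corticospinal facilitation)
#'
#' `(active mean / non-active mean) * 100`. Values above 100 indicate
#' muscle-specific facilitation during imagery of the recorded muscle;
#' exactly 100 means no muscle-specific effect.
#'
#' @param active_mean mean single-pulse MEP amplitude when the recorded
#'   muscle is the imagined one (micro-volts).
#' @param nonactive_mean mean amplitude when the other muscle is imagined;
#'   must be > 0.
#' @return percentage.
#' @export
#' @examples
#' pct_mep_change(150, 100)  # 150
pct_mep_change <- function(active_mean, nonactive_mean) {
  if (any(nonactive_mean <= 0))
    stop("non-active mean must be > 0; measure undefined")
  (active_mean / nonactive_mean) * 100
}

#' Percentage inhibition in a paired-pulse protocol
#'
#' `(conditioned mean / unconditioned mean) * 100`; values below 100
#' indicate inhibition by the conditioning stimulus.
#'
#' @param conditioned_mean mean conditioned (paired-pulse) MEP amplitude.
#' @param unconditioned_mean mean unconditioned (single-pulse) amplitude;
#'   must be > 0.
#' @return percentage.
#' @export
pct_inhibition <- function(conditioned_mean, unconditioned_mean) {
  if (any(unconditioned_mean <= 0))
    stop("unconditioned mean must be > 0; measure undefined")
  (conditioned_mean / unconditioned_mean) * 100
}

#' Change in inhibition between active and non-active imagery
#'
#' Simple subtraction of the two inhibition percentages; positive values
#' indicate muscle-specific disinhibition during imagery of the recorded
#' muscle.
#'
#' @param inh_active,inh_nonactive inhibition percentages (>= 0).
#' @return percentage points.
#' @export
delta_inhibition <- function(inh_active, inh_nonactive) {
  stopifnot(all(inh_active >= 0), all(inh_nonactive >= 0))
  inh_active - inh_nonactive
}

#' Derive per-participant neurophysiological outcome measures
#'
#' For each participant and muscle, aggregates retained trial amplitudes by
#' cell mean (or median) and composes the three outcome formulas. For
#' muscle FDI the "active" condition is imagery of FDI and the "non-active"
#' condition imagery of ADM; symmetrically for ADM. The rest condition is
#' aggregated and reported but does not enter the measures. The combined
#' measures are the arithmetic means of the two per-muscle values.
#'
#' @param trials data.frame of (QC-retained) MEP trials with columns
#'   `participant_id`, `condition`, `protocol`, `muscle`, `amplitude`.
#' @param aggregate `"mean"` (default) or `"median"` trial aggregation.
#' @return data.table, one row per participant: per-muscle and combined
#'   `pct_mep_change`, `inh_active`, `inh_nonactive`, `delta_inh`, the rest-
#'   condition means, the number of trials used, and a `complete` flag
#'   (FALSE when any required cell is empty; such participants get NA
#'   measures rather than an error).
#' @export
derive_neuro_outcomes <- function(trials, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  dt <- data.table::as.data.table(trials)
  need <- c("participant_id", "condition", "protocol", "muscle", "amplitude")
  if (!all(need %in% names(dt)))
    stop("trials must have columns: ", paste(need, collapse = ", "))

  cell <- if (aggregate == "mean") {
    # spelled out so data.table's optimized group mean kicks in
    dt[, .(m = mean(amplitude), k = .N),
       by = .(participant_id, condition, protocol, muscle)]
  } else {
    dt[, .(m = agg(amplitude), k = .N),
       by = .(participant_id, condition, protocol, muscle)]
  }
  w <- data.table::dcast(cell, participant_id ~ condition + protocol + muscle,
                         value.var = "m")
  col <- function(nm) if (nm %in% names(w)) w[[nm]] else rep(NA_real_, nrow(w))
  ntr <- cell[, .(n_trials = sum(k)), by = participant_id]

  # a cell mean is "usable" when present and positive (ratio denominators)
  ratio100 <- function(num, den) ifelse(!is.na(den) & den > 0 & !is.na(num),
                                        100 * num / den, NA_real_)
  per_muscle <- function(musc) {
    other <- if (musc == "FDI") "ADM" else "FDI"
    act_s <- col(paste0("imagery_", musc, "_single_", musc))
    non_s <- col(paste0("imagery_", other, "_single_", musc))
    act_p <- col(paste0("imagery_", musc, "_paired_", musc))
    non_p <- col(paste0("imagery_", other, "_paired_", musc))
    ia <- ratio100(act_p, act_s)
    ina <- ratio100(non_p, non_s)
    list(pct = ratio100(act_s, non_s), ia = ia, ina = ina, di = ia - ina,
         rest_s = col(paste0("rest_single_", musc)),
         rest_p = col(paste0("rest_paired_", musc)))
  }
  f <- per_muscle("FDI")
  a <- per_muscle("ADM")
  out <- data.table::data.table(
    participant_id = w$participant_id,
    pct_mep_change_fdi = f$pct, pct_mep_change_adm = a$pct,
    pct_mep_change = (f$pct + a$pct) / 2,
    inh_active_fdi = f$ia, inh_active_adm = a$ia,
    inh_nonactive_fdi = f$ina, inh_nonactive_adm = a$ina,
    delta_inh_fdi = f$di, delta_inh_adm = a$di,
    delta_inh = (f$di + a$di) / 2,
    rest_mean_single_fdi = f$rest_s, rest_mean_single_adm = a$rest_s,
    rest_mean_paired_fdi = f$rest_p, rest_mean_paired_adm = a$rest_p,
    complete = !is.na(f$pct) & !is.na(a$pct) & !is.na(f$di) & !is.na(a$di)
  )
  out <- merge(out, ntr, by = "participant_id")
  data.table::setkey(out, participant_id)
  out[]
}
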