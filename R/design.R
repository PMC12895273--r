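# Constraint-based pseudo-randomized schedules for the TMS session, the
# hand-laterality judgement task, and the chronometric radial Fitts task.

TMS_CONDITIONS <- c("imagery_FDI", "imagery_ADM", "rest")
TMS_PROTOCOLS <- c("single", "paired")

# canonical target-diameter -> index-of-difficulty lookup (PsychoPy units, bits)
CRFT_DIAMETERS <- c(0.018, 0.024, 0.05, 0.1, 0.21)
CRFT_IDS <- c(6.34, 5.35, 4.3, 3.38, 2.47)

#' Fitts index of difficulty for the radial reaching task
#'
#' The five task targets use a fixed, canonical diameter-to-ID lookup. No
#' standard Fitts formulation reproduces those printed IDs exactly from the
#' stated 0.4-unit edge-to-edge distance, so the lookup is authoritative; a
#' Shannon formulation `log2(distance/diameter + 1)` is provided as a
#' documented, non-canonical alternative for other geometries.
#'
#' @param diameter target diameter in PsychoPy units. For `"lookup"` it must
#'   be one of 0.018, 0.024, 0.05, 0.1, 0.21.
#' @param formulation `"lookup"` (canonical) or `"shannon"`.
#' @param distance centre-to-centre or edge-to-edge amplitude for the
#'   Shannon formulation (default 0.4).
#' @return index of difficulty in bits.
#' @export
#' @examples
#' fitts_id(0.21)             # 2.47
#' fitts_id(0.4, "shannon")   # 1
fitts_id <- function(diameter, formulation = c("lookup", "shannon"),
                     distance = 0.4) {
  formulation <- match.arg(formulation)
  if (formulation == "shannon") {
    stopifnot(all(diameter > 0), distance > 0)
    return(log2(distance / diameter + 1))
  }
  i <- vapply(diameter, function(d) {
    j <- which(abs(CRFT_DIAMETERS - d) < 1e-9)
    if (length(j) != 1L)
      stop("unknown target diameter for lookup: ", d)
    j
  }, integer(1))
  CRFT_IDS[i]
}

#' Target table for the chronometric radial Fitts task
#'
#' @return data.frame of the five targets (diameter, id_bits) with the task
#'   geometry (home target, edge-to-edge distance, repetitions per condition)
#'   in attributes.
#' @export
crft_design <- function() {
  d <- data.frame(diameter = CRFT_DIAMETERS, id_bits = CRFT_IDS)
  attr(d, "home") <- list(diameter = 0.05, position = c(0, -0.2))
  attr(d, "distance") <- 0.4
  attr(d, "reps_per_id") <- 4L
  attr(d, "reaches_per_trial") <- 5L
  d
}

#' Truncated Gaussian pulse-onset times
#'
#' Draws from a normal distribution truncated to `[lo, hi]` by resampling,
#' matching the stated pulse-timing model (mean 2 s, SD 0.25 s, delivered
#' 1-3 s after the Go signal).
#'
#' @param n number of draws.
#' @param mean,sd Gaussian parameters (seconds).
#' @param lo,hi truncation bounds (seconds).
#' @return numeric vector of length `n`, all inside `[lo, hi]`.
#' @export
rtrunc_gauss <- function(n, mean = 2, sd = 0.25, lo = 1, hi = 3) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0L) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# sample a protocol order for one sub-block: 5 single + 5 paired,
# no more than `max_run` consecutive identical protocols
sample_protocol_subblock <- function(max_run = 3L, budget = 10000L) {
  base <- rep(TMS_PROTOCOLS, each = 5L)
  for (i in seq_len(budget)) {
    cand <- sample(base)
    if (max(rle(cand)$lengths) <= max_run) return(cand)
  }
  stop("internal error: protocol rejection budget exhausted")  # nocov
}

#' Build the pseudo-randomized TMS session schedule
#'
#' 180 trials in 3 blocks of 60; each block has 6 sub-blocks of 10
#' same-condition trials arranged so every window of three consecutive
#' sub-blocks within a block contains each condition exactly once and no
#' condition repeats across consecutive sub-blocks (including block
#' boundaries). Each sub-block mixes 5 single-pulse and 5 paired-pulse
#' trials with at most 3 consecutive trials of the same protocol. One
#' common multiset of 60 truncated-Gaussian pulse times is drawn and
#' independently re-ordered for each condition. Two attention checks per
#' block are placed at the ends of distinct sub-blocks.
#'
#' @param seed integer seed.
#' @param iti_range inter-trial interval range in seconds (min must be >= 3).
#' @return data.frame with one row per trial: `trial`, `block`, `sub_block`
#'   (1-18), `condition`, `protocol`, `pulse_time`, `iti`,
#'   `attention_check`.
#' @export
build_tms_schedule <- function(seed, iti_range = c(4, 6)) {
  stopifnot(iti_range[1] >= 3, iti_range[2] >= iti_range[1])
  set.seed(as.integer(seed))
  budget <- 10000L

  # condition order: each block is a random permutation repeated twice,
  # which is the unique structure satisfying the 3-sub-block window rule;
  # resample at block boundaries so no condition repeats consecutively
  block_patterns <- vector("list", 3L)
  block_patterns[[1L]] <- sample(TMS_CONDITIONS)
  for (b in 2:3) {
    for (i in seq_len(budget)) {
      p <- sample(TMS_CONDITIONS)
      if (p[1L] != block_patterns[[b - 1L]][3L]) break
      if (i == budget) stop("internal error: block pattern budget exhausted")  # nocov
    }
    block_patterns[[b]] <- p
  }
  sub_conditions <- unlist(lapply(block_patterns, function(p) c(p, p)))

  protocol <- unlist(lapply(1:18, function(s) sample_protocol_subblock()))
  cond_trial <- rep(sub_conditions, each = 10L)

  # one common multiset of 60 pulse times, shuffled independently per condition
  times60 <- rtrunc_gauss(60L)
  pulse_time <- numeric(180L)
  for (cond in TMS_CONDITIONS) {
    idx <- which(cond_trial == cond)
    pulse_time[idx] <- sample(times60)
  }

  # attention checks: 2 distinct sub-blocks per block, flagged on their
  # final trial
  check_sub <- unlist(lapply(0:2, function(b) 6L * b + sample.int(6L, 2L)))
  sub_block <- rep(1:18, each = 10L)
  trial_in_sub <- rep(1:10, times = 18L)
  attention_check <- sub_block %in% check_sub & trial_in_sub == 10L

  data.frame(
    trial = 1:180,
    block = rep(1:3, each = 60L),
    sub_block = sub_block,
    condition = cond_trial,
    protocol = protocol,
    pulse_time = pulse_time,
    iti = runif(180L, iti_range[1], iti_range[2]),
    attention_check = attention_check
  )
}

#' Validate a TMS session schedule against all design constraints
#'
#' Pure predicate over every constraint of the session design: trial and
#' cell counts, block and sub-block structure, the 3-sub-block window rule,
#' no consecutive same-condition sub-blocks, 5+5 protocol mix with maximum
#' run length 3, pulse-time and inter-trial-interval bounds, and the
#' attention-check layout.
#'
#' @param sched a schedule as returned by [build_tms_schedule].
#' @return `TRUE` if all constraints hold, otherwise `FALSE` with a
#'   character vector of violations in attribute `"violations"`.
#' @export
validate_tms_schedule <- function(sched) {
  v <- character(0)
  chk <- function(ok, msg) if (!ok) v <<- c(v, msg)

  chk(nrow(sched) == 180L, "trial count != 180")
  tab <- table(sched$condition, sched$protocol)
  chk(all(dim(tab) == c(3L, 2L)) && all(tab == 30L),
      "condition x protocol cells != 30 trials each")
  chk(all(table(sched$block) == 60L), "blocks != 60 trials")

  sub_cond <- tapply(sched$condition, sched$sub_block, unique)
  chk(all(lengths(sub_cond) == 1L) && length(sub_cond) == 18L &&
        all(table(sched$sub_block) == 10L),
      "sub-blocks are not 18 homogeneous sets of 10 trials")
  sc <- vapply(sub_cond, `[`, character(1), 1L)

  for (b in 0:2) {
    blk <- sc[(6L * b + 1L):(6L * b + 6L)]
    for (w in 1:4)
      chk(length(unique(blk[w:(w + 2L)])) == 3L,
          sprintf("block %d window %d misses a condition", b + 1L, w))
  }
  chk(all(sc[-1] != sc[-18L]), "condition repeated in consecutive sub-blocks")

  for (s in 1:18) {
    p <- sched$protocol[sched$sub_block == s]
    chk(sum(p == "single") == 5L && sum(p == "paired") == 5L,
        sprintf("sub-block %d protocol mix != 5+5", s))
    chk(max(rle(p)$lengths) <= 3L,
        sprintf("sub-block %d has > 3 consecutive same-protocol trials", s))
  }

  chk(all(sched$iti >= 3), "inter-trial interval < 3 s")
  chk(all(sched$pulse_time >= 1 & sched$pulse_time <= 3),
      "pulse time outside [1, 3] s")

  ac <- sched[sched$attention_check, , drop = FALSE]
  chk(nrow(ac) == 6L, "attention checks != 6")
  chk(all(table(factor(ac$block, levels = 1:3)) == 2L),
      "attention checks != 2 per block")
  chk(anyDuplicated(ac$sub_block) == 0L,
      "attention checks share a sub-block")
  last_trial <- tapply(sched$trial, sched$sub_block, max)
  chk(all(ac$trial %in% last_trial), "attention check not at sub-block end")

  structure(length(v) == 0L, violations = v)
}

#' The 32 unique hand-laterality stimuli
#'
#' Crossing of hand (L/R), view (palm/back) and 8 rotation angles, with the
#' rotation-direction label. Nominal angles 45/90/135 are labelled medial
#' and 225/270/315 lateral (0 and 180 are neutral), identically for both
#' hands under the task's mirrored angle convention (clockwise for right
#' hands, counterclockwise for left); `swap_direction` flips the mapping.
#'
#' @param swap_direction logical; exchange medial and lateral labels.
#' @return data.frame of 32 stimuli: `stimulus` (id), `hand`, `view`,
#'   `angle`, `direction`.
#' @export
hljt_stimuli <- function(swap_direction = FALSE) {
  g <- expand.grid(hand = c("L", "R"), view = c("palm", "back"),
                   angle = seq(0L, 315L, by = 45L),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  medial <- c(45L, 90L, 135L)
  lateral <- c(225L, 270L, 315L)
  if (swap_direction) { tmp <- medial; medial <- lateral; lateral <- tmp }
  g$direction <- ifelse(g$angle %in% medial, "medial",
                        ifelse(g$angle %in% lateral, "lateral", "neutral"))
  g <- g[order(g$hand, g$view, g$angle), ]
  g$stimulus <- paste(g$hand, g$view, g$angle, sep = "_")
  rownames(g) <- NULL
  g[, c("stimulus", "hand", "view", "angle", "direction")]
}

#' Build the hand-laterality judgement task schedule
#'
#' One practice block of 32 trials (each unique stimulus once) followed by
#' 3 test blocks of 96 trials; each test block consists of 3 sub-blocks of
#' 32 trials containing every stimulus exactly once, so no stimulus can
#' appear more than twice consecutively anywhere in the test sequence.
#'
#' @param seed integer seed.
#' @param swap_direction passed to [hljt_stimuli].
#' @return data.frame with one row per trial: `phase` ("practice"/"test"),
#'   `block` (0 for practice, 1-3 for test), `sub_block`, `trial`, plus the
#'   stimulus columns of [hljt_stimuli].
#' @export
build_hljt_schedule <- function(seed, swap_direction = FALSE) {
  set.seed(as.integer(seed))
  stim <- hljt_stimuli(swap_direction)
  perm <- function() stim[sample.int(32L), , drop = FALSE]
  practice <- cbind(phase = "practice", block = 0L, sub_block = 0L, perm())
  test <- do.call(rbind, lapply(1:9, function(s) {
    cbind(phase = "test", block = ((s - 1L) %/% 3L) + 1L, sub_block = s, perm())
  }))
  out <- rbind(practice, test)
  out$trial <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Validate a hand-laterality schedule
#'
#' @param sched a schedule as returned by [build_hljt_schedule].
#' @return `TRUE` if all constraints hold, otherwise `FALSE` with violations
#'   in attribute `"violations"`.
#' @export
validate_hljt_schedule <- function(sched) {
  v <- character(0)
  chk <- function(ok, msg) if (!ok) v <<- c(v, msg)

  test <- sched[sched$phase == "test", , drop = FALSE]
  prac <- sched[sched$phase == "practice", , drop = FALSE]
  chk(length(unique(sched$stimulus)) == 32L, "unique stimuli != 32")
  chk(nrow(test) == 288L, "test trials != 288")
  chk(nrow(prac) == 32L && anyDuplicated(prac$stimulus) == 0L,
      "practice block is not one repetition per stimulus")
  chk(all(table(test$stimulus) == 9L), "test repetitions per stimulus != 9")
  sub_ok <- vapply(split(test$stimulus, test$sub_block),
                   function(s) length(s) == 32L && anyDuplicated(s) == 0L,
                   logical(1))
  chk(all(sub_ok), "a test sub-block is not a complete permutation")
  chk(max(rle(test$stimulus)$lengths) <= 2L,
      "a stimulus appears more than twice consecutively")
  structure(length(v) == 0L, violations = v)
}
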