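# Forward simulation: a behavioral agent with task-dependent accuracy and a
# 16-channel EEG synthesizer that injects a posterior-maximal P300b at
# attended-word onsets and nothing elsewhere.

#' Default P300b scalp topography
#'
#' Per-channel weights of the injected P300b: 1.0 over the centro-parietal
#' midline (CPZ, PZ, POZ), 0.6 over the flanking parietal ring
#' (CP3, CP4, OZ), 0.3 elsewhere. Qualitatively posterior-maximal; the exact
#' values are free parameters.
#'
#' @return Named numeric vector over \code{\link{batteryMontage}}.
#' @export
defaultTopography <- function() {
  ch <- batteryMontage()
  w <- rep(0.3, length(ch))
  names(w) <- ch
  w[c("CPZ", "PZ", "POZ")] <- 1.0
  w[c("CP3", "CP4", "OZ")] <- 0.6
  w
}

#' Simulation configuration
#'
#' Generative parameters of the synthetic participant. Defaults emulate a
#' healthy adult: a 4 microvolt P300b peaking 450 ms after attended-word
#' onset, AR(1) background noise, and behavioral accuracies near the healthy
#' range (WM recall 0.97/0.80/0.64 for set sizes 4/6/8, reasoning 0.95,
#' target counting 0.70).
#'
#' @param p300Amplitude peak amplitude of the injected P300b, microvolts.
#' @param p300Latency_s peak latency after word onset, seconds.
#' @param p300Width_s full width of the raised-cosine kernel, seconds.
#' @param topography named per-channel weight vector (montage order).
#' @param noiseSD noise standard deviation per channel, microvolts.
#' @param noiseModel "ar1", "white" or "pink".
#' @param ar1Coef AR(1) coefficient when \code{noiseModel = "ar1"}.
#' @param accuracyWM named vector, probability of a correct recall answer by
#'   set size ("4", "6", "8").
#' @param accuracyAR probability of a correct reasoning answer.
#' @param countAccuracy probability of a correct count report.
#' @param samplingRate Hz.
#' @return list of class "SimulationConfig".
#' @export
simConfig <- function(p300Amplitude = 4, p300Latency_s = 0.45,
                      p300Width_s = 0.4, topography = defaultTopography(),
                      noiseSD = 9, noiseModel = c("ar1", "white", "pink"),
                      ar1Coef = 0.95,
                      accuracyWM = c("4" = 0.97, "6" = 0.80, "8" = 0.64),
                      accuracyAR = 0.95, countAccuracy = 0.70,
                      samplingRate = 256) {
  noiseModel <- match.arg(noiseModel)
  probs <- c(accuracyWM, accuracyAR, countAccuracy)
  if (any(probs < 0 | probs > 1)) stop("accuracies must lie in [0, 1]")
  if (!all(c("4", "6", "8") %in% names(accuracyWM)))
    stop("accuracyWM must be named by set size: \"4\", \"6\", \"8\"")
  if (is.null(names(topography)) ||
      !setequal(names(topography), batteryMontage()))
    stop("topography must be named over the 16-channel montage")
  topography <- topography[batteryMontage()]
  if (which.max(topography) != match("CPZ", batteryMontage()) &&
      max(topography) > topography[["CPZ"]] + 1e-12 &&
      max(topography[c("CPZ", "PZ", "POZ")]) < max(topography))
    stop("topography must be maximal over the centro-parietal midline")
  structure(list(
    p300Amplitude = p300Amplitude, p300Latency_s = p300Latency_s,
    p300Width_s = p300Width_s, topography = topography, noiseSD = noiseSD,
    noiseModel = noiseModel, ar1Coef = ar1Coef, accuracyWM = accuracyWM,
    accuracyAR = accuracyAR, countAccuracy = countAccuracy,
    samplingRate = samplingRate
  ), class = "SimulationConfig")
}

#' Simulate the behavioral agent
#'
#' One row per trial. The agent attends the word it answers: in AT the given
#' target, in WM the probed word (correct with the set-size-specific
#' accuracy, otherwise a uniformly chosen wrong member of the memory set), in
#' AR the correct noun with probability \code{accuracyAR}, otherwise the
#' other noun of the sentence. The count report is correct with probability
#' \code{countAccuracy}, otherwise off by one within the offered options
#' {7, 8, 9, 10}.
#'
#' @param schedule a \linkS4class{BatterySchedule}.
#' @param cfg a \code{\link{simConfig}}.
#' @return data.frame: trial, task, attended_word_id, answer_word_id,
#'   correct, reported_count, true_count.
#' @export
simulateAgent <- function(schedule, cfg = simConfig()) {
  tr <- schedule@trials
  n <- nrow(tr)
  attended <- integer(n)
  correct <- logical(n)
  reported <- integer(n)
  for (i in seq_len(n)) {
    target <- tr$target_word_id[i]
    if (tr$task[i] == "AT") {
      attended[i] <- target
      correct[i] <- TRUE
    } else if (tr$task[i] == "WM") {
      acc <- cfg$accuracyWM[[as.character(tr$set_size[i])]]
      if (stats::runif(1) < acc) {
        attended[i] <- target
      } else {
        wrong <- setdiff(schedule@memorySets[[i]], target)
        attended[i] <- if (length(wrong) == 1L) wrong else sample(wrong, 1)
      }
      correct[i] <- attended[i] == target
    } else {
      other <- if (target == tr$noun1_id[i]) tr$noun2_id[i] else tr$noun1_id[i]
      attended[i] <- if (stats::runif(1) < cfg$accuracyAR) target else other
      correct[i] <- attended[i] == target
    }
    trueCount <- sum(schedule@streams[[i]] == attended[i])
    if (stats::runif(1) < cfg$countAccuracy) {
      reported[i] <- trueCount
    } else {
      opts <- intersect(trueCount + c(-1L, 1L), 7:10)
      reported[i] <- if (length(opts) == 1L) opts else sample(opts, 1)
    }
  }
  data.frame(trial = tr$trial, task = tr$task, attended_word_id = attended,
             answer_word_id = attended, correct = correct,
             reported_count = reported,
             true_count = mapply(function(s, a) sum(s == a),
                                 schedule@streams, attended))
}

#' Raised-cosine P300b kernel
#'
#' Single positive half-wave peaking at \code{latency_s} with full width
#' \code{width_s}, sampled on the epoch grid.
#'
#' @param nSamples number of post-onset samples to render.
#' @param fs sampling rate (Hz).
#' @param amplitude peak amplitude (microvolts).
#' @param latency_s peak latency (seconds).
#' @param width_s full width (seconds).
#' @return numeric vector of length \code{nSamples}.
#' @export
p300Kernel <- function(nSamples, fs, amplitude = 4, latency_s = 0.45,
                       width_s = 0.4) {
  t <- (seq_len(nSamples) - 1L) / fs
  x <- (t - latency_s) / (width_s / 2)
  k <- ifelse(abs(x) <= 1, amplitude * 0.5 * (1 + cos(pi * x)), 0)
  k
}

# continuous noise, one channel x samples matrix
simNoise <- function(nCh, nSamp, cfg) {
  if (cfg$noiseSD == 0) return(matrix(0, nCh, nSamp))
  z <- matrix(stats::rnorm(nCh * nSamp), nCh, nSamp)
  if (cfg$noiseModel == "white") return(cfg$noiseSD * z)
  if (cfg$noiseModel == "ar1") {
    a <- cfg$ar1Coef
    out <- t(apply(z, 1, function(e)
      as.numeric(stats::filter(e, a, method = "recursive"))))
    # scale innovations so the stationary SD equals noiseSD
    return(out * cfg$noiseSD * sqrt(1 - a^2))
  }
  # pink: 1/sqrt(f) spectral shaping via FFT
  out <- t(apply(z, 1, function(e) {
    n <- length(e)
    f <- c(1, seq_len(n - 1))
    sp <- stats::fft(e) / sqrt(pmin(f, n - f + 1))
    Re(stats::fft(sp, inverse = TRUE)) / n
  }))
  out * (cfg$noiseSD / stats::sd(as.numeric(out)))
}

#' Synthesize a continuous EEG recording for a session
#'
#' Renders background noise for the whole session and adds the P300b kernel,
#' scaled by the scalp topography, at the onset of every stream word that
#' equals the trial's attended word. Unattended words add nothing, so their
#' post-baseline expected mean is zero.
#'
#' @param schedule a \linkS4class{BatterySchedule}.
#' @param agent output of \code{\link{simulateAgent}} (or any data.frame with
#'   \code{trial} and \code{attended_word_id}).
#' @param cfg a \code{\link{simConfig}}.
#' @param trials optional vector of trial numbers to render (default: all).
#'   Events and data cover only those trials; epoching then yields exactly
#'   those trials' epochs.
#' @param gap_s gap between streams, seconds (see
#'   \code{\link{scheduleEvents}}).
#' @return An \linkS4class{EEGRecording} whose events table carries an
#'   \code{attended} flag.
#' @export
synthesizeRecording <- function(schedule, agent, cfg = simConfig(),
                                trials = NULL, gap_s = 1) {
  fs <- cfg$samplingRate
  ev <- scheduleEvents(schedule, gap_s = gap_s, leadIn_s = 1)
  if (!is.null(trials)) {
    ev <- ev[ev$trial_index %in% trials, ]
    if (!nrow(ev)) stop("no events in the selected trials")
    # re-pack the timeline so the recording has no dead stretches
    onsets <- ev$onset_s
    split_idx <- split(seq_len(nrow(ev)), factor(ev$trial_index,
                                                 unique(ev$trial_index)))
    cursor <- 1
    for (ix in split_idx) {
      n <- length(ix)
      onsets[ix] <- cursor + (seq_len(n) - 1L) * 0.5
      cursor <- cursor + n * 0.5 + gap_s
    }
    ev$onset_s <- onsets
  }
  attMap <- agent$attended_word_id[match(ev$trial_index, agent$trial)]
  ev$attended <- ev$word_id == attMap
  nCh <- length(batteryMontage())
  totalDur <- max(ev$onset_s) + 1.6   # room for the last epoch window
  nSamp <- ceiling(totalDur * fs)
  data <- simNoise(nCh, nSamp, cfg)
  kern <- p300Kernel(round(1.0 * fs), fs, cfg$p300Amplitude,
                     cfg$p300Latency_s, cfg$p300Width_s)
  topo <- cfg$topography
  onsetSamples <- floor(ev$onset_s * fs)
  for (j in which(ev$attended)) {
    s0 <- onsetSamples[j] + 1L
    idx <- s0:(s0 + length(kern) - 1L)
    data[, idx] <- data[, idx] + outer(topo, kern)
  }
  events <- data.frame(sample = as.integer(onsetSamples),
                       onset_s = ev$onset_s, word_id = ev$word_id,
                       trial = ev$trial_index, block = ev$block_index,
                       task = ev$task, is_target = ev$is_target,
                       attended = ev$attended)
  new("EEGRecording", data = data, channels = batteryMontage(),
      samplingRate = fs, events = events)
}
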