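#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib p300battery, .registration = TRUE
NULL

#' The 16-channel montage of the battery
#'
#' Channel labels of the centro-parietal 10-10 montage the battery records
#' from, in canonical order.
#'
#' @return Character vector of 16 electrode labels.
#' @export
#' @examples
#' batteryMontage()
batteryMontage <- function() {
  c("FC3", "C3", "CP3", "FCZ", "CZ", "CPZ", "FC4", "C4", "CP4",
    "T7", "T8", "PZ", "POZ", "OZ", "P7", "P8")
}

#' BatterySchedule: the full session plan
#'
#' A six-block, 72-trial session plan (block order AT, WM, AR, AT, WM, AR;
#' 12 trials per block). Each trial carries its oddball stream (a shuffled
#' multiset with an equal number of occurrences of all eight words), and the
#' task-specific payload: the experimenter-given target (AT), the memory set
#' and probe position (WM), or the reasoning sentence (AR).
#'
#' @slot trials data.frame with one row per trial: \code{trial}, \code{block},
#'   \code{task} ("AT"/"WM"/"AR"), \code{repetitions} (7--10),
#'   \code{target_word_id} (0--7, the correct answer), \code{set_size},
#'   \code{probe_position} (WM, NA otherwise), \code{noun1_id},
#'   \code{noun2_id}, \code{verb}, \code{voice}, \code{polarity} (AR, NA
#'   otherwise).
#' @slot streams list of 72 integer vectors of word ids (0--7), the timed word
#'   order of each trial's stream.
#' @slot memorySets list of 72 entries; for WM trials an integer vector of
#'   word ids (the ordered memory set), otherwise NULL.
#' @slot vocabulary character vector of 8 word labels, indexed by word id + 1.
#' @slot seed integer seed the schedule was drawn with.
#' @export
setClass("BatterySchedule",
  representation(
    trials = "data.frame",
    streams = "list",
    memorySets = "list",
    vocabulary = "character",
    seed = "integer"
  )
)

setValidity("BatterySchedule", function(object) {
  msg <- character()
  tr <- object@trials
  if (nrow(tr) != 72L) msg <- c(msg, "schedule must contain 72 trials")
  if (length(object@streams) != nrow(tr))
    msg <- c(msg, "one stream per trial required")
  if (length(object@vocabulary) != 8L ||
      anyDuplicated(object@vocabulary))
    msg <- c(msg, "vocabulary must be 8 unique word labels")
  if (nrow(tr) == 72L) {
    if (!identical(as.vector(table(tr$block)), rep(12L, 6L)))
      msg <- c(msg, "6 blocks of 12 trials required")
    at <- tr[tr$task == "AT", ]
    if (nrow(at) != 24L || !all(table(factor(at$target_word_id, 0:7)) == 3L))
      msg <- c(msg, "AT: each word must be target exactly 3 times")
    wm <- tr[tr$task == "WM", ]
    if (nrow(wm) != 24L ||
        !all(table(factor(wm$set_size, c(4, 6, 8))) == 8L))
      msg <- c(msg, "WM: each set size must be used in exactly 8 trials")
    ar <- tr[tr$task == "AR", ]
    if (nrow(ar) != 24L)
      msg <- c(msg, "AR: 24 trials required")
    else {
      tmpl <- interaction(ar$verb, ar$voice, ar$polarity, drop = FALSE)
      if (!all(table(tmpl) == 3L))
        msg <- c(msg, "AR: each of the 8 sentence templates must occur 3 times")
      key <- paste(ar$noun1_id, ar$noun2_id, ar$verb, ar$voice, ar$polarity)
      if (anyDuplicated(key))
        msg <- c(msg, "AR: the 24 sentences must be unique")
    }
  }
  # stream equal-count invariant
  for (i in seq_along(object@streams)) {
    s <- object@streams[[i]]
    r <- tr$repetitions[i]
    if (length(s) != 8L * r || !all(table(factor(s, 0:7)) == r)) {
      msg <- c(msg, sprintf("stream %d violates the equal-count invariant", i))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' EEGRecording: continuous multichannel EEG with event markers
#'
#' @slot data numeric matrix, channels x samples, microvolts.
#' @slot channels character vector of channel labels (montage order).
#' @slot samplingRate sampling rate in Hz.
#' @slot events data.frame of stimulus events: \code{sample} (0-based sample
#'   index of onset), \code{onset_s}, \code{word_id}, \code{trial},
#'   \code{block}, \code{task}.
#' @export
setClass("EEGRecording",
  representation(
    data = "matrix",
    channels = "character",
    samplingRate = "numeric",
    events = "data.frame"
  )
)

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channels))
    msg <- c(msg, "data rows must match channel labels")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a positive scalar")
  ev <- object@events
  if (nrow(ev)) {
    if (is.unsorted(ev$sample, strictly = TRUE))
      msg <- c(msg, "event sample indices must be strictly increasing")
    if (any(ev$sample < 0) || any(ev$sample >= ncol(object@data)))
      msg <- c(msg, "event sample indices must lie within the recording")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: baseline-windowed epochs around stimulus onsets
#'
#' Fixed-window (-200 to 1000 ms) segments of multichannel EEG time-locked to
#' word onsets, with per-epoch metadata.
#'
#' @slot data numeric array, channels x time x epochs, microvolts.
#' @slot times numeric vector of sample times in seconds relative to onset.
#' @slot channels character vector of channel labels.
#' @slot samplingRate sampling rate in Hz.
#' @slot info data.frame with one row per epoch (word_id, trial, block, task,
#'   plus any flags added downstream).
#' @slot baselined logical; TRUE once baseline correction has been applied.
#' @export
setClass("EpochSet",
  representation(
    data = "array",
    times = "numeric",
    channels = "character",
    samplingRate = "numeric",
    info = "data.frame",
    baselined = "logical"
  )
)

setValidity("EpochSet", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "data must be a channels x time x epochs array")
  else {
    if (d[1] != length(object@channels))
      msg <- c(msg, "channel dimension must match channel labels")
    if (d[2] != length(object@times))
      msg <- c(msg, "time dimension must match times vector")
    if (d[3] != nrow(object@info))
      msg <- c(msg, "epoch dimension must match metadata rows")
  }
  if (length(msg)) msg else TRUE
})

#' CMPTResult: outcome of a cluster-mass permutation test
#'
#' @slot tmap numeric matrix, channels x time, the pointwise t statistic.
#' @slot times numeric vector of epoch times (seconds).
#' @slot channels character vector of channel labels.
#' @slot clusters data.frame, one row per cluster (sorted by decreasing
#'   absolute mass): \code{id}, \code{mass}, \code{sign}, \code{size},
#'   \code{p}, \code{t_start}, \code{t_end}.
#' @slot membership integer matrix channels x time; 0 outside clusters, else
#'   the cluster id.
#' @slot p overall permutation p-value (of the largest-|mass| cluster); 1 when
#'   no cluster formed.
#' @slot selectedRegion logical matrix channels x time: the largest
#'   significant cluster (empty when the test is not significant).
#' @slot threshold cluster-forming t threshold.
#' @slot nullMax numeric vector, permutation null of the maximum |mass|.
#' @slot nPerm number of permutations (0 for exhaustive enumeration).
#' @slot level "group" or "single".
#' @slot alpha significance level used for region selection.
#' @export
setClass("CMPTResult",
  representation(
    tmap = "matrix",
    times = "numeric",
    channels = "character",
    clusters = "data.frame",
    membership = "matrix",
    p = "numeric",
    selectedRegion = "matrix",
    threshold = "numeric",
    nullMax = "numeric",
    nPerm = "numeric",
    level = "character",
    alpha = "numeric"
  )
)

setValidity("CMPTResult", function(object) {
  msg <- character()
  if (!object@level %in% c("group", "single"))
    msg <- c(msg, "level must be 'group' or 'single'")
  if (length(object@p) != 1L || object@p <= 0 || object@p > 1)
    msg <- c(msg, "p must lie in (0, 1]")
  sig <- object@p <= object@alpha && nrow(object@clusters) > 0L
  if (sig != any(object@selectedRegion))
    msg <- c(msg, "selectedRegion must be nonempty iff the test is significant")
  if (length(msg)) msg else TRUE
})
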