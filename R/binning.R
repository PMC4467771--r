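# Condition binning: assign stream epochs to positive (attended/correct) and
# negative (unattended/incorrect) conditions under each task's logic.

.checkTask <- function(schedule, trial, task) {
  tr <- schedule@trials[schedule@trials$trial == trial, ]
  if (!nrow(tr)) stop("unknown trial ", trial)
  if (tr$task != task) stop("trial ", trial, " is not a ", task, " trial")
  tr
}

.trialEpochs <- function(epochs, trial) {
  which(epochs@info$trial == trial)
}

.binning <- function(positive, negative, excluded = integer(0),
                     reason = character(0)) {
  structure(list(positive = positive, negative = negative,
                 excluded = excluded, reason = reason),
            class = "ConditionBinning")
}

#' Bin one AT trial: target vs all other words
#'
#' Positive = epochs of the experimenter-given target word; negative = all
#' other stream epochs (7:1 negative:positive in expectation).
#'
#' @param epochs an \linkS4class{EpochSet} whose metadata has \code{trial}
#'   and \code{word_id}.
#' @param schedule the \linkS4class{BatterySchedule}.
#' @param trial the AT trial number.
#' @return A ConditionBinning: lists \code{positive}, \code{negative},
#'   \code{excluded} of epoch indices into \code{epochs}.
#' @export
binAttention <- function(epochs, schedule, trial) {
  tr <- .checkTask(schedule, trial, "AT")
  idx <- .trialEpochs(epochs, trial)
  w <- epochs@info$word_id[idx]
  pos <- idx[w == tr$target_word_id]
  if (!length(pos))
    warning("target word has no surviving epochs in trial ", trial)
  .binning(pos, idx[w != tr$target_word_id])
}

#' Bin one WM trial: correct word vs all other words
#'
#' Positive = epochs of the probed (correct) word, regardless of what the
#' participant answered; negative = epochs of the seven other words.
#'
#' @inheritParams binAttention
#' @param trial the WM trial number.
#' @return A ConditionBinning.
#' @export
binWM <- function(epochs, schedule, trial) {
  tr <- .checkTask(schedule, trial, "WM")
  idx <- .trialEpochs(epochs, trial)
  w <- epochs@info$word_id[idx]
  .binning(idx[w == tr$target_word_id], idx[w != tr$target_word_id])
}

#' Bin one AR trial: correct noun vs the other sentence noun only
#'
#' Positive = epochs of the correct noun; negative = epochs of the other
#' noun of the sentence; the remaining six words are excluded, not pooled.
#' Pooling them would dilute the incorrect bin: a participant who solved the
#' sentence wrongly still attends one of the two nouns, and averaging that
#' P300b with six flat responses would bias the contrast toward
#' significance.
#'
#' @inheritParams binAttention
#' @param trial the AR trial number.
#' @return A ConditionBinning.
#' @export
binAR <- function(epochs, schedule, trial) {
  tr <- .checkTask(schedule, trial, "AR")
  idx <- .trialEpochs(epochs, trial)
  w <- epochs@info$word_id[idx]
  correct <- tr$target_word_id
  other <- if (correct == tr$noun1_id) tr$noun2_id else tr$noun1_id
  pos <- idx[w == correct]
  neg <- idx[w == other]
  if (!length(pos) && !length(neg))
    warning("both sentence nouns lost to rejection in trial ", trial)
  .binning(pos, neg, idx[!w %in% c(correct, other)],
           "not a sentence noun")
}

#' Partition epochs by the participant's behavioral answer
#'
#' Attended = epochs whose word equals the answer the participant gave in
#' that trial (right or wrong); unattended = all other stream epochs. Trials
#' without a behavioral response are excluded with a warning.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param responses data.frame with \code{trial} and \code{answer_word_id}
#'   (e.g. from \code{\link{simulateAgent}}).
#' @return list with \code{attended} and \code{unattended} epoch indices.
#' @export
binAttendedByBehavior <- function(epochs, responses) {
  info <- epochs@info
  m <- match(info$trial, responses$trial)
  if (anyNA(m)) {
    missing <- unique(info$trial[is.na(m)])
    warning("no behavioral response for trial(s) ",
            paste(missing, collapse = ", "), "; excluded")
  }
  ans <- responses$answer_word_id[m]
  keep <- !is.na(ans)
  att <- which(keep & info$word_id == ans)
  una <- which(keep & info$word_id != ans)
  list(attended = att, unattended = una)
}

#' Restrict a schedule's WM trials to given set sizes
#'
#' @param schedule a \linkS4class{BatterySchedule}.
#' @param allowed subset of c(4, 6, 8).
#' @return Integer vector of retained WM trial numbers.
#' @export
restrictSetSizes <- function(schedule, allowed) {
  if (!all(allowed %in% c(4, 6, 8)))
    stop("allowed must be a subset of {4, 6, 8}")
  tr <- schedule@trials
  out <- tr$trial[tr$task == "WM" & tr$set_size %in% allowed]
  if (!length(out)) stop("no WM trials at the requested set sizes")
  out
}

#' Bin a whole task's epochs into pooled conditions
#'
#' Applies the per-trial binning of the task to every trial present in the
#' epoch set and pools the indices; single-participant CMPT compares the two
#' pooled sets.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param schedule the \linkS4class{BatterySchedule}.
#' @param task "AT", "WM" or "AR".
#' @param trials optional subset of trial numbers (e.g. from
#'   \code{\link{restrictSetSizes}}).
#' @return list with pooled \code{positive}, \code{negative},
#'   \code{excluded} epoch indices.
#' @export
binSession <- function(epochs, schedule, task = c("AT", "WM", "AR"),
                       trials = NULL) {
  task <- match.arg(task)
  tr <- schedule@trials
  tt <- tr$trial[tr$task == task]
  if (!is.null(trials)) tt <- intersect(tt, trials)
  tt <- intersect(tt, unique(epochs@info$trial))
  if (!length(tt)) stop("no epochs for task ", task)
  f <- switch(task, AT = binAttention, WM = binWM, AR = binAR)
  pos <- neg <- exc <- integer(0)
  for (t in tt) {
    b <- f(epochs, schedule, t)
    pos <- c(pos, b$positive); neg <- c(neg, b$negative)
    exc <- c(exc, b$excluded)
  }
  list(positive = pos, negative = neg, excluded = exc)
}
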