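# Session plan: 6 blocks (AT, WM, AR, AT, WM, AR) x 12 trials, with
# per-block balancing of stream repetitions and the task-specific payloads.

#' Build a full battery schedule
#'
#' Draws the 72-trial session plan. Constraints: each word is the AT target
#' exactly 3 times; each WM set size (4, 6, 8) is used in exactly 8 trials
#' with memory sets sampled without replacement from the vocabulary; the 24 AR
#' sentences are unique, three per template type, with noun pairs sampled
#' without replacement; within each 12-trial block each stream repetition
#' count r in 7..10 is used 3 times.
#'
#' @param vocab character vector of 8 unique word labels.
#' @param seed integer seed; all schedule randomness flows from it.
#' @param forbidImmediateRepeats passed to \code{\link{generateStream}}.
#' @return A \linkS4class{BatterySchedule}.
#' @export
#' @examples
#' sched <- buildSchedule(seed = 1)
#' table(scheduleTrials(sched)$task)
buildSchedule <- function(vocab = wordVocabulary(), seed = 1L,
                          forbidImmediateRepeats = FALSE) {
  if (length(vocab) != 8L || anyDuplicated(vocab))
    stop("vocab must be 8 unique word labels")
  vocab <- unname(vocab)
  seed <- as.integer(seed)
  set.seed(seed)

  tasks <- c("AT", "WM", "AR", "AT", "WM", "AR")
  # AT targets: each word id 3x across the two AT blocks
  atTargets <- sample(rep(0:7, 3))
  # WM set sizes: each of 4/6/8 in 8 of the 24 WM trials
  wmSizes <- sample(rep(c(4L, 6L, 8L), 8))
  # AR sentences: 3 instances of each of the 8 templates, unique overall
  tmpl <- sentenceTemplates()
  arRows <- sample(rep(seq_len(8L), 3))
  arKey <- character(0)
  arN1 <- arN2 <- integer(24)
  for (i in seq_len(24L)) {
    repeat {
      pair <- sample(0:7, 2)
      key <- paste(pair[1], pair[2], arRows[i])
      if (!key %in% arKey) break
    }
    arKey <- c(arKey, key)
    arN1[i] <- pair[1]; arN2[i] <- pair[2]
  }

  trials <- data.frame(
    trial = 1:72, block = rep(1:6, each = 12L), task = rep(tasks, each = 12L),
    repetitions = NA_integer_, target_word_id = NA_integer_,
    set_size = NA_integer_, probe_position = NA_integer_,
    noun1_id = NA_integer_, noun2_id = NA_integer_,
    verb = NA_character_, voice = NA_character_, polarity = NA_character_,
    stringsAsFactors = FALSE
  )
  streams <- vector("list", 72L)
  memorySets <- vector("list", 72L)

  iAT <- 0L; iWM <- 0L; iAR <- 0L
  for (b in 1:6) {
    idx <- which(trials$block == b)
    trials$repetitions[idx] <- sample(rep(7:10, 3))
    for (t in idx) {
      streams[[t]] <- generateStream(trials$repetitions[t],
                                     forbidImmediateRepeats)$order
      if (trials$task[t] == "AT") {
        iAT <- iAT + 1L
        trials$target_word_id[t] <- atTargets[iAT]
      } else if (trials$task[t] == "WM") {
        iWM <- iWM + 1L
        sz <- wmSizes[iWM]
        ms <- sample(0:7, sz)
        pp <- sample.int(sz, 1)
        trials$set_size[t] <- sz
        trials$probe_position[t] <- pp
        trials$target_word_id[t] <- wmCorrectAnswer(ms, pp)
        memorySets[[t]] <- ms
      } else {
        iAR <- iAR + 1L
        row <- tmpl[arRows[iAR], ]
        n1 <- arN1[iAR]; n2 <- arN2[iAR]
        s <- makeSentence(vocab[n1 + 1L], vocab[n2 + 1L], row$verb, row$voice,
                          row$polarity)
        ans <- solveSentence(s)
        trials$noun1_id[t] <- n1
        trials$noun2_id[t] <- n2
        trials$verb[t] <- row$verb
        trials$voice[t] <- row$voice
        trials$polarity[t] <- row$polarity
        trials$target_word_id[t] <- if (ans == vocab[n1 + 1L]) n1 else n2
      }
    }
  }
  new("BatterySchedule", trials = trials, streams = streams,
      memorySets = memorySets, vocabulary = vocab, seed = seed)
}

#' Reasoning sentence of an AR trial
#'
#' @param schedule a \linkS4class{BatterySchedule}.
#' @param trial trial number (must be an AR trial).
#' @return A Sentence.
#' @export
trialSentence <- function(schedule, trial) {
  tr <- schedule@trials[trial, ]
  if (tr$task != "AR") stop("trial ", trial, " is not an AR trial")
  v <- schedule@vocabulary
  makeSentence(v[tr$noun1_id + 1L], v[tr$noun2_id + 1L], tr$verb, tr$voice,
               tr$polarity)
}

#' Lay the schedule out in time and export stimulus events
#'
#' Places every stream word on the 500 ms stimulus grid, with a configurable
#' gap between consecutive streams. The gap stands in for the behavioural
#' question/answer and rest periods, whose exact durations do not affect the
#' ERP analysis.
#'
#' @param schedule a \linkS4class{BatterySchedule}.
#' @param gap_s seconds between the end of one stream and the next (default 1).
#' @param leadIn_s seconds before the first stimulus (default 1).
#' @return data.frame with columns onset_s, duration_s, word_id, trial_index,
#'   block_index, task, is_target.
#' @export
scheduleEvents <- function(schedule, gap_s = 1, leadIn_s = 1) {
  tr <- schedule@trials
  slot <- 0.5
  out <- vector("list", nrow(tr))
  cursor <- leadIn_s
  for (i in seq_len(nrow(tr))) {
    s <- schedule@streams[[i]]
    onsets <- cursor + (seq_along(s) - 1L) * slot
    out[[i]] <- data.frame(
      onset_s = onsets, duration_s = 0.4, word_id = s,
      trial_index = tr$trial[i], block_index = tr$block[i], task = tr$task[i],
      is_target = s == tr$target_word_id[i]
    )
    cursor <- cursor + length(s) * slot + gap_s
  }
  do.call(rbind, out)
}

#' Serialize a schedule to JSON
#'
#' @param schedule a \linkS4class{BatterySchedule}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSchedule <- function(schedule, path) {
  tr <- schedule@trials
  doc <- list(
    vocabulary = schedule@vocabulary,
    seed = schedule@seed,
    timing = timingModel(),
    trials = lapply(seq_len(nrow(tr)), function(i) {
      x <- as.list(tr[i, ])
      x <- x[!vapply(x, function(v) is.na(v) && !is.character(v), logical(1))]
      x <- x[!vapply(x, function(v) length(v) == 1 && is.na(v), logical(1))]
      x$stream <- schedule@streams[[i]]
      if (!is.null(schedule@memorySets[[i]]))
        x$memory_set <- schedule@memorySets[[i]]
      x
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a schedule back from JSON
#'
#' @param path file written by \code{\link{writeSchedule}}.
#' @return A \linkS4class{BatterySchedule}.
#' @export
readSchedule <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(doc$trials)
  get1 <- function(x, f, default) if (is.null(x[[f]])) default else x[[f]]
  trials <- do.call(rbind, lapply(doc$trials, function(x) data.frame(
    trial = x$trial, block = x$block, task = x$task,
    repetitions = x$repetitions, target_word_id = x$target_word_id,
    set_size = get1(x, "set_size", NA_integer_),
    probe_position = get1(x, "probe_position", NA_integer_),
    noun1_id = get1(x, "noun1_id", NA_integer_),
    noun2_id = get1(x, "noun2_id", NA_integer_),
    verb = get1(x, "verb", NA_character_),
    voice = get1(x, "voice", NA_character_),
    polarity = get1(x, "polarity", NA_character_),
    stringsAsFactors = FALSE
  )))
  trials$trial <- as.integer(trials$trial)
  trials$block <- as.integer(trials$block)
  trials$repetitions <- as.integer(trials$repetitions)
  trials$target_word_id <- as.integer(trials$target_word_id)
  trials$set_size <- as.integer(trials$set_size)
  trials$probe_position <- as.integer(trials$probe_position)
  trials$noun1_id <- as.integer(trials$noun1_id)
  trials$noun2_id <- as.integer(trials$noun2_id)
  streams <- lapply(doc$trials, function(x)
    as.integer(unlist(x$stream)))
  memorySets <- lapply(doc$trials, function(x)
    if (is.null(x$memory_set)) NULL else as.integer(unlist(x$memory_set)))
  new("BatterySchedule", trials = trials, streams = streams,
      memorySets = memorySets,
      vocabulary = as.character(unlist(doc$vocabulary)),
      seed = as.integer(doc$seed))
}

#' Write stimulus events as tab-separated text
#'
#' @param events data.frame from \code{\link{scheduleEvents}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEvents <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a stimulus event table
#'
#' Validates that onsets are sorted and unique.
#'
#' @param path TSV written by \code{\link{writeEvents}} (columns onset_s,
#'   word_id, trial_index, block_index, task at minimum).
#' @return data.frame of events sorted by onset.
#' @export
readEvents <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "word_id", "trial_index", "block_index", "task")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop("event file lacks required columns: ", paste(miss, collapse = ", "))
  if (is.unsorted(ev$onset_s, strictly = TRUE))
    stop("event onsets must be strictly increasing")
  ev
}
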