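# Protocol primitives: word vocabulary, oddball streams, reasoning sentences
# and their solver, probe answers, timing arithmetic.

#' Default word vocabulary
#'
#' Eight monosyllabic English nouns with distinct onset consonants, indexed by
#' word id 0--7. Any 8 unique labels may be substituted.
#'
#' @return Character vector of length 8, names "0".."7".
#' @export
#' @examples
#' wordVocabulary()
wordVocabulary <- function() {
  v <- c("cake", "dot", "fish", "pen", "lamp", "rose", "bird", "tree")
  names(v) <- as.character(0:7)
  v
}

#' Generate an oddball word stream
#'
#' Builds the timed word sequence of one trial: each of the 8 word ids occurs
#' exactly \code{repetitions} times, in a uniformly shuffled order, so the
#' stream length is 56, 64, 72 or 80 words. Stimuli are 400 ms long with a
#' 100 ms inter-stimulus interval (one 500 ms slot per word).
#'
#' @param repetitions integer in 7..10, occurrences of each word.
#' @param forbidImmediateRepeats logical; when TRUE the shuffle is redrawn
#'   (rejection sampling) until no word directly follows itself. Default FALSE.
#' @return list with components \code{order} (integer vector of word ids,
#'   0-based), \code{repetitions}, \code{stimulus_s} (0.4), \code{isi_s} (0.1).
#' @export
#' @examples
#' s <- generateStream(8)
#' table(s$order)   # every word id exactly 8 times
generateStream <- function(repetitions, forbidImmediateRepeats = FALSE) {
  if (length(repetitions) != 1L || !repetitions %in% 7:10)
    stop("repetitions must be a single integer in 7..10")
  repetitions <- as.integer(repetitions)
  order <- sample(rep(0:7, repetitions))
  if (forbidImmediateRepeats) {
    while (any(diff(order) == 0L)) order <- sample(rep(0:7, repetitions))
  }
  list(order = as.integer(order), repetitions = repetitions,
       stimulus_s = 0.4, isi_s = 0.1)
}

#' The eight reasoning sentence templates
#'
#' The full cross of verb (precede/follow) x voice (active/passive) x
#' polarity (positive/negative), with the answer slot each template resolves
#' to ("noun1" = first-mentioned noun, "noun2" = second-mentioned).
#'
#' @return data.frame with columns verb, voice, polarity, answer (8 rows).
#' @export
#' @examples
#' sentenceTemplates()
sentenceTemplates <- function() {
  g <- expand.grid(
    polarity = c("positive", "negative"),
    voice = c("active", "passive"),
    verb = c("precede", "follow"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("verb", "voice", "polarity")]
  flips <- (g$verb == "follow") + (g$voice == "passive") +
    (g$polarity == "negative")
  g$answer <- ifelse(flips %% 2L == 0L, "noun1", "noun2")
  g
}

#' Construct a reasoning sentence
#'
#' @param noun1,noun2 word labels; noun1 is mentioned first in the sentence.
#' @param verb "precede" or "follow".
#' @param voice "active" or "passive".
#' @param polarity "positive" or "negative".
#' @return list of class "Sentence".
#' @export
#' @examples
#' makeSentence("cake", "dot", "follow", "active", "negative")
makeSentence <- function(noun1, noun2, verb = c("precede", "follow"),
                         voice = c("active", "passive"),
                         polarity = c("positive", "negative")) {
  verb <- match.arg(verb); voice <- match.arg(voice)
  polarity <- match.arg(polarity)
  if (identical(noun1, noun2)) stop("the two nouns must differ")
  structure(list(noun1 = noun1, noun2 = noun2, verb = verb, voice = voice,
                 polarity = polarity),
            class = "Sentence")
}

#' Solve a reasoning sentence
#'
#' Returns the noun that occupies first position under the sentence's logical
#' reading. In the base form "noun1 precedes noun2" (active, positive) the
#' first-mentioned noun is first; switching the verb to "follow", the voice to
#' passive, or the polarity to negative each inverts the temporal relation, so
#' the answer is noun1 exactly when an even number of those inversions apply.
#'
#' @param s a Sentence (see \code{\link{makeSentence}}).
#' @return The word label in first position.
#' @export
#' @examples
#' solveSentence(makeSentence("cake", "dot", "precede", "active", "positive"))
solveSentence <- function(s) {
  if (!inherits(s, "Sentence")) stop("s must be a Sentence")
  # truth value of "noun1 comes first", toggled by each inversion
  noun1First <- TRUE
  if (s$verb == "follow") noun1First <- !noun1First
  if (s$voice == "passive") noun1First <- !noun1First
  if (s$polarity == "negative") noun1First <- !noun1First
  if (noun1First) s$noun1 else s$noun2
}

#' @export
format.Sentence <- function(x, ...) {
  v <- if (x$verb == "precede") c("precedes", "preceded") else
    c("follows", "followed")
  if (x$voice == "active") {
    core <- if (x$polarity == "positive") v[1] else paste("does not",
      sub("s$", "", v[1]))
  } else {
    core <- if (x$polarity == "positive") paste("is", v[2], "by") else
      paste("is not", v[2], "by")
  }
  paste(x$noun1, core, x$noun2)
}

#' @export
print.Sentence <- function(x, ...) {
  cat(format(x), "->", solveSentence(x), "\n")
  invisible(x)
}

#' Correct answer to a memory probe
#'
#' "What was the xth word": returns the element of the ordered memory set at
#' the (1-based) probe position.
#'
#' @param memorySet vector, the ordered memory set.
#' @param probePosition 1-based ordinal position.
#' @return The element at that position.
#' @export
wmCorrectAnswer <- function(memorySet, probePosition) {
  if (length(probePosition) != 1L || probePosition < 1 ||
      probePosition > length(memorySet) ||
      probePosition != as.integer(probePosition))
    stop("probePosition must be an integer in 1..length(memorySet)")
  memorySet[[as.integer(probePosition)]]
}

#' Protocol timing model
#'
#' Timing constants of the battery: 400 ms stimuli with 100 ms ISI (a 500 ms
#' slot), 8 stimuli per attended target (the target plus its seven
#' distractors, on average), a 10 s inter-trial rest, a 10 s WM retention
#' delay, and a 2 s post-response delay in AR.
#'
#' @return list of timing constants (seconds, except counts).
#' @export
timingModel <- function() {
  list(stimulus_s = 0.4, isi_s = 0.1, stimuliPerTarget = 8L,
       interTrialRest_s = 10, wmDelay_s = 10, arPostResponseDelay_s = 2)
}

#' Stream delivery time for a number of attended targets
#'
#' Each attended target occupies one 500 ms slot and is accompanied, on
#' average, by seven unattended stimuli of the same duration, so one target
#' costs 8 x 500 ms = 4 s of stream time. Question/rest time is excluded.
#'
#' @param nTargets number of attended targets (>= 0).
#' @param timing a \code{\link{timingModel}}.
#' @return Delivery time in seconds.
#' @export
#' @examples
#' protocolDuration(75)   # 300 s = 5 min
protocolDuration <- function(nTargets, timing = timingModel()) {
  if (any(nTargets < 0)) stop("nTargets must be non-negative")
  nTargets * timing$stimuliPerTarget * (timing$stimulus_s + timing$isi_s)
}

#' Chance level of a forced choice among words
#'
#' @param nWords number of response options (>= 1).
#' @return 1 / nWords.
#' @export
#' @examples
#' chanceLevel(8)  # 0.125
chanceLevel <- function(nWords) {
  if (any(nWords < 1)) stop("nWords must be at least 1")
  1 / nWords
}
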