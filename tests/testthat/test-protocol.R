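# Protocol construction: streams, sentences, probes, timing, schedule.

test_that("streams carry every word equally often at all admissible lengths", {
  set.seed(42)
  for (r in 7:10) {
    s <- generateStream(r)
    expect_length(s$order, 8 * r)
    expect_true(all(table(factor(s$order, 0:7)) == r))
  }
  expect_setequal(vapply(7:10, function(r) length(generateStream(r)$order),
                         numeric(1)), c(56, 64, 72, 80))
  expect_error(generateStream(6), "7..10")
  expect_error(generateStream(11), "7..10")
})

test_that("immediate-repeat suppression leaves counts intact", {
  set.seed(7)
  for (i in 1:5) {
    s <- generateStream(7, forbidImmediateRepeats = TRUE)
    expect_false(any(diff(s$order) == 0))
    expect_true(all(table(factor(s$order, 0:7)) == 7))
  }
})

test_that("the sentence solver reproduces the printed truth table", {
  # row-for-row reference: first position under each template, nouns
  # (cake, dot)
  ref <- list(
    list("precede", "active", "positive", "cake"),
    list("precede", "active", "negative", "dot"),
    list("precede", "passive", "positive", "dot"),
    list("precede", "passive", "negative", "cake"),
    list("follow", "active", "positive", "dot"),
    list("follow", "active", "negative", "cake"),
    list("follow", "passive", "positive", "cake"),
    list("follow", "passive", "negative", "dot")
  )
  for (row in ref) {
    s <- makeSentence("cake", "dot", row[[1]], row[[2]], row[[3]])
    expect_identical(solveSentence(s), row[[4]])
  }
})

test_that("solver toggles flip the answer and pairs of toggles restore it", {
  tm <- sentenceTemplates()
  expect_identical(nrow(tm), 8L)
  expect_identical(sum(tm$answer == "noun1"), 4L)
  flip <- list(
    verb = c(precede = "follow", follow = "precede"),
    voice = c(active = "passive", passive = "active"),
    polarity = c(positive = "negative", negative = "positive")
  )
  for (i in seq_len(8)) {
    s0 <- makeSentence("pen", "fish", tm$verb[i], tm$voice[i], tm$polarity[i])
    a0 <- solveSentence(s0)
    for (fld in names(flip)) {
      s1 <- s0
      s1[[fld]] <- unname(flip[[fld]][s0[[fld]]])
      expect_false(solveSentence(s1) == a0)
      for (fld2 in names(flip)) {
        s2 <- s1
        s2[[fld2]] <- unname(flip[[fld2]][s1[[fld2]]])
        if (fld2 == fld) next
        expect_false(solveSentence(s2) == solveSentence(s1))
        expect_identical(solveSentence(s2), a0)
      }
    }
    # swapping the noun assignment swaps the answer label
    sw <- makeSentence("fish", "pen", tm$verb[i], tm$voice[i], tm$polarity[i])
    expect_false(solveSentence(sw) == a0)
  }
})

test_that("memory probes return the xth word and reject bad positions", {
  expect_identical(wmCorrectAnswer(c("dot", "cake", "pen", "fish"), 1), "dot")
  v <- wordVocabulary()
  expect_identical(wmCorrectAnswer(v, 8), unname(v[8]))
  set.seed(1)
  for (i in 1:20) {
    sz <- sample(c(4, 6, 8), 1)
    ms <- sample(v, sz)
    x <- sample(sz, 1)
    expect_identical(wmCorrectAnswer(ms, x), unname(ms[x]))  # index oracle
  }
  expect_error(wmCorrectAnswer(v[1:4], 5), "probePosition")
  expect_error(wmCorrectAnswer(v[1:4], 0), "probePosition")
})

test_that("protocol timing arithmetic is exact", {
  expect_equal(protocolDuration(1), 4)
  expect_equal(protocolDuration(75), 300)
  expect_equal(protocolDuration(25), 100)
  expect_error(protocolDuration(-1), "non-negative")
  expect_equal(chanceLevel(8), 0.125)
  expect_equal(chanceLevel(1), 1)
  expect_equal(chanceLevel(2), 0.5)
  expect_error(chanceLevel(0), "at least 1")
})

test_that("schedules satisfy every count invariant across seeds", {
  for (seed in c(1, 17, 202)) {
    sched <- buildSchedule(seed = seed)
    expect_true(validObject(sched))
    tr <- scheduleTrials(sched)
    expect_identical(nrow(tr), 72L)
    expect_identical(as.vector(table(tr$task)), rep(24L, 3))
    at <- tr[tr$task == "AT", ]
    expect_true(all(table(factor(at$target_word_id, 0:7)) == 3))
    wm <- tr[tr$task == "WM", ]
    expect_true(all(table(wm$set_size) == 8))
    # per-block repetition balance: each r in 7..10 three times per block
    for (b in 1:6)
      expect_true(all(table(tr$repetitions[tr$block == b]) == 3))
    # WM probe positions within sets; AR answers match the solver
    expect_true(all(wm$probe_position <= wm$set_size))
    ar <- tr[tr$task == "AR", ]
    for (i in seq_len(nrow(ar))) {
      s <- trialSentence(sched, ar$trial[i])
      expect_identical(vocabulary(sched)[ar$target_word_id[i] + 1],
                       solveSentence(s))
    }
  }
  expect_error(buildSchedule(vocab = letters[1:5]), "8 unique")
})

test_that("schedule and event serialization round-trips", {
  sched <- buildSchedule(seed = 5)
  tmp <- tempfile(fileext = ".json")
  writeSchedule(sched, tmp)
  back <- readSchedule(tmp)
  expect_identical(scheduleTrials(back), scheduleTrials(sched))
  expect_identical(trialStreams(back), trialStreams(sched))
  expect_identical(vocabulary(back), vocabulary(sched))

  ev <- scheduleEvents(sched)
  expect_identical(nrow(ev), sum(lengths(trialStreams(sched))))
  # onsets advance on the 500 ms stimulus grid within a trial
  one <- ev[ev$trial_index == 3, ]
  expect_equal(diff(one$onset_s), rep(0.5, nrow(one) - 1))
  tsv <- tempfile(fileext = ".tsv")
  writeEvents(ev, tsv)
  back2 <- readEvents(tsv)
  expect_equal(back2$onset_s, ev$onset_s)
  expect_identical(as.integer(back2$word_id), ev$word_id)

  bad <- ev
  bad$onset_s[2] <- bad$onset_s[1]
  writeEvents(bad, tsv)
  expect_error(readEvents(tsv), "increasing")
  writeEvents(ev[, setdiff(names(ev), "task")], tsv)
  expect_error(readEvents(tsv), "required columns")
})
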