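# Independent oracles and small fixture builders used across the suite.

# wrap a channels x time x epochs array as an EpochSet
makeEpochSet <- function(arr, fs = 256, times = NULL, info = NULL,
                         channels = NULL) {
  d <- dim(arr)
  if (is.null(times)) times <- (seq_len(d[2]) - 1) / fs
  if (is.null(channels))
    channels <- if (d[1] == 16) batteryMontage() else
      paste0("CH", seq_len(d[1]))
  if (is.null(info))
    info <- data.frame(trial = rep(1L, d[3]), word_id = 0L)
  new("EpochSet", data = arr, times = times, channels = channels,
      samplingRate = fs, info = info, baselined = TRUE)
}

# white-noise epoch array with an optional effect (scaled by a posterior-ish
# weight profile) added to the middle third of samples of the first nEffect
# epochs
nullEpochArray <- function(nEpochs, nCh = 16, nT = 308, sd = 1,
                           effect = 0, nEffect = 0) {
  arr <- array(rnorm(nCh * nT * nEpochs, sd = sd), c(nCh, nT, nEpochs))
  if (nEffect > 0 && effect != 0) {
    topo <- if (nCh == 16) unname(defaultTopography()) else
      seq(1, 0.3, length.out = nCh)
    k <- numeric(nT)
    mid <- seq.int(ceiling(nT / 3), floor(2 * nT / 3))
    k[mid] <- effect
    add <- outer(topo, k)
    for (e in seq_len(nEffect)) arr[, , e] <- arr[, , e] + add
  }
  arr
}

# pointwise two-sample pooled-variance t via stats::t.test (oracle)
oracleT2 <- function(a, b) {
  unname(stats::t.test(a, b, var.equal = TRUE)$statistic)
}

# flood-fill clustering oracle: recursive connected components over a
# supra-threshold mask, connectivity = same channel adjacent samples or
# adjacent channels (per adjacency matrix) at the same sample
oracleClusters <- function(tmap, threshold, adj, startCol = 1) {
  nCh <- nrow(tmap); nT <- ncol(tmap)
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- matrix(FALSE, nCh, nT)
    mask[, startCol:nT] <- if (sgn > 0)
      tmap[, startCol:nT, drop = FALSE] > threshold
    else tmap[, startCol:nT, drop = FALSE] < -threshold
    seen <- matrix(FALSE, nCh, nT)
    for (c0 in seq_len(nT)) for (r0 in seq_len(nCh)) {
      if (!mask[r0, c0] || seen[r0, c0]) next
      stack <- list(c(r0, c0))
      members <- NULL
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        r <- p[1]; cc <- p[2]
        if (seen[r, cc]) next
        seen[r, cc] <- TRUE
        members <- rbind(members, p)
        nbrs <- list()
        if (cc > 1) nbrs <- c(nbrs, list(c(r, cc - 1)))
        if (cc < nT) nbrs <- c(nbrs, list(c(r, cc + 1)))
        for (r2 in which(adj[r, ])) nbrs <- c(nbrs, list(c(r2, cc)))
        for (q in nbrs)
          if (mask[q[1], q[2]] && !seen[q[1], q[2]])
            stack <- c(stack, list(q))
      }
      out[[length(out) + 1]] <- list(
        members = members,
        mass = sum(tmap[members])
      )
    }
  }
  out
}

# exhaustive single-level CMPT oracle on a tiny instance: enumerate all
# partitions, max |cluster mass| each, p = proportion >= observed
oracleExactCMPT <- function(arr, nA, threshold, adj, startCol = 1) {
  d <- dim(arr)
  n <- d[3]
  tmapFor <- function(idxA) {
    tm <- matrix(0, d[1], d[2])
    for (ch in seq_len(d[1])) for (s in seq_len(d[2]))
      tm[ch, s] <- oracleT2(arr[ch, s, idxA], arr[ch, s, -idxA])
    tm
  }
  maxMass <- function(idxA) {
    cl <- oracleClusters(tmapFor(idxA), threshold, adj, startCol)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }
  combs <- utils::combn(n, nA)
  stats <- apply(combs, 2, maxMass)
  obs <- maxMass(seq_len(nA))
  list(p = mean(stats >= obs - 1e-12), obs = obs, null = stats)
}

# small agent/session fixture at a given noise level and accuracy
miniSession <- function(seed, noiseSD = 5, trials = 1:4,
                        cfg = simConfig(noiseSD = noiseSD)) {
  sched <- buildSchedule(seed = seed)
  set.seed(seed)
  agent <- simulateAgent(sched, cfg)
  rec <- bandpassFilter(synthesizeRecording(sched, agent, cfg,
                                            trials = trials))
  epochs <- baselineCorrect(epochRecording(rec))
  list(schedule = sched, agent = agent, epochs = epochs)
}
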