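# Preprocessing: zero-phase band-pass filtering, epoching on the
# floor(onset*fs) grid, baseline correction, and epoch-level artifact
# rejection (kurtosis, extreme values, improbability, linear trend).

#' Zero-phase band-pass filter a recording
#'
#' 4th-order Butterworth high-pass and low-pass sections applied with zero
#' phase: the data are filtered in the frequency domain by the cascade's
#' squared magnitude response (the forward-backward/filtfilt equivalent), so
#' the passband gain is ~1 and P300 latency is preserved.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param low high-pass edge, Hz (default 0.5).
#' @param high low-pass edge, Hz (default 10).
#' @param order Butterworth order of each section (default 4).
#' @return The filtered \linkS4class{EEGRecording}.
#' @export
bandpassFilter <- function(recording, low = 0.5, high = 10, order = 4) {
  fs <- recording@samplingRate
  if (!(low > 0 && high > low)) stop("need 0 < low < high")
  if (fs <= 2 * high) stop("sampling rate must exceed twice the upper edge")
  x <- recording@data
  n <- ncol(x)
  nfft <- stats::nextn(n, c(2, 3, 5))        # composite length: fast FFT
  f <- (seq_len(nfft) - 1) / nfft * fs
  f <- pmin(f, fs - f)                       # two-sided frequency axis
  # |H|^2 of forward-backward filtering = squared magnitude of each section
  gain <- 1 / (1 + (f / high)^(2 * order)) * # low-pass, applied twice
    ifelse(f > 0, 1 / (1 + (low / f)^(2 * order)), 0)  # high-pass
  for (ch in seq_len(nrow(x))) {
    y <- stats::fft(c(x[ch, ], numeric(nfft - n))) * gain
    x[ch, ] <- Re(stats::fft(y, inverse = TRUE))[seq_len(n)] / nfft
  }
  initialize(recording, data = x)
}

#' Cut a recording into fixed-window epochs
#'
#' Epochs span -200 to 1000 ms relative to each event onset. Window sample
#' indices are \code{floor(onset_s * fs) + (round(-0.2 * fs) : round(1.0 *
#' fs))} (both ends included; 308 samples at 256 Hz). Events whose window
#' falls partly outside the recording are dropped with a warning.
#'
#' @param recording an \linkS4class{EEGRecording}.
#' @param events optional event data.frame (default: the recording's own
#'   events). Must carry \code{sample} (0-based onset sample) or
#'   \code{onset_s}, plus any metadata columns to propagate.
#' @param window_s length-2 numeric, window in seconds (default
#'   \code{c(-0.2, 1.0)}).
#' @return An \linkS4class{EpochSet}; metadata rows are the retained events.
#' @export
epochRecording <- function(recording, events = NULL,
                           window_s = c(-0.2, 1.0)) {
  fs <- recording@samplingRate
  if (is.null(events)) events <- recording@events
  if (!nrow(events)) stop("no events to epoch")
  if (is.null(events$sample)) {
    if (is.null(events$onset_s)) stop("events need 'sample' or 'onset_s'")
    events$sample <- floor(events$onset_s * fs)
  }
  rel <- round(window_s[1] * fs):round(window_s[2] * fs)
  nSamp <- ncol(recording@data)
  # 0-based absolute indices of each epoch's samples
  start <- events$sample + rel[1]
  end <- events$sample + rel[length(rel)]
  ok <- start >= 0 & end < nSamp
  if (!any(ok)) stop("no event window lies fully inside the recording")
  if (any(!ok))
    warning(sum(!ok), " event(s) too close to the recording edge; dropped")
  events <- events[ok, , drop = FALSE]
  nCh <- nrow(recording@data)
  nT <- length(rel)
  arr <- array(0, dim = c(nCh, nT, nrow(events)))
  for (k in seq_len(nrow(events))) {
    idx <- (events$sample[k] + rel) + 1L   # to 1-based R indexing
    arr[, , k] <- recording@data[, idx]
  }
  new("EpochSet", data = arr, times = rel / fs,
      channels = recording@channels, samplingRate = fs,
      info = as.data.frame(events, row.names = seq_len(nrow(events))),
      baselined = FALSE)
}

#' Baseline-correct an epoch set
#'
#' Subtracts, per channel and epoch, the mean voltage over the prestimulus
#' window (samples with t < 0; -200 to 0 ms).
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @return The corrected \linkS4class{EpochSet} (idempotent).
#' @export
baselineCorrect <- function(epochs) {
  bl <- which(epochs@times < 0)
  if (!length(bl) || any(epochs@times[bl] < min(epochs@times) - 1e-9))
    stop("baseline window must lie inside the epoch window")
  arr <- epochs@data
  d <- dim(arr)
  # per-channel/epoch baseline means (channels x epochs)
  base <- colMeans(aperm(arr[, bl, , drop = FALSE], c(2, 1, 3)))
  arr <- matrix(arr, d[1] * d[2], d[3]) - base[rep(seq_len(d[1]), d[2]), ]
  dim(arr) <- d
  initialize(epochs, data = arr, baselined = TRUE)
}

#' Default artifact-rejection criteria
#'
#' Epoch-level analogues of the component statistics used for artifact
#' screening: kurtosis |z| > 5 across epochs, absolute amplitude > 100
#' microvolts, joint-improbability |z| > 5, and a linear trend with R^2 >
#' 0.5 together with a fitted range > 75 microvolts.
#'
#' @param maxAbs_uV absolute-amplitude threshold (microvolts).
#' @param kurtosisZ kurtosis z-score threshold.
#' @param improbabilityZ improbability z-score threshold.
#' @param trendR2 R-squared threshold of the linear trend.
#' @param trendRange_uV fitted trend range threshold (microvolts).
#' @return list of thresholds.
#' @export
artifactCriteria <- function(maxAbs_uV = 100, kurtosisZ = 5,
                             improbabilityZ = 5, trendR2 = 0.5,
                             trendRange_uV = 75) {
  list(maxAbs_uV = maxAbs_uV, kurtosisZ = kurtosisZ,
       improbabilityZ = improbabilityZ, trendR2 = trendR2,
       trendRange_uV = trendRange_uV)
}

# excess-kurtosis of a vector
.kurtosis <- function(x) {
  m <- mean(x); s2 <- mean((x - m)^2)
  if (s2 == 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

#' Reject artifact-contaminated epochs
#'
#' Applies the \code{\link{artifactCriteria}} per epoch (worst channel
#' governs) and removes epochs failing any criterion. Rejection happens
#' before condition binning, so all conditions face identical criteria.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param criteria list from \code{\link{artifactCriteria}}.
#' @return list with \code{epochs} (the cleaned \linkS4class{EpochSet}) and
#'   \code{report} (per-criterion rejection counts plus indices).
#' @export
rejectArtifacts <- function(epochs, criteria = artifactCriteria()) {
  arr <- epochs@data
  d <- dim(arr)
  nEp <- d[3]
  nCh <- d[1]
  maxAbs <- apply(abs(arr), 3, max)
  failAmp <- maxAbs > criteria$maxAbs_uV

  # kurtosis z across epochs, per channel; epoch fails if any channel |z| > thr
  ku <- apply(arr, c(1, 3), .kurtosis)           # channels x epochs
  kz <- t(scale(t(ku)))                          # z across epochs per channel
  kz[is.na(kz)] <- 0
  failKurt <- apply(abs(kz) > criteria$kurtosisZ, 2, any)

  # improbability: mean negative log-likelihood of the epoch's samples under
  # a per-channel Gaussian fit to all epochs, z-scored across epochs
  nll <- matrix(0, nCh, nEp)
  for (ch in seq_len(nCh)) {
    x <- arr[ch, , ]
    m <- mean(x); s <- stats::sd(as.numeric(x))
    if (s == 0) next
    nll[ch, ] <- colMeans((x - m)^2) / (2 * s^2)
  }
  nz <- t(scale(t(nll)))
  nz[is.na(nz)] <- 0
  failImp <- apply(abs(nz) > criteria$improbabilityZ, 2, any)

  # linear trend: per channel slope fit; fail if R^2 and fitted range exceed
  t0 <- epochs@times
  tc <- t0 - mean(t0)
  sst_t <- sum(tc^2)
  failTrend <- logical(nEp)
  for (k in seq_len(nEp)) {
    X <- arr[, , k]
    slopes <- (X %*% tc) / sst_t
    fitted_range <- abs(slopes) * diff(range(t0))
    ssr <- slopes^2 * sst_t
    sst <- rowSums((X - rowMeans(X))^2)
    r2 <- ifelse(sst > 0, ssr / sst, 0)
    failTrend[k] <- any(r2 > criteria$trendR2 &
                          fitted_range > criteria$trendRange_uV)
  }

  bad <- failAmp | failKurt | failImp | failTrend
  keep <- which(!bad)
  if (!length(keep)) stop("all epochs rejected")
  report <- list(
    n_input = nEp, n_retained = length(keep), n_rejected = sum(bad),
    by_criterion = c(amplitude = sum(failAmp), kurtosis = sum(failKurt),
                     improbability = sum(failImp), trend = sum(failTrend)),
    rejected_epochs = which(bad)
  )
  out <- initialize(epochs, data = arr[, , keep, drop = FALSE],
                    info = epochs@info[keep, , drop = FALSE])
  list(epochs = out, report = report)
}

#' Average epochs into an ERP
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param which optional integer/logical index of epochs to average
#'   (default: all).
#' @return list of class "ERP": \code{mean} (channels x time matrix),
#'   \code{n} (epochs contributing), \code{times}, \code{channels},
#'   \code{condition}.
#' @param condition optional condition label.
#' @export
erpAverage <- function(epochs, which = NULL, condition = NA_character_) {
  arr <- epochs@data
  if (!is.null(which)) arr <- arr[, , which, drop = FALSE]
  if (!dim(arr)[3]) stop("no epochs to average")
  structure(list(mean = apply(arr, c(1, 2), mean), n = dim(arr)[3],
                 times = epochs@times, channels = epochs@channels,
                 condition = condition),
            class = "ERP")
}
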