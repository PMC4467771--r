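# Monte Carlo analysis of statistical sensitivity: mean single-level CMPT
# p-value as a function of the number of attended targets (n, multiples of
# 25; 7n unattended) and of simulated accuracy (attended/unattended swaps).

#' Monte Carlo configuration
#'
#' @param nGrid target counts (multiples of 25, increasing).
#' @param repsPerN repetitions per (accuracy, n) cell (default 100).
#' @param accuracies simulated accuracy levels (default 0.3..1.0 by 0.1).
#' @param alpha significance level (default 0.05).
#' @param unattendedRatio unattended epochs per attended one (default 7).
#' @param nPerm permutations per CMPT repetition (default 500).
#' @return list of class "MonteCarloConfig".
#' @export
mcConfig <- function(nGrid = seq(25, 600, by = 25), repsPerN = 100,
                     accuracies = seq(0.3, 1.0, by = 0.1), alpha = 0.05,
                     unattendedRatio = 7, nPerm = 500) {
  if (is.unsorted(nGrid, strictly = TRUE) || any(nGrid %% 25 != 0))
    stop("nGrid must be increasing multiples of 25")
  if (repsPerN < 1) stop("repsPerN must be >= 1")
  if (any(accuracies <= 0 | accuracies > 1))
    stop("accuracies must lie in (0, 1]")
  structure(list(nGrid = as.integer(nGrid), repsPerN = as.integer(repsPerN),
                 accuracies = accuracies, alpha = alpha,
                 unattendedRatio = unattendedRatio, nPerm = nPerm),
            class = "MonteCarloConfig")
}

#' Subsample attended and unattended epoch pools
#'
#' Draws n attended and ratio * n unattended epoch indices uniformly,
#' without replacement while the pool suffices, with replacement (flagged)
#' otherwise.
#'
#' @param attendedPool,unattendedPool integer index vectors.
#' @param n number of attended epochs to draw.
#' @param ratio unattended per attended (default 7).
#' @return list: \code{A}, \code{B} (index vectors), \code{replacedA},
#'   \code{replacedB} (logical: sampled with replacement).
#' @export
subsampleEpochs <- function(attendedPool, unattendedPool, n, ratio = 7) {
  if (!length(attendedPool) || !length(unattendedPool))
    stop("epoch pools must be nonempty")
  nB <- ratio * n
  repA <- n > length(attendedPool)
  repB <- nB > length(unattendedPool)
  list(A = sample(attendedPool, n, replace = repA),
       B = sample(unattendedPool, nB, replace = repB),
       replacedA = repA, replacedB = repB)
}

#' Swap attended and unattended epochs to simulate a given accuracy
#'
#' Exchanges k = round((1 - accuracy) * |A|) uniformly chosen members of A
#' with k uniformly chosen members of B (round half to even), so that a
#' fraction ~accuracy of the "attended" condition actually carries attended
#' epochs. Group sizes are preserved.
#'
#' @param A,B index vectors of the two conditions.
#' @param accuracy simulated accuracy in [0, 1].
#' @return list with the swapped \code{A} and \code{B}.
#' @export
swapForAccuracy <- function(A, B, accuracy) {
  if (accuracy < 0 || accuracy > 1) stop("accuracy must lie in [0, 1]")
  k <- round((1 - accuracy) * length(A))
  if (k == 0) return(list(A = A, B = B))
  ia <- sample(seq_along(A), k)
  ib <- sample(seq_along(B), k)
  tmp <- A[ia]
  A[ia] <- B[ib]
  B[ib] <- tmp
  list(A = A, B = B)
}

#' Monte Carlo sensitivity curves for one participant
#'
#' For each accuracy level and each n in the grid: repeatedly (1) subsample
#' n attended and 7n unattended epochs from the participant's
#' behavior-defined pools, (2) swap a fraction 1 - accuracy of the attended
#' selection with unattended epochs, (3) run the single-level CMPT, then
#' average the repetitions' p-values arithmetically.
#'
#' @param epochs baseline-corrected \linkS4class{EpochSet}.
#' @param attendedPool,unattendedPool epoch index pools (from
#'   \code{\link{binAttendedByBehavior}}).
#' @param cfg a \code{\link{mcConfig}}.
#' @param adjacency electrode adjacency matrix.
#' @return data.frame: accuracy, n, mean_p, sd_p, n_failed.
#' @export
mcCurve <- function(epochs, attendedPool, unattendedPool, cfg = mcConfig(),
                    adjacency = buildAdjacency()) {
  out <- list()
  for (acc in cfg$accuracies) {
    for (n in cfg$nGrid) {
      ps <- rep(NA_real_, cfg$repsPerN)
      for (r in seq_len(cfg$repsPerN)) {
        sel <- subsampleEpochs(attendedPool, unattendedPool, n,
                               cfg$unattendedRatio)
        sw <- swapForAccuracy(sel$A, sel$B, acc)
        res <- tryCatch(
          cmptSingle(epochs, sw$A, sw$B, adjacency, nPerm = cfg$nPerm,
                     alpha = cfg$alpha),
          error = function(e) NULL)
        if (!is.null(res)) ps[r] <- pValue(res)
      }
      ok <- !is.na(ps)
      if (any(!ok))
        warning(sum(!ok), " repetition(s) failed at accuracy ", acc,
                ", n = ", n)
      out[[length(out) + 1L]] <- data.frame(
        accuracy = acc, n = n, mean_p = mean(ps[ok]),
        sd_p = stats::sd(ps[ok]), n_failed = sum(!ok))
    }
  }
  do.call(rbind, out)
}

#' Smallest target count reaching significance
#'
#' First grid n whose mean p-value falls below alpha; NA ("unattained") when
#' none does.
#'
#' @param curve data.frame with \code{n} and \code{mean_p} (one accuracy
#'   level).
#' @param alpha significance level (default 0.05).
#' @return The n value, or NA if unattained.
#' @export
requiredTargets <- function(curve, alpha = 0.05) {
  curve <- curve[order(curve$n), ]
  hit <- which(curve$mean_p < alpha)
  if (!length(hit)) NA_integer_ else as.integer(curve$n[hit[1]])
}

#' Required targets per accuracy level
#'
#' @param curves \code{\link{mcCurve}} output covering several accuracies.
#' @param alpha significance level.
#' @return data.frame: accuracy, required_n (NA when unattained).
#' @export
requiredTargetsByAccuracy <- function(curves, alpha = 0.05) {
  accs <- sort(unique(curves$accuracy))
  data.frame(accuracy = accs,
             required_n = vapply(accs, function(a)
               requiredTargets(curves[curves$accuracy == a, ], alpha),
               integer(1)))
}
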