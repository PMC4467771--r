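# Spatiotemporal cluster-mass permutation test (CMPT), Maris-Oostenveld
# formulation: threshold a pointwise t map at the two-sided point-level
# critical t, group supra-threshold points into spatiotemporally connected
# clusters, score each by its summed t (mass), and compare the largest
# |mass| against a permutation null of the maximum |mass|.

#' 2D montage coordinates of the 16 electrodes
#'
#' Projected scalp-disc positions (x = right, y = anterior) in the
#' topographic-plot convention: head disc of radius 0.5, one 10% arc step =
#' 0.1. Approximate standard 10-10 positions.
#'
#' @return 16 x 2 matrix with electrode rownames.
#' @export
montageCoordinates <- function() {
  co <- rbind(
    FC3 = c(-0.20, 0.10), C3 = c(-0.20, 0.00), CP3 = c(-0.20, -0.10),
    FCZ = c(0.00, 0.10), CZ = c(0.00, 0.00), CPZ = c(0.00, -0.10),
    FC4 = c(0.20, 0.10), C4 = c(0.20, 0.00), CP4 = c(0.20, -0.10),
    T7 = c(-0.40, 0.00), T8 = c(0.40, 0.00),
    PZ = c(0.00, -0.20), POZ = c(0.00, -0.30), OZ = c(0.00, -0.40),
    P7 = 0.4 * c(-cospi(0.2), -sinpi(0.2)),
    P8 = 0.4 * c(cospi(0.2), -sinpi(0.2))
  )
  colnames(co) <- c("x", "y")
  co[batteryMontage(), ]
}

#' Build an electrode adjacency graph
#'
#' Electrodes closer than \code{threshold} (normalized head-radius units) are
#' neighbors. The graph is symmetric and irreflexive; a configuration with an
#' isolated electrode is rejected.
#'
#' @param coords electrode coordinate matrix (rownames = labels).
#' @param threshold neighbor distance threshold (default 0.4).
#' @return Logical adjacency matrix.
#' @export
#' @examples
#' adj <- buildAdjacency()
#' which(adj["CZ", ])   # includes FCZ and CPZ
buildAdjacency <- function(coords = montageCoordinates(), threshold = 0.4) {
  d <- as.matrix(stats::dist(coords))
  adj <- d < threshold
  diag(adj) <- FALSE
  if (any(rowSums(adj) == 0))
    stop("isolated electrode(s): ",
         paste(rownames(coords)[rowSums(adj) == 0], collapse = ", "))
  adj
}

# adjacency matrix -> 0-based CSR-style index/pointer pair for the C++ core
.adjFlat <- function(adj) {
  n <- nrow(adj)
  idx <- integer(0)
  ptr <- integer(n + 1)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ]) - 1L
    idx <- c(idx, nb)
    ptr[i + 1] <- length(idx)
  }
  list(idx = as.integer(idx), ptr = as.integer(ptr))
}

#' Cluster-forming threshold
#'
#' The t value whose two-sided point-level p equals \code{clusterAlpha} at
#' the given degrees of freedom.
#'
#' @param df degrees of freedom of the pointwise test.
#' @param clusterAlpha two-sided point-level alpha (default 0.05).
#' @return Positive t threshold.
#' @export
clusterThreshold <- function(df, clusterAlpha = 0.05) {
  stats::qt(1 - clusterAlpha / 2, df)
}

#' Pointwise paired t map (group level)
#'
#' Paired t statistic per (electrode, time) over participant-wise A - B
#' difference ERPs; df = n - 1.
#'
#' @param erpA,erpB numeric arrays, channels x time x participants, the two
#'   condition ERPs in matched participant order.
#' @return channels x time t matrix.
#' @export
statMapGroup <- function(erpA, erpB) {
  if (!identical(dim(erpA), dim(erpB)))
    stop("condition ERP arrays must be paired (identical dimensions)")
  d <- dim(erpA)
  if (d[3] < 2) stop("need ERPs from at least 2 participants")
  D <- matrix(erpA - erpB, d[1] * d[2], d[3])
  matrix(cppTmapPaired(D), d[1], d[2])
}

#' Pointwise two-sample t map (single-participant level)
#'
#' Pooled-variance two-sample t per (electrode, time); unbalanced groups
#' allowed (typically ~7 unattended epochs per attended one).
#'
#' @param epochsA,epochsB numeric arrays, channels x time x epochs.
#' @return channels x time t matrix.
#' @export
statMapSingle <- function(epochsA, epochsB) {
  dA <- dim(epochsA); dB <- dim(epochsB)
  if (!identical(dA[1:2], dB[1:2]))
    stop("epoch arrays must share channels and time axis")
  if (dA[3] < 2 || dB[3] < 2) stop("each group needs at least 2 epochs")
  nPts <- dA[1] * dA[2]
  X <- cbind(matrix(epochsA, nPts, dA[3]), matrix(epochsB, nPts, dB[3]))
  isA <- rep(c(TRUE, FALSE), c(dA[3], dB[3]))
  matrix(cppTmapTwo(X, isA), dA[1], dA[2])
}

#' Form spatiotemporal clusters from a t map
#'
#' Points with t > threshold (and, separately, t < -threshold) are grouped
#' into connected components: same electrode at adjacent samples, or
#' neighboring electrodes at the same sample. Clustering is restricted to
#' times >= \code{clusterStart_s} (post-stimulus window).
#'
#' @param tmap channels x time t matrix.
#' @param threshold positive cluster-forming t threshold.
#' @param adjacency logical adjacency matrix (\code{\link{buildAdjacency}}).
#' @param times time axis in seconds (default: 0-based sample index /
#'   arbitrary; only used for the window restriction and cluster extents).
#' @param clusterStart_s first time included in clustering (default 0;
#'   \code{-Inf} to use the whole map).
#' @return list: \code{clusters} data.frame (id, mass, sign, size, t_start,
#'   t_end) sorted by decreasing |mass|, and \code{membership} integer
#'   matrix (0 outside clusters).
#' @export
formClusters <- function(tmap, threshold, adjacency = buildAdjacency(),
                         times = NULL, clusterStart_s = 0) {
  if (threshold <= 0) stop("threshold must be positive")
  nCh <- nrow(tmap); nT <- ncol(tmap)
  if (nrow(adjacency) != nCh) stop("adjacency does not match channel count")
  if (is.null(times)) times <- seq_len(nT) - 1
  startCol <- if (is.finite(clusterStart_s))
    match(TRUE, times >= clusterStart_s) else 1L
  if (is.na(startCol)) stop("clusterStart_s is beyond the time axis")
  fl <- .adjFlat(adjacency)
  res <- cppClusters(as.numeric(tmap), nCh, nT, fl$idx, fl$ptr, threshold,
                     startCol - 1L)
  membership <- matrix(res$membership, nCh, nT)
  masses <- res$masses
  if (!length(masses)) {
    return(list(clusters = data.frame(id = integer(0), mass = numeric(0),
                                      sign = integer(0), size = integer(0),
                                      t_start = numeric(0),
                                      t_end = numeric(0)),
                membership = membership))
  }
  cl <- data.frame(id = seq_along(masses), mass = masses,
                   sign = ifelse(masses > 0, 1L, -1L),
                   size = as.integer(tabulate(membership[membership > 0],
                                              length(masses))),
                   t_start = NA_real_, t_end = NA_real_)
  for (i in cl$id) {
    cols <- which(apply(membership == i, 2, any))
    cl$t_start[i] <- times[min(cols)]
    cl$t_end[i] <- times[max(cols)]
  }
  # sort by |mass|, ties broken by earliest onset
  cl <- cl[order(-abs(cl$mass), cl$t_start), ]
  rownames(cl) <- NULL
  list(clusters = cl, membership = membership)
}

# shared tail: given observed clusters + null max-mass distribution, build the
# CMPTResult
.finishCMPT <- function(tmap, times, channels, fc, nullMax, nPerm, exact,
                        threshold, level, alpha) {
  cl <- fc$clusters
  if (nrow(cl)) {
    denom <- if (exact) length(nullMax) else length(nullMax) + 1
    cl$p <- vapply(cl$mass, function(m) {
      hits <- sum(nullMax >= abs(m) - 1e-12)
      if (exact) hits / denom else (hits + 1) / denom
    }, numeric(1))
    p <- cl$p[1]
  } else {
    p <- 1
    cl$p <- numeric(0)
  }
  sel <- matrix(FALSE, nrow(tmap), ncol(tmap))
  if (nrow(cl) && p <= alpha)
    sel <- fc$membership == cl$id[1]
  new("CMPTResult", tmap = tmap, times = times, channels = channels,
      clusters = cl, membership = fc$membership, p = p,
      selectedRegion = sel, threshold = threshold,
      nullMax = as.numeric(nullMax), nPerm = if (exact) 0 else nPerm,
      level = level, alpha = alpha)
}

#' Single-participant cluster-mass permutation test
#'
#' Compares two pooled epoch samples (e.g. attended vs unattended, or
#' correct vs incorrect) with a pointwise pooled-variance t map, cluster
#' formation at the two-sided point-level critical t, and a permutation null
#' built from random re-partitions of the pooled epochs into groups of the
#' original sizes. p = (number of null max |mass| >= observed + 1) /
#' (nPerm + 1); with \code{exact = TRUE} all distinct partitions are
#' enumerated instead and p is the exact proportion.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param positive,negative epoch indices of the two conditions (e.g. from
#'   \code{\link{binSession}}).
#' @param adjacency electrode adjacency matrix.
#' @param nPerm number of permutations (default 500).
#' @param clusterAlpha point-level two-sided alpha forming the threshold.
#' @param alpha cluster-level significance level for region selection.
#' @param clusterStart_s first time entering clustering (default 0 s).
#' @param exact enumerate all partitions (only for <= 12 pooled epochs).
#' @return A \linkS4class{CMPTResult}.
#' @export
cmptSingle <- function(epochs, positive, negative,
                       adjacency = buildAdjacency(), nPerm = 500,
                       clusterAlpha = 0.05, alpha = 0.05,
                       clusterStart_s = 0, exact = FALSE) {
  if (length(positive) < 2 || length(negative) < 2)
    stop("each condition needs at least 2 epochs")
  d <- dim(epochs@data)
  nPts <- d[1] * d[2]
  nA <- length(positive); nB <- length(negative)
  X <- epochs@data[, , c(positive, negative), drop = FALSE]
  dim(X) <- c(nPts, nA + nB)
  isA <- rep(c(TRUE, FALSE), c(nA, nB))
  tmap <- matrix(cppTmapTwo(X, isA), d[1], d[2])
  thr <- clusterThreshold(nA + nB - 2, clusterAlpha)
  fc <- formClusters(tmap, thr, adjacency, epochs@times, clusterStart_s)
  fl <- .adjFlat(adjacency)
  startCol <- if (is.finite(clusterStart_s))
    match(TRUE, epochs@times >= clusterStart_s) - 1L else 0L
  if (exact) {
    n <- nA + nB
    if (choose(n, nA) > 10000)
      stop("exact enumeration limited to small instances")
    combs <- utils::combn(n, nA)
    nullMax <- apply(combs, 2, function(ix) {
      cppMaxMassTwo(X, seq_len(n) %in% ix, d[1], d[2], fl$idx, fl$ptr, thr,
                    startCol)
    })
  } else {
    if (nPerm < 100) stop("nPerm must be at least 100")
    if (choose(nA + nB, nA) < 1 / alpha)
      warning("fewer distinct partitions than 1/alpha; p-values are coarse")
    nullMax <- cppNullMaxSingle(X, nA, d[1], d[2], fl$idx, fl$ptr, thr,
                                nPerm, startCol)
  }
  .finishCMPT(tmap, epochs@times, epochs@channels, fc, nullMax, nPerm,
              exact, thr, "single", alpha)
}

#' Group-level cluster-mass permutation test
#'
#' Paired test over participants: pointwise paired t on the participant-wise
#' condition-A minus condition-B difference ERPs (df = n - 1), cluster
#' formation, and a permutation null from random sign flips of the
#' difference ERPs.
#'
#' @param erpA,erpB channels x time x participants arrays of condition ERPs
#'   in matched order.
#' @param times time axis (seconds) of the ERP samples.
#' @param channels channel labels.
#' @inheritParams cmptSingle
#' @param nPerm number of sign-flip permutations (default 1000).
#' @return A \linkS4class{CMPTResult}.
#' @export
cmptGroup <- function(erpA, erpB, times, channels = batteryMontage(),
                      adjacency = buildAdjacency(), nPerm = 1000,
                      clusterAlpha = 0.05, alpha = 0.05,
                      clusterStart_s = 0) {
  if (!identical(dim(erpA), dim(erpB)))
    stop("condition ERP arrays must be paired (identical dimensions)")
  d <- dim(erpA)
  n <- d[3]
  if (n < 2) stop("need at least 2 participants")
  if (2^n < 1 / alpha)
    warning("fewer distinct sign flips than 1/alpha; p-values are coarse")
  tmap <- statMapGroup(erpA, erpB)
  thr <- clusterThreshold(n - 1, clusterAlpha)
  fc <- formClusters(tmap, thr, adjacency, times, clusterStart_s)
  fl <- .adjFlat(adjacency)
  startCol <- if (is.finite(clusterStart_s))
    match(TRUE, times >= clusterStart_s) - 1L else 0L
  D <- matrix(erpA - erpB, d[1] * d[2], n)
  nullMax <- cppNullMaxGroup(D, d[1], d[2], fl$idx, fl$ptr, thr, nPerm,
                             startCol)
  .finishCMPT(tmap, times, channels, fc, nullMax, nPerm, FALSE, thr,
              "group", alpha)
}
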