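# Cluster-mass permutation test: adjacency, stat maps, clustering,
# permutation and exhaustive p-values.

test_that("adjacency is symmetric, irreflexive, and matches the montage", {
  adj <- buildAdjacency()
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_true(all(rowSums(adj) >= 1))
  cz <- adj["CZ", ]
  expect_true(all(c("FCZ", "CPZ") %in% names(which(cz))))
  expect_error(buildAdjacency(threshold = 0.01), "isolated")
})

test_that("group stat map equals a paired t.test oracle pointwise", {
  set.seed(70)
  n <- 14
  erpA <- array(rnorm(4 * 6 * n, mean = 0.3), c(4, 6, n))
  erpB <- array(rnorm(4 * 6 * n), c(4, 6, n))
  tm <- statMapGroup(erpA, erpB)
  for (pt in list(c(1, 1), c(3, 5), c(4, 6))) {
    oracle <- stats::t.test(erpA[pt[1], pt[2], ], erpB[pt[1], pt[2], ],
                            paired = TRUE)$statistic
    expect_equal(tm[pt[1], pt[2]], unname(oracle), tolerance = 1e-12)
  }
  # A = B: all-zero map; a large constant shift: every t positive
  expect_equal(max(abs(statMapGroup(erpA, erpA))), 0)
  expect_true(all(statMapGroup(erpA + 5, erpB) > 0))
  expect_true(all(statMapGroup(erpA + 1, erpA) > 0))  # degenerate variance
  expect_error(statMapGroup(erpA, erpB[, , 1:7]), "paired")
})

test_that("single-level stat map equals a two-sample t.test oracle", {
  set.seed(71)
  a <- array(rnorm(3 * 5 * 12, mean = 1), c(3, 5, 12))
  b <- array(rnorm(3 * 5 * 84), c(3, 5, 84))
  tm <- statMapSingle(a, b)
  for (pt in list(c(1, 1), c(2, 4), c(3, 5))) {
    expect_equal(tm[pt[1], pt[2]],
                 oracleT2(a[pt[1], pt[2], ], b[pt[1], pt[2], ]),
                 tolerance = 1e-12)
  }
  # identical distributions: few large |t|
  set.seed(72)
  null <- statMapSingle(array(rnorm(16 * 50 * 30), c(16, 50, 30)),
                        array(rnorm(16 * 50 * 30), c(16, 50, 30)))
  expect_lt(mean(abs(null) > 2), 0.15)
})

test_that("cluster formation matches a flood-fill oracle on hand-built maps", {
  adj2 <- matrix(c(FALSE, TRUE, TRUE, FALSE), 2)  # two connected electrodes
  rownames(adj2) <- colnames(adj2) <- c("E1", "E2")
  tmap <- rbind(c(0, 3, 3, 0, 4),
                c(0, 0, 3, 0, -4))
  fc <- formClusters(tmap, 2, adj2, times = 0:4, clusterStart_s = -Inf)
  oc <- oracleClusters(tmap, 2, adj2)
  expect_identical(nrow(fc$clusters), length(oc))
  expect_equal(sort(fc$clusters$mass),
               sort(vapply(oc, `[[`, 0, "mass")))
  # the bridge at (E1,3)-(E2,3) joins the first three supra points
  expect_identical(fc$clusters$size[fc$clusters$mass == 9], 3L)
  # sub-threshold map: no clusters; singleton: one cluster of its own t
  expect_identical(nrow(formClusters(tmap * 0.1, 2, adj2,
                                     clusterStart_s = -Inf)$clusters), 0L)
  single <- matrix(c(0, 0, 5, 0), 1)
  adj1 <- matrix(FALSE, 1, 1)
  fcs <- formClusters(single, 2, adj1, clusterStart_s = -Inf)
  expect_identical(nrow(fcs$clusters), 1L)
  expect_equal(fcs$clusters$mass, 5)
  expect_identical(fcs$clusters$size, 1L)
})

test_that("random maps cluster identically to the oracle", {
  set.seed(73)
  adj <- buildAdjacency()
  for (i in 1:5) {
    tmap <- matrix(rnorm(16 * 12, sd = 1.5), 16, 12)
    fc <- formClusters(tmap, 1.5, adj, times = 0:11, clusterStart_s = 0)
    oc <- oracleClusters(tmap, 1.5, adj)
    expect_identical(nrow(fc$clusters), length(oc))
    expect_equal(sort(round(fc$clusters$mass, 9)),
                 sort(round(vapply(oc, `[[`, 0, "mass"), 9)))
  }
})

test_that("exhaustive enumeration matches the brute-force oracle", {
  set.seed(74)
  arr <- nullEpochArray(6, nCh = 3, nT = 8, effect = 2.5, nEffect = 3)
  arr <- arr[1:3, , ]   # keep it tiny: 3 channels
  adj3 <- matrix(TRUE, 3, 3); diag(adj3) <- FALSE
  rownames(adj3) <- colnames(adj3) <- paste0("CH", 1:3)
  ep <- makeEpochSet(arr, channels = paste0("CH", 1:3), times = 0:7)
  res <- cmptSingle(ep, 1:3, 4:6, adjacency = adj3, exact = TRUE,
                    clusterStart_s = -Inf)
  thr <- clusterThreshold(4)
  oracle <- oracleExactCMPT(arr, 3, thr, adj3)
  expect_length(res@nullMax, 20)      # all C(6,3) partitions
  expect_equal(pValue(res), oracle$p, tolerance = 1e-12)
})

test_that("permutation p saturates at its floor for a huge injected effect", {
  set.seed(75)
  arr <- nullEpochArray(40, nT = 60, sd = 0.01, effect = 5, nEffect = 5)
  ep <- makeEpochSet(arr, times = (0:59) / 256)
  res <- cmptSingle(ep, 1:5, 6:40, nPerm = 300)
  expect_equal(pValue(res), 1 / 301, tolerance = 1e-12)
  expect_true(any(selectedRegion(res)))
  expect_identical(clusterTable(res)$sign[1], 1L)
})

test_that("p-values are invariant to channel reordering and A/B swap", {
  set.seed(76)
  arr <- nullEpochArray(24, nT = 40, effect = 3, nEffect = 12)
  ep <- makeEpochSet(arr, times = (0:39) / 256)
  adj <- buildAdjacency()
  set.seed(100); r1 <- cmptSingle(ep, 1:12, 13:24, adj, nPerm = 200)
  # permute channels consistently
  perm <- sample(16)
  arrP <- arr[perm, , ]
  epP <- makeEpochSet(arrP, channels = batteryMontage()[perm],
                      times = (0:39) / 256)
  adjP <- adj[perm, perm]
  set.seed(100); r2 <- cmptSingle(epP, 1:12, 13:24, adjP, nPerm = 200)
  expect_equal(pValue(r1), pValue(r2), tolerance = 1e-12)
  expect_equal(abs(clusterTable(r1)$mass), abs(clusterTable(r2)$mass),
               tolerance = 1e-9)
  # swapping conditions flips cluster signs, preserves |mass| and p
  set.seed(100); r3 <- cmptSingle(ep, 13:24, 1:12, adj, nPerm = 200)
  expect_equal(pValue(r1), pValue(r3), tolerance = 1e-12)
  expect_equal(clusterTable(r1)$mass, -clusterTable(r3)$mass,
               tolerance = 1e-9)
})

test_that("stronger effects never raise the mean p on matched noise", {
  set.seed(77)
  meanP <- function(effect) {
    ps <- vapply(1:4, function(i) {
      arr <- nullEpochArray(48, nT = 60, effect = effect, nEffect = 6)
      ep <- makeEpochSet(arr, times = (0:59) / 256)
      pValue(cmptSingle(ep, 1:6, 7:48, nPerm = 200))
    }, numeric(1))
    mean(ps)
  }
  expect_lte(meanP(2.5), meanP(0.5) + 0.05)
})

test_that("group-level permutation detects a consistent condition shift", {
  set.seed(78)
  n <- 14
  base <- array(rnorm(16 * 60 * n, sd = 1), c(16, 60, n))
  effect <- nullEpochArray(n, nT = 60, sd = 0, effect = 1.2, nEffect = n)
  erpA <- base + effect
  erpB <- array(rnorm(16 * 60 * n, sd = 1), c(16, 60, n))
  res <- cmptGroup(erpA, erpB, times = (0:59) / 256, nPerm = 500)
  expect_lt(pValue(res), 0.01)
  expect_true(any(selectedRegion(res)))
  # null data: non-significant most of the time (spot check)
  res0 <- cmptGroup(array(rnorm(16 * 60 * n), c(16, 60, n)),
                    array(rnorm(16 * 60 * n), c(16, 60, n)),
                    times = (0:59) / 256, nPerm = 300)
  expect_gt(pValue(res0), 1 / 301)
})
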