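test_that("two well-separated dense disks give exactly two clusters and no noise", {
  t <- two_disk_table()
  cs <- extractClusters(t, clusterParams(40, 10))
  lab <- clusterLabels(cs)
  expect_equal(nClusters(cs), 2L)
  expect_equal(sum(lab == -1L), 0L)
  expect_equal(as.vector(table(lab)), c(100L, 100L))

  ## epsilon-connected-component oracle: at eps = 50 nm the two disks form
  ## two components of >= 40 points each, and the HDBSCAN partition must
  ## coincide with those components
  xy <- locCoords(t)
  adj <- as.matrix(dist(xy)) <= 50
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  big <- as.integer(names(which(table(comp) >= 40)))
  expect_length(big, 2L)
  for (b in big) {
    members <- which(comp == b)
    expect_equal(length(unique(lab[members])), 1L)
    expect_gte(lab[members][1], 0L)
  }
})

test_that("tables smaller than the minimum cluster size yield only noise", {
  set.seed(21)
  t <- localizationTable(runif(30, 0, 200), runif(30, 0, 200),
                         adcount = rep(2e4, 30))
  cs <- extractClusters(t, clusterParams(40, 10))
  expect_equal(nClusters(cs), 0L)
  expect_true(all(clusterLabels(cs) == -1L))
})

test_that("sparse uniform background yields no clusters in almost all runs", {
  ## 1 per um^2 over 100 um^2: ~100 points spread over 10 x 10 um
  zero <- vapply(1:100, function(s) {
    set.seed(s)
    n <- rpois(1, 100)
    t <- localizationTable(runif(n, 0, 1e4), runif(n, 0, 1e4),
                           adcount = rep(2e4, n))
    nClusters(extractClusters(t, clusterParams(40, 10))) == 0L
  }, logical(1))
  expect_gte(mean(zero), 0.95)
})

test_that("cluster labels form a partition and ids are ordered by size", {
  sim <- simulateScene(paperLikeScene(nClusters = 6, seed = 13))
  cs <- extractClusters(sim$locs, clusterParams(40, 10))
  lab <- clusterLabels(cs)
  expect_length(lab, nLocs(sim$locs))
  k <- nClusters(cs)
  expect_setequal(unique(lab[lab >= 0]), seq_len(k) - 1L)
  sizes <- as.vector(table(factor(lab[lab >= 0], levels = seq_len(k) - 1L)))
  expect_true(all(diff(sizes) <= 0))
  expect_true(all(sizes >= 40))
})

test_that("clustering matches the reference Python implementation on clean blobs", {
  set.seed(5)
  xy <- rbind(cbind(runif(120, 0, 600), runif(120, 0, 600)),
              cbind(runif(80, 5000, 5500), runif(80, 5000, 5500)),
              cbind(runif(150, 0, 700), runif(150, 8000, 8700)))
  t <- localizationTable(xy[, 1], xy[, 2], adcount = rep(2e4, nrow(xy)))
  lab <- clusterLabels(extractClusters(t, clusterParams(40, 10)))

  csv <- tempfile(fileext = ".csv")
  out <- tempfile(fileext = ".txt")
  write.csv(data.frame(x = xy[, 1], y = xy[, 2]), csv, row.names = FALSE)
  script <- sprintf(paste0(
    "import pandas as pd\n",
    "from sklearn.cluster import HDBSCAN\n",
    "xy = pd.read_csv(%s).values\n",
    "h = HDBSCAN(min_cluster_size=40, min_samples=10, copy=True).fit(xy)\n",
    "open(%s, 'w').write('\\n'.join(str(int(l)) for l in h.labels_))\n"),
    deparse(csv), deparse(out))
  status <- system2("python", c("-c", shQuote(script)))
  expect_equal(status, 0L)
  ref <- as.integer(readLines(out, warn = FALSE))
  ## same partition up to label permutation, same noise set
  expect_equal(lab == -1L, ref == -1L)
  tab <- table(lab[lab >= 0], ref[ref >= 0])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("the sweep grid enumerates the printed parameter ranges", {
  spec <- sweepGridSpec()
  expect_identical(spec$mcs, as.integer(seq(10, 100, 10)))
  expect_identical(spec$ms,
                   as.integer(c(2, 5, 10, 15, 20, 25, seq(30, 100, 10))))
  expect_equal(length(spec$mcs) * length(spec$ms), 140L)
})

test_that("sweep on a constructed two-cluster image behaves as expected", {
  t <- two_disk_table()
  g <- runSweep(list(t))
  expect_equal(dim(g@cells), c(10L, 14L))
  expect_true(all(g@cells %in% c(0, 1, 2)))
  expect_equal(g@cells[match(40, g@mcsValues), match(10, g@msValues)], 2)

  ## median over five copies of the same image equals the single-image grid
  g5 <- runSweep(rep(list(t), 5))
  expect_identical(g5@cells, g@cells)

  ## raising min cluster size never increases the cluster count
  for (j in seq_along(g@msValues))
    expect_true(all(diff(g@cells[, j]) <= 0))

  expect_error(runSweep(list()), "empty")
})

test_that("stable-parameter selection implements the plateau rule", {
  spec <- sweepGridSpec()
  ## constant grid: the anchored default lies in the single plateau
  gconst <- new("SweepGrid", mcsValues = spec$mcs, msValues = spec$ms,
                cells = matrix(7, 10, 14), nImages = 1L)
  p <- selectStableParams(gconst)
  expect_equal(p@minClusterSize, 40L)
  expect_equal(p@minSamples, 10L)

  ## a single 3x3 constant block in an otherwise chaotic grid
  set.seed(8)
  chaotic <- matrix(sample(c(1, 5, 20, 60, 95), 140, replace = TRUE), 10, 14)
  chaotic[4:6, 6:8] <- 11
  gblock <- new("SweepGrid", mcsValues = spec$mcs, msValues = spec$ms,
                cells = chaotic, nImages = 1L)
  pb <- selectStableParams(gblock)
  expect_true(pb@minClusterSize %in% spec$mcs[4:6])
  expect_true(pb@minSamples %in% spec$ms[6:8])

  ## zero tolerance with no equal neighbours: widened with a warning
  gnone <- new("SweepGrid", mcsValues = spec$mcs, msValues = spec$ms,
               cells = matrix(seq(1, by = 1, length.out = 140) *
                                rep(c(1, 2), 70), 10, 14),
               nImages = 1L)
  expect_warning(selectStableParams(gnone, relTol = 0), "widened")
})
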