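test_that("single-triangle alpha shapes follow the squared-circumradius threshold", {
  tri <- rbind(c(0, 0), c(100, 0), c(0, 100))  # circumradius^2 = 5000
  expect_equal(shapeArea(alphaShapeArea(tri, 10000)), 5000)
  expect_equal(shapeArea(alphaShapeArea(tri, 4000)), 0)
  ## threshold is inclusive at equality
  expect_equal(shapeArea(alphaShapeArea(tri, 5000)), 5000)
  ## boundary of the retained triangle is its three edges
  sh <- alphaShapeArea(tri, 10000)
  expect_equal(nrow(sh@boundary), 3L)
})

test_that("degenerate point sets yield flagged zero-area shapes", {
  two <- rbind(c(0, 0), c(50, 50))
  expect_true(alphaShapeArea(two, 1e4)@degenerate)
  coll <- cbind(seq(0, 100, 10), seq(0, 200, 20))
  sh <- alphaShapeArea(coll, 1e4)
  expect_true(sh@degenerate)
  expect_equal(sh@area, 0)
})

test_that("areas match an independent Delaunay engine with explicit circumradii", {
  set.seed(30)
  for (rep in 1:10) {
    n <- sample(20:300, 1)
    pts <- cbind(runif(n, 0, 500), runif(n, 0, 500))
    for (alpha in c(900, 2500, 10000, 40000)) {
      expect_equal(shapeArea(alphaShapeArea(pts, alpha)),
                   alpha_area_oracle(pts, alpha), tolerance = 1e-12)
    }
  }
})

test_that("large alpha recovers the convex hull and area is monotone in alpha", {
  set.seed(31)
  for (rep in 1:10) {
    pts <- disk_points(sample(30:200, 1), c(500, 500), 300)
    areas <- vapply(alphaGrid(),
                    function(a) shapeArea(alphaShapeArea(pts, a)), numeric(1))
    expect_true(all(diff(areas) >= 0))
    ## at alpha beyond every circumradius the shape fills the hull
    expect_equal(shapeArea(alphaShapeArea(pts, 1e9)), convex_hull_area(pts),
                 tolerance = 1e-9)
  }
})

test_that("areas are scale-equivariant", {
  set.seed(32)
  pts <- cbind(runif(80, 0, 400), runif(80, 0, 400))
  a1 <- shapeArea(alphaShapeArea(pts, 8000))
  for (s in c(0.5, 3, 10)) {
    a2 <- shapeArea(alphaShapeArea(pts * s, 8000 * s^2))
    expect_equal(a2, a1 * s^2, tolerance = 1e-9)
  }
})

test_that("the alpha sweep covers the printed grid and summarises medians", {
  expect_length(alphaGrid(), 40L)
  expect_equal(min(alphaGrid()), 25)
  expect_equal(max(alphaGrid()), 40000)

  ## a single equilateral triangle: median area is a step function
  side <- 100
  tri <- rbind(c(0, 0), c(side, 0), c(side / 2, side * sqrt(3) / 2))
  r2 <- (side / sqrt(3))^2
  sw <- areaVsAlphaSweep(list(tri))
  tri_area <- sqrt(3) / 4 * side^2 / 1e6
  expect_equal(sw@medianArea, ifelse(alphaGrid() >= r2, tri_area, 0))

  ## fifty synthetic disk clusters: median nondecreasing over all 40 alphas
  set.seed(33)
  clusters <- lapply(1:50, function(i) disk_points(80, c(0, 0), 220))
  sw2 <- areaVsAlphaSweep(clusters)
  expect_true(all(diff(sw2@medianArea) >= -1e-15))
  expect_true(all(sw2@q25 <= sw2@medianArea + 1e-15))
  expect_true(all(sw2@q75 >= sw2@medianArea - 1e-15))
  expect_true(is.na(sw2@pctIncrease[1]))

  expect_error(areaVsAlphaSweep(list(rbind(c(0, 0), c(1, 1)))), "degenerate")
})

test_that("alpha selection picks the first sub-threshold step of the median curve", {
  mk <- function(med) {
    pct <- c(NA, ifelse(med[-length(med)] > 0,
                        100 * diff(med) / med[-length(med)], NA))
    new("AlphaSweepResult", alphas = alphaGrid(), medianArea = med,
        q25 = med, q75 = med, pctIncrease = pct, nClusters = 1L)
  }
  ## construct a median curve with step increases 12, 8, 4.9, 3, ... percent
  med <- numeric(40)
  med[1] <- 0.05
  incr <- c(12, 8, 4.9, rep(3, 36)) / 100
  for (i in 2:40) med[i] <- med[i - 1] * (1 + incr[i - 1])
  r <- mk(med)
  expect_equal(selectAlpha(r), alphaGrid()[4])  # the 4.9% step

  ## strictly-below comparison: an exactly-5% step does not trigger
  r5 <- new("AlphaSweepResult", alphas = alphaGrid(),
            medianArea = rep(0.1, 40), q25 = rep(0.1, 40), q75 = rep(0.1, 40),
            pctIncrease = c(NA, rep(5, 39)), nClusters = 1L)
  expect_error(selectAlpha(r5), "widen")
  expect_equal(selectAlpha(r5, thresholdPct = 5.01), alphaGrid()[2])

  ## the first grid alpha is never selectable even on a flat curve
  flat <- rep(0.1, 40)
  expect_equal(selectAlpha(mk(flat)), alphaGrid()[2])

  ## all steps >= 5%: no selection
  med_up <- 0.05 * 1.08^(0:39)
  expect_error(selectAlpha(mk(med_up)), "widen")
})

test_that("rule agrees with an independent re-implementation on simulated clusters", {
  sim <- simulateScene(paperLikeScene(nClusters = 50, seed = 9))
  cs <- extractClusters(sim$locs, clusterParams(40, 10))
  pts <- clusterPoints(sim$locs, cs)
  sw <- areaVsAlphaSweep(pts)
  picked <- selectAlpha(sw)
  ## oracle: first alpha (beyond the first) whose median-step increase is
  ## strictly below 5%, recomputed from the raw per-cluster areas
  med <- vapply(alphaGrid(), function(a)
    median(vapply(pts, function(p) shapeArea(alphaShapeArea(p, a)), numeric(1))),
    numeric(1))
  pct <- 100 * diff(med) / med[-40]
  oracle <- alphaGrid()[-1][which(pct < 5)[1]]
  expect_equal(picked, oracle)
})
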