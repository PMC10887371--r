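test_that("CSV localization tables round-trip bit-exactly", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("x_nm,y_nm,frame,adcount",
               "100.5,200.25,0,15000",
               "300,400,10,13000",
               "55.125,66.5,14999,20000"), path)
  t <- readLocalizations(path)
  expect_s4_class(t, "LocalizationTable")
  expect_identical(t@x, c(100.5, 300, 55.125))
  expect_identical(t@y, c(200.25, 400, 66.5))
  expect_identical(t@frame, c(0L, 10L, 14999L))
  expect_identical(t@adcount, c(15000, 13000, 20000))

  set.seed(1)
  n <- 1000
  big <- localizationTable(runif(n, 0, 5e4), runif(n, 0, 5e4),
                           frame = sample(0:14999, n, replace = TRUE),
                           adcount = runif(n, 0, 3e4))
  for (dialect in c("csv", "rapidstorm_txt")) {
    p <- tempfile()
    writeLocalizations(big, p, dialect = dialect)
    back <- readLocalizations(p, dialect = dialect)
    expect_identical(back@x, big@x, info = dialect)
    expect_identical(back@y, big@y, info = dialect)
    expect_identical(back@frame, big@frame, info = dialect)
    expect_identical(back@adcount, big@adcount, info = dialect)
  }
})

test_that("reader rejects malformed input with informative errors", {
  p <- tempfile()
  writeLines(c("x_nm,y_nm,frame", "1,2,0"), p)
  expect_error(readLocalizations(p), "adcount")

  p2 <- tempfile()
  file.create(p2)
  expect_error(readLocalizations(p2), "empty")

  ## malformed rows are dropped and counted, good rows survive
  p3 <- tempfile()
  writeLines(c("x_nm,y_nm,frame,adcount", "1,2,0,15000",
               "not,a,row", "3,4,oops,16000", "5,6,2,17000"), p3)
  expect_message(t <- readLocalizations(p3), "2 malformed")
  expect_equal(length(t), 2L)
  expect_identical(attr(t, "rejected"), 2L)

  ## rapidSTORM dialect: comment header with synonym column names
  p4 <- tempfile()
  writeLines(c("# Position-0-0 Position-1-0 ImageNumber-0-0 Amplitude-0-0",
               "12.5 40 3 15000", "100 200 7 9000"), p4)
  t4 <- readLocalizations(p4)
  expect_equal(t4@x, c(12.5, 100))
  expect_equal(t4@adcount, c(15000, 9000))
})

test_that("amplitude filter is strictly 'over' the threshold and idempotent", {
  t <- localizationTable(1:3, 1:3, adcount = c(11999, 12000, 12001))
  kept <- filterByAdcount(t)
  expect_equal(length(kept), 1L)
  expect_equal(kept@adcount, 12001)

  ## threshold 0 keeps every positive-amplitude row
  t2 <- localizationTable(1:5, 1:5, adcount = c(1, 2, 3, 4, 5))
  expect_identical(as.data.frame(filterByAdcount(t2, 0)), as.data.frame(t2))

  ## large random table agrees with direct enumeration, and the filter is
  ## idempotent
  set.seed(2)
  n <- 10000
  t3 <- localizationTable(runif(n), runif(n), adcount = runif(n, 0, 24000))
  f1 <- filterByAdcount(t3)
  expect_equal(length(f1), sum(t3@adcount > 12000))
  expect_identical(as.data.frame(filterByAdcount(f1)), as.data.frame(f1))
})

test_that("ROI clipping keeps interior and boundary points", {
  roi <- roiPolygon(rbind(c(0, 0), c(1000, 0), c(1000, 1000), c(0, 1000)))
  t <- localizationTable(c(500, 1500, 1000, 0), c(500, 500, 500, 0),
                         adcount = rep(2e4, 4))
  kept <- clipToRoi(t, roi)
  ## interior point and the two boundary points survive; outside point dropped
  expect_equal(kept@x, c(500, 1000, 0))

  ## clipping to a polygon covering the bounding box is the identity
  big <- roiPolygon(rbind(c(-1, -1), c(2000, -1), c(2000, 2000), c(-1, 2000)))
  expect_identical(as.data.frame(clipToRoi(t, big)), as.data.frame(t))

  expect_error(roiPolygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "area")
})

test_that("ROI clipping agrees with a ray-casting oracle on random convex polygons", {
  set.seed(3)
  ## random convex 7-gon: points on an ellipse at sorted angles
  th <- sort(runif(7, 0, 2 * pi))
  vx <- 2500 + 1800 * cos(th)
  vy <- 2500 + 1200 * sin(th)
  roi <- roiPolygon(cbind(vx, vy))
  n <- 5000
  t <- localizationTable(runif(n, 0, 5000), runif(n, 0, 5000),
                         adcount = rep(2e4, n))
  kept <- clipToRoi(t, roi)
  oracle <- ray_cast_inside(t@x, t@y, vx, vy)
  expect_equal(length(kept), sum(oracle))
  expect_equal(kept@x, t@x[oracle])
  expect_equal(kept@y, t@y[oracle])
})

test_that("binned rendering uses half-open 10 nm bins and conserves counts", {
  t1 <- localizationTable(5, 5, adcount = 2e4)
  img <- renderBinned(t1)
  expect_equal(dim(img@counts), c(1L, 1L))
  expect_equal(img@counts[1, 1], 1L)

  ## a localization at exactly (10, 10) falls in the second bin of each axis
  t2 <- localizationTable(10, 10, adcount = 2e4)
  img2 <- renderBinned(t2, dim = c(3L, 3L))
  expect_equal(img2@counts[2, 2], 1L)
  expect_equal(sum(img2@counts), 1L)
  expect_equal(img2@counts[1, 1], 0L)

  set.seed(4)
  n <- 2500
  t3 <- localizationTable(runif(n, 0, 990), runif(n, 0, 490),
                          adcount = rep(2e4, n))
  expect_equal(sum(renderBinned(t3)@counts), n)

  expect_error(renderBinned(localizationTable(numeric(), numeric())), "empty")
})

test_that("pixel/nm conversion is exact multiplication and invertible", {
  expect_equal(pxToNm(c(2, 3), 127), c(254, 381))
  expect_equal(pxToNm(c(0, 0), 130), c(0, 0))
  set.seed(5)
  coords <- matrix(runif(200, 0, 512), ncol = 2)
  for (px in c(127, 130, 10))
    expect_equal(nmToPx(pxToNm(coords, px), px), coords, tolerance = 1e-12)
})

test_that("ROI CSV round trip and pixel-unit conversion work", {
  rois <- list(
    roiPolygon(rbind(c(0, 0), c(500, 0), c(250, 400)), label = "b1"),
    roiPolygon(rbind(c(10, 10), c(60, 10), c(60, 80), c(10, 80)),
               label = "b2"))
  p <- tempfile(fileext = ".csv")
  writeRois(rois, p)
  back <- readRois(p)
  expect_named(back, c("b1", "b2"))
  expect_equal(roiVertices(back$b1), roiVertices(rois[[1]]))
  expect_equal(roiArea(back$b2), roiArea(rois[[2]]))

  ## annotation-pixel vertices are scaled by the 10 nm reconstruction pixel
  ppx <- tempfile(fileext = ".csv")
  writeLines(c("label,vertex_index,x,y,units",
               "r1,1,0,0,px", "r1,2,100,0,px", "r1,3,100,100,px",
               "r1,4,0,100,px"), ppx)
  r <- readRois(ppx)$r1
  expect_equal(max(roiVertices(r)), 1000)
  expect_equal(roiArea(r), 1)  # (100 px * 10 nm)^2 = 1 um^2
})
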