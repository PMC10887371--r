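test_that("cell inclusion is boundary-inclusive at -50 mV and 4 MOhm", {
  expect_true(includeCell(ephysCell("a", vm = -65, rm = 6)))
  expect_false(includeCell(ephysCell("b", vm = -45, rm = 6)))
  expect_true(includeCell(ephysCell("c", vm = -50, rm = 4)))
  expect_false(includeCell(ephysCell("d", vm = -65, rm = 3.9)))
  expect_error(includeCell(ephysCell("e", vm = NA_real_, rm = 5)), "missing")
})

test_that("voltage scaling is the exact linear-IV factor and invertible", {
  expect_equal(scaleMepsc(-1.0), -0.75)
  expect_equal(scaleMepsc(-1.0, holdM = -80, target = -80), -1.0)
  amps <- c(-0.4, -1.2, -0.85)
  back <- scaleMepsc(scaleMepsc(amps, -80, -60), -60, -80)
  expect_equal(back, amps, tolerance = 1e-12)
  ## composing scalings multiplies factors
  expect_equal(scaleMepsc(scaleMepsc(-1, -80, -60), -60, -40),
               scaleMepsc(-1, -80, -40), tolerance = 1e-12)
  expect_error(scaleMepsc(-1, holdM = 0), "reversal")
})

test_that("quantal content divides mean evoked by scaled mean mini amplitude", {
  cell <- ephysCell("q1", vm = -65, rm = 6,
                    mepscAmps = rep(-1.0, 25), eepscAmps = rep(-75, 10))
  r <- quantalContent(cell)
  expect_equal(r@quantalContent, 100)
  expect_equal(r@meanMepscScaled, -0.75)

  ## evoked equal to the scaled mini mean gives quantal content one
  cell1 <- ephysCell("q2", vm = -60, rm = 5,
                     mepscAmps = c(-1, -1), eepscAmps = c(-0.75, -0.75))
  expect_equal(quantalContent(cell1)@quantalContent, 1)

  ## sign convention invariance: flipping all amplitudes leaves it unchanged
  flip <- ephysCell("q3", vm = -65, rm = 6,
                    mepscAmps = rep(1.0, 25), eepscAmps = rep(75, 10))
  expect_equal(quantalContent(flip)@quantalContent, 100)

  expect_error(quantalContent(ephysCell("q4", vm = -65, rm = 6,
                                        mepscAmps = numeric(),
                                        eepscAmps = -1)), "at least one")
  expect_error(quantalContent(ephysCell("q5", vm = -65, rm = 6,
                                        mepscAmps = c(-1, 1) * 0,
                                        eepscAmps = -1)), "zero")
})

test_that("paired-pulse ratio averages traces before taking the ratio", {
  expect_equal(pairedPulseRatio(cbind(rep(-60, 5), rep(-60, 5))), 1)
  expect_equal(pairedPulseRatio(cbind(rep(-60, 5), rep(-90, 5))), 1.5)
  set.seed(50)
  pairs <- cbind(-60 + rnorm(8, 0, 5), -70 + rnorm(8, 0, 5))
  expect_identical(pairedPulseRatio(pairs),
                   mean(pairs[, 2]) / mean(pairs[, 1]))
  expect_error(pairedPulseRatio(cbind(numeric(), numeric())), "no paired")
  expect_error(pairedPulseRatio(cbind(c(-1, 1), c(1, 1))), "zero")
})

test_that("simulated cells return the generator's quantal content", {
  ## noise-free: exact recovery in every cell
  cells0 <- simulateCells(5, trueQc = 50, cv = 0, seed = 7)
  for (c in cells0) {
    expect_equal(quantalContent(c)@quantalContent, 50, tolerance = 1e-12)
    expect_equal(quantalContent(c)@ppr, 1, tolerance = 1e-12)
  }

  ## determinism
  a <- simulateCells(3, seed = 9)
  b <- simulateCells(3, seed = 9)
  expect_identical(lapply(a, function(c) c@mepscAmps),
                   lapply(b, function(c) c@mepscAmps))
  expect_identical(lapply(a, function(c) c@eepscAmps),
                   lapply(b, function(c) c@eepscAmps))

  ## 200 cells at 10% CV: population estimator bias below 2%
  cells <- simulateCells(200, trueQc = 50, cv = 0.1, seed = 11)
  qcs <- vapply(cells, function(c) quantalContent(c)@quantalContent,
                numeric(1))
  expect_lt(abs(mean(qcs) - 50) / 50, 0.02)
  expect_true(all(vapply(cells, includeCell, logical(1))))
})

test_that("cells and events round-trip through the CSV interface", {
  cells <- simulateCells(3, trueQc = 40, cv = 0.05, seed = 13)
  cp <- tempfile(fileext = ".csv"); ep <- tempfile(fileext = ".csv")
  cdf <- data.frame(cell_id = vapply(cells, function(c) c@cellId, ""),
                    vm_mV = vapply(cells, function(c) c@vm, 0),
                    rm_MOhm = vapply(cells, function(c) c@rm, 0))
  edf <- do.call(rbind, lapply(cells, function(c) rbind(
    data.frame(cell_id = c@cellId, kind = "mepsc",
               amplitude_nA = c@mepscAmps, pair_index = NA),
    data.frame(cell_id = c@cellId, kind = "eepsc",
               amplitude_nA = c@eepscAmps, pair_index = NA),
    data.frame(cell_id = c@cellId, kind = "ppr1",
               amplitude_nA = c@pprPairs[, 1],
               pair_index = seq_len(nrow(c@pprPairs))),
    data.frame(cell_id = c@cellId, kind = "ppr2",
               amplitude_nA = c@pprPairs[, 2],
               pair_index = seq_len(nrow(c@pprPairs))))))
  write.csv(cdf, cp, row.names = FALSE)
  write.csv(edf, ep, row.names = FALSE)
  back <- readEphysCells(cp, ep)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]@mepscAmps, cells[[i]]@mepscAmps)
    expect_equal(quantalContent(back[[i]])@quantalContent,
                 quantalContent(cells[[i]])@quantalContent)
    expect_equal(quantalContent(back[[i]])@ppr,
                 quantalContent(cells[[i]])@ppr)
  }
  expect_error(readEphysCells(cp, cp), "missing")
})
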