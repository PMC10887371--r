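#' Cell inclusion criteria for voltage-clamp recordings
#'
#' A recording enters the analysis only when the cell's initial membrane
#' potential is at least as hyperpolarized as -50 mV and its membrane
#' resistance is at least 4 MOhm. Both boundaries are inclusive ("at least
#' -50 mV", ">= 4 MOhm").
#'
#' @param c an [EphysCell-class].
#' @param vmMax most depolarized acceptable membrane potential (mV,
#'   default -50).
#' @param rmMin minimum membrane resistance (MOhm, default 4).
#' @return logical(1).
#' @examples
#' includeCell(ephysCell("c1", vm = -65, rm = 6))   # TRUE
#' includeCell(ephysCell("c2", vm = -45, rm = 6))   # FALSE
#' includeCell(ephysCell("c3", vm = -50, rm = 4))   # TRUE (boundaries)
#' @export
includeCell <- function(c, vmMax = -50, rmMin = 4) {
  stopifnot(is(c, "EphysCell"))
  if (length(c@vm) != 1L || is.na(c@vm) || length(c@rm) != 1L || is.na(c@rm))
    stop("cell '", c@cellId, "' is missing vm or rm", call. = FALSE)
  c@vm <= vmMax && c@rm >= rmMin
}

#' Scale an mEPSC amplitude between holding potentials
#'
#' Assumes a linear current-voltage relationship with a 0 mV reversal
#' potential: `amp * (target - eRev) / (holdM - eRev)`. Scaling from -80 mV
#' to -60 mV therefore multiplies amplitudes by exactly 0.75.
#'
#' @param amp amplitude(s) in nA recorded at `holdM`.
#' @param holdM recording holding potential in mV (default -80).
#' @param target potential to scale to in mV (default -60).
#' @param eRev reversal potential in mV (default 0).
#' @return scaled amplitude(s) in nA.
#' @examples
#' scaleMepsc(-1.0)  # -0.75
#' @export
scaleMepsc <- function(amp, holdM = -80, target = -60, eRev = 0) {
  if (holdM == eRev)
    stop("holding potential equals the reversal potential", call. = FALSE)
  amp * ((target - eRev) / (holdM - eRev))
}

#' Paired-pulse ratio
#'
#' Ratio of the mean second-pulse amplitude to the mean first-pulse amplitude
#' over the averaged paired-pulse traces (average-then-ratio).
#'
#' @param pairs two-column matrix (or data.frame) of (A1, A2) amplitudes,
#'   one row per trace.
#' @return numeric(1) ratio.
#' @examples
#' pairedPulseRatio(cbind(c(-60, -60), c(-90, -90)))  # 1.5
#' @export
pairedPulseRatio <- function(pairs) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs)) stop("no paired-pulse traces", call. = FALSE)
  m1 <- mean(pairs[, 1]); m2 <- mean(pairs[, 2])
  if (m1 == 0) stop("mean first-pulse amplitude is zero", call. = FALSE)
  m2 / m1
}

#' Quantal content of one cell
#'
#' Mean evoked EPSC amplitude divided by the mean miniature EPSC amplitude of
#' the same cell, after scaling the minis from their holding potential to the
#' evoked holding potential (linear I-V, 0 mV reversal). Includes the
#' paired-pulse ratio when pairs were recorded.
#'
#' @param c an [EphysCell-class] with at least one mEPSC and one eEPSC.
#' @param eRev reversal potential in mV (default 0).
#' @return a [QuantalResult-class].
#' @examples
#' cell <- ephysCell("c1", vm = -65, rm = 6,
#'                   mepscAmps = rep(-1, 20), eepscAmps = rep(-75, 10))
#' quantalContent(cell)  # quantal content 100
#' @export
quantalContent <- function(c, eRev = 0) {
  stopifnot(is(c, "EphysCell"))
  if (!length(c@eepscAmps) || !length(c@mepscAmps))
    stop("cell '", c@cellId, "' needs at least one eEPSC and one mEPSC",
         call. = FALSE)
  mean_e <- mean(c@eepscAmps)
  mean_m <- scaleMepsc(mean(c@mepscAmps), holdM = c@holdM, target = c@holdE,
                       eRev = eRev)
  if (mean_m == 0) stop("mean mEPSC amplitude is zero", call. = FALSE)
  ppr <- if (nrow(c@pprPairs)) pairedPulseRatio(c@pprPairs) else NA_real_
  new("QuantalResult", cellId = c@cellId, meanEepsc = mean_e,
      meanMepscScaled = mean_m, quantalContent = mean_e / mean_m, ppr = ppr)
}

#' Simulate voltage-clamp cells with known quantal content
#'
#' Generates event-amplitude tables whose construction fixes the true quantal
#' content: per cell, mEPSC amplitudes are drawn around `mepscMu` (nA,
#' magnitude, emitted negative at -80 mV) with multiplicative Gaussian noise
#' of the given coefficient of variation, and eEPSC amplitudes around
#' `trueQc * mepscMu * 0.75` (the mini mean scaled to -60 mV) with the same
#' relative noise. With `cv = 0` every cell's estimated quantal content
#' equals `trueQc` exactly. Paired-pulse traces are drawn around
#' `truePpr * A1`. Output is bit-reproducible under the seed; the caller's
#' RNG state is untouched.
#'
#' @param nCells number of cells.
#' @param trueQc true quantal content (default 50).
#' @param mepscMu mean mEPSC magnitude in nA at -80 mV (default 1).
#' @param cv coefficient of variation of the multiplicative noise
#'   (default 0.1).
#' @param nMepsc,nEepsc,nPairs events per cell (defaults 50, 10, 8 — ten
#'   evoked responses averaged per cell, as in the reference protocol).
#' @param truePpr true paired-pulse ratio (default 1).
#' @param seed RNG seed.
#' @return list of [EphysCell-class] objects.
#' @export
simulateCells <- function(nCells, trueQc = 50, mepscMu = 1, cv = 0.1,
                          nMepsc = 50L, nEepsc = 10L, nPairs = 8L,
                          truePpr = 1, seed = 1L) {
  stopifnot(nCells >= 1, trueQc > 0, mepscMu > 0, cv >= 0)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  noise <- function(n) pmax(1 + cv * rnorm(n), 0.05)
  lapply(seq_len(nCells), function(i) {
    m <- -mepscMu * noise(nMepsc)                      # at -80 mV
    e <- -trueQc * mepscMu * 0.75 * noise(nEepsc)      # at -60 mV
    a1 <- -trueQc * mepscMu * 0.75 * noise(nPairs)
    a2 <- truePpr * a1 * noise(nPairs)
    ephysCell(sprintf("cell%03d", i),
              vm = -65 + rnorm(1, 0, 3), rm = 6 + abs(rnorm(1, 0, 1)),
              mepscAmps = m, eepscAmps = e, pprPairs = cbind(a1, a2))
  })
}

#' Read cells and event amplitudes from CSV
#'
#' `cellsPath` needs columns `cell_id, vm_mV, rm_MOhm` (optional `condition`);
#' `eventsPath` needs `cell_id, kind, amplitude_nA` with kind in
#' `mepsc, eepsc, ppr1, ppr2` (paired-pulse rows matched by `pair_index`),
#' and optionally `hold_mV`.
#'
#' @param cellsPath,eventsPath CSV file paths.
#' @return named list of [EphysCell-class] objects.
#' @export
readEphysCells <- function(cellsPath, eventsPath) {
  cells <- read.csv(cellsPath, stringsAsFactors = FALSE)
  events <- read.csv(eventsPath, stringsAsFactors = FALSE)
  need_c <- c("cell_id", "vm_mV", "rm_MOhm")
  need_e <- c("cell_id", "kind", "amplitude_nA")
  if (length(miss <- setdiff(need_c, names(cells))))
    stop("cells file is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (length(miss <- setdiff(need_e, names(events))))
    stop("events file is missing: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out <- lapply(seq_len(nrow(cells)), function(i) {
    id <- cells$cell_id[i]
    ev <- events[events$cell_id == id, , drop = FALSE]
    p1 <- ev[ev$kind == "ppr1", , drop = FALSE]
    p2 <- ev[ev$kind == "ppr2", , drop = FALSE]
    pp <- if (nrow(p1) && nrow(p2) && "pair_index" %in% names(ev)) {
      shared <- intersect(p1$pair_index, p2$pair_index)
      cbind(p1$amplitude_nA[match(shared, p1$pair_index)],
            p2$amplitude_nA[match(shared, p2$pair_index)])
    } else matrix(numeric(), ncol = 2)
    ephysCell(id, vm = cells$vm_mV[i], rm = cells$rm_MOhm[i],
              mepscAmps = ev$amplitude_nA[ev$kind == "mepsc"],
              eepscAmps = ev$amplitude_nA[ev$kind == "eepsc"],
              pprPairs = pp)
  })
  names(out) <- cells$cell_id
  out
}
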