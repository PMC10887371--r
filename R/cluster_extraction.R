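#' Extract localization clusters with HDBSCAN
#'
#' Partitions a localization table into density-based clusters plus noise
#' using hierarchical density-based spatial clustering of applications with
#' noise (HDBSCAN) on the (x, y) coordinates; frame and amplitude metadata are
#' carried through untouched. Labelling is deterministic for a fixed input:
#' cluster ids 0..K-1 are assigned by decreasing cluster size, ties broken by
#' the smallest member index. Every reported cluster has at least
#' `minClusterSize` members; unassigned localizations get label -1.
#'
#' Tables with fewer localizations than `minClusterSize` (or than
#' `minSamples + 1`) yield zero clusters, not an error.
#'
#' @param t a non-empty [LocalizationTable-class] with coordinates in nm.
#' @param p a [ClusterParams-class]; the study default is
#'   `clusterParams(40, 10)`.
#' @param roiLabel label recorded on the result.
#' @return a [ClusterSet-class].
#' @seealso [runSweep()], [selectStableParams()], [clusterPoints()]
#' @export
extractClusters <- function(t, p = clusterParams(), roiLabel = "roi") {
  stopifnot(is(t, "LocalizationTable"), is(p, "ClusterParams"))
  validObject(p)
  if (length(t) == 0L) stop("empty localization table", call. = FALSE)
  labels <- .hdbscan(locCoords(t), p@minClusterSize, p@minSamples)
  new("ClusterSet", labels = labels, params = p,
      roiLabel = as.character(roiLabel))
}

#' Split a localization table by cluster
#'
#' @param t the clustered [LocalizationTable-class].
#' @param cs the matching [ClusterSet-class].
#' @return a list of coordinate matrices, one per cluster id 0..K-1.
#' @export
clusterPoints <- function(t, cs) {
  stopifnot(is(t, "LocalizationTable"), is(cs, "ClusterSet"),
            length(t) == length(cs@labels))
  k <- nClusters(cs)
  xy <- locCoords(t)
  lapply(seq_len(k) - 1L, function(id) xy[cs@labels == id, , drop = FALSE])
}

#' The default HDBSCAN sweep axes
#'
#' Minimum cluster size 10 to 100 in increments of 10; minimum samples 2,
#' 5 to 25 in increments of 5, and 30 to 100 in increments of 10 — 140
#' combinations in all.
#'
#' @return list with integer vectors `mcs` (10 values) and `ms` (14 values).
#' @export
sweepGridSpec <- function() {
  list(mcs = as.integer(seq(10L, 100L, by = 10L)),
       ms = as.integer(c(2L, seq(5L, 25L, by = 5L), seq(30L, 100L, by = 10L))))
}

#' Run the two-parameter HDBSCAN sweep
#'
#' Clusters every image at every combination of minimum cluster size and
#' minimum samples and records the median, across images, of the number of
#' detected clusters — the quantity used to choose stable parameters.
#' The mutual-reachability hierarchy of an image depends only on minimum
#' samples, so it is computed once per `ms` value and re-condensed for each
#' minimum cluster size.
#'
#' @param images a non-empty list of [LocalizationTable-class] objects (one
#'   per image/NMJ).
#' @param mcsValues,msValues the sweep axes; defaults are the 10 x 14 grid of
#'   [sweepGridSpec()].
#' @return a [SweepGrid-class].
#' @seealso [selectStableParams()]
#' @export
runSweep <- function(images, mcsValues = sweepGridSpec()$mcs,
                     msValues = sweepGridSpec()$ms) {
  if (is(images, "LocalizationTable")) images <- list(images)
  if (!length(images)) stop("empty image list", call. = FALSE)
  stopifnot(all(vapply(images, is, logical(1), "LocalizationTable")))
  mcsValues <- as.integer(mcsValues); msValues <- as.integer(msValues)

  counts <- array(NA_real_,
                  dim = c(length(mcsValues), length(msValues), length(images)))
  for (im in seq_along(images)) {
    xy <- locCoords(images[[im]])
    n <- nrow(xy)
    for (j in seq_along(msValues)) {
      ms <- msValues[j]
      if (n <= ms) {
        counts[, j, im] <- 0
        next
      }
      tree <- .sl_tree(xy, ms)
      for (i in seq_along(mcsValues)) {
        mcs <- mcsValues[i]
        labels <- if (n < mcs) rep(-1L, n) else .hdbscan_from_tree(tree, mcs)
        counts[i, j, im] <- if (any(labels >= 0L)) max(labels) + 1L else 0L
      }
    }
  }
  cells <- apply(counts, c(1, 2), median)
  new("SweepGrid", mcsValues = mcsValues, msValues = msValues,
      cells = cells, nImages = length(images))
}

#' Select stable HDBSCAN parameters from a sweep grid
#'
#' The reference protocol fixes the final parameters "in the stable range" of
#' the sweep; this function operationalises that as a plateau rule. A grid
#' cell qualifies when its median cluster count differs by at most `relTol`
#' (relative) from every 4-neighbour; qualifying cells are grouped into
#' 4-connected plateaus and the largest plateau wins (preferring, among
#' equally large ones, a plateau containing the anchored default). If the
#' default parameter pair lies inside the winning plateau it is returned;
#' otherwise the plateau cell closest to the grid centre is returned (ties:
#' smaller minimum cluster size, then smaller minimum samples).
#'
#' If no cell qualifies at `relTol`, the tolerance is widened stepwise with a
#' warning until a plateau appears.
#'
#' @param g a [SweepGrid-class].
#' @param relTol relative tolerance between neighbouring cells (default 0.10).
#' @param default the anchored parameter pair, `c(mcs, ms)`; default
#'   `c(40, 10)`.
#' @return a [ClusterParams-class].
#' @export
selectStableParams <- function(g, relTol = 0.10, default = c(40L, 10L)) {
  stopifnot(is(g, "SweepGrid"))
  M <- g@cells
  nr <- nrow(M); nc <- ncol(M)

  reldiff <- function(a, b) {
    m <- pmax(abs(a), abs(b))
    ifelse(m > 0, abs(a - b) / m, 0)
  }
  qualifies <- function(tol) {
    q <- matrix(TRUE, nr, nc)
    if (nr > 1L) {
      d <- reldiff(M[-1L, , drop = FALSE], M[-nr, , drop = FALSE]) <= tol
      q[-1L, ] <- q[-1L, , drop = FALSE] & d
      q[-nr, ] <- q[-nr, , drop = FALSE] & d
    }
    if (nc > 1L) {
      d <- reldiff(M[, -1L, drop = FALSE], M[, -nc, drop = FALSE]) <= tol
      q[, -1L] <- q[, -1L, drop = FALSE] & d
      q[, -nc] <- q[, -nc, drop = FALSE] & d
    }
    q
  }

  tol <- relTol
  q <- qualifies(tol)
  while (!any(q)) {
    tol <- if (tol <= 0) 0.05 else tol * 2
    q <- qualifies(tol)
  }
  if (tol != relTol)
    warning(sprintf(
      "no stable plateau at relTol = %g; widened tolerance to %g",
      relTol, tol), call. = FALSE)

  ## 4-connected components of qualifying cells
  comp <- matrix(0L, nr, nc)
  ncomp <- 0L
  for (s in which(q)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    stack <- s
    while (length(stack)) {
      cell <- stack[[1L]]; stack <- stack[-1L]
      if (comp[cell] != 0L) next
      comp[cell] <- ncomp
      i <- (cell - 1L) %% nr + 1L; j <- (cell - 1L) %/% nr + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] >= 1L && nb[1] <= nr && nb[2] >= 1L && nb[2] <= nc &&
            q[nb[1], nb[2]] && comp[nb[1], nb[2]] == 0L)
          stack <- c(stack, (nb[2] - 1L) * nr + nb[1])
      }
    }
  }

  di <- match(default[1], g@mcsValues)
  dj <- match(default[2], g@msValues)
  default_comp <- if (!is.na(di) && !is.na(dj)) comp[di, dj] else 0L
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  best <- which(sizes == max(sizes))
  win <- if (default_comp %in% best) default_comp else best[1L]

  if (win == default_comp)
    return(clusterParams(default[1], default[2]))

  cells <- which(comp == win)
  i <- (cells - 1L) %% nr + 1L; j <- (cells - 1L) %/% nr + 1L
  d2 <- (i - (nr + 1) / 2)^2 + (j - (nc + 1) / 2)^2
  ord <- order(d2, g@mcsValues[i], g@msValues[j])
  pick <- ord[1L]
  clusterParams(g@mcsValues[i[pick]], g@msValues[j[pick]])
}
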