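## Delaunay triangulation of a point set with per-triangle areas and squared
## circumradii; the single geometric primitive behind every alpha-shape
## computation here. Returns NULL for degenerate input (<3 distinct points or
## all collinear).
.delaunay_triangles <- function(points) {
  pts <- unique(points[stats::complete.cases(points), , drop = FALSE])
  if (nrow(pts) < 3L) return(NULL)
  ## collinearity: all cross products relative to the first edge vanish
  v1 <- pts[2, ] - pts[1, ]
  cross <- (pts[, 1] - pts[1, 1]) * v1[2] - (pts[, 2] - pts[1, 2]) * v1[1]
  scale <- max(abs(pts - matrix(pts[1, ], nrow(pts), 2, byrow = TRUE)))
  if (all(abs(cross) <= 1e-9 * scale^2)) return(NULL)

  dd <- suppressWarnings(deldir::deldir(pts[, 1], pts[, 2],
                                        suppressMsge = TRUE))
  tl <- deldir::triang.list(dd)
  if (!length(tl)) return(NULL)
  tri <- t(vapply(tl, function(tr) tr$ptNum, integer(3)))

  ax <- pts[tri[, 1], 1]; ay <- pts[tri[, 1], 2]
  bx <- pts[tri[, 2], 1]; by <- pts[tri[, 2], 2]
  cx <- pts[tri[, 3], 1]; cy <- pts[tri[, 3], 2]
  area <- abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
  a2 <- (bx - cx)^2 + (by - cy)^2
  b2 <- (ax - cx)^2 + (ay - cy)^2
  c2 <- (ax - bx)^2 + (ay - by)^2
  r2 <- ifelse(area > 0, a2 * b2 * c2 / (16 * area^2), Inf)
  list(points = pts, tri = tri, area = area, r2 = r2)
}

#' 2D alpha shape of a point set
#'
#' Computes the alpha shape under the squared-circumradius convention: the
#' Delaunay triangulation is computed and a triangle is retained iff its
#' squared circumradius is at most `alpha` (nm^2), so `alpha = x^2` keeps
#' triangles whose circumcircle radius does not exceed x nm. The shape's area
#' is the summed area of retained triangles; its boundary is the set of edges
#' belonging to exactly one retained triangle.
#'
#' Point sets with fewer than three distinct points, or collinear ones, yield
#' a degenerate shape of area 0 (flagged, not an error) — such clusters are
#' later caught by the lower area-exclusion bound.
#'
#' @param points two-column matrix of (x, y) positions in nm.
#' @param alpha squared-circumradius threshold in nm^2 (> 0); the study value
#'   is 9025 nm^2 (x = 95 nm).
#' @return an [AlphaShape-class].
#' @examples
#' tri <- rbind(c(0, 0), c(100, 0), c(0, 100))   # circumradius^2 = 5000
#' shapeArea(alphaShapeArea(tri, 10000))          # 5000 nm^2
#' shapeArea(alphaShapeArea(tri, 4000))           # 0
#' @seealso [areaVsAlphaSweep()], [selectAlpha()]
#' @export
alphaShapeArea <- function(points, alpha) {
  stopifnot(alpha > 0)
  points <- as.matrix(points)
  dt <- .delaunay_triangles(points)
  if (is.null(dt))
    return(new("AlphaShape", alpha = as.numeric(alpha),
               triangles = matrix(integer(), ncol = 3), area = 0,
               boundary = matrix(integer(), ncol = 2), degenerate = TRUE))
  keep <- dt$r2 <= alpha
  tri <- dt$tri[keep, , drop = FALSE]
  edges <- rbind(tri[, c(1, 2), drop = FALSE],
                 tri[, c(2, 3), drop = FALSE],
                 tri[, c(1, 3), drop = FALSE])
  edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  key <- paste(edges[, 1], edges[, 2])
  boundary <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
  new("AlphaShape", alpha = as.numeric(alpha), triangles = tri,
      area = sum(dt$area[keep]), boundary = boundary, degenerate = FALSE)
}

#' The default alpha grid
#'
#' alpha = x^2 nm^2 with x running from 5 to 200 nm in increments of 5:
#' 40 values from 25 to 40000 nm^2.
#'
#' @return numeric(40) of alpha values in nm^2.
#' @export
alphaGrid <- function() seq(5, 200, by = 5)^2

#' Median cluster area as a function of alpha
#'
#' Evaluates every cluster's alpha-shape area on an alpha grid and summarises
#' the population per alpha by the median and quartiles (in um^2), together
#' with the percent increase of the median from each grid step to the next —
#' the curve from which the final alpha is chosen. Each cluster is
#' triangulated once and re-thresholded per alpha.
#'
#' Degenerate clusters contribute area 0 throughout; if every cluster is
#' degenerate this is an error.
#'
#' @param clusters list of two-column coordinate matrices (nm), one per
#'   cluster, e.g. from [clusterPoints()].
#' @param alphas the alpha grid in nm^2 (default [alphaGrid()]).
#' @return an [AlphaSweepResult-class].
#' @seealso [selectAlpha()]
#' @export
areaVsAlphaSweep <- function(clusters, alphas = alphaGrid()) {
  if (is.matrix(clusters)) clusters <- list(clusters)
  if (!length(clusters)) stop("no clusters supplied", call. = FALSE)
  alphas <- sort(as.numeric(alphas))
  dts <- lapply(clusters, function(cl) .delaunay_triangles(as.matrix(cl)))
  if (all(vapply(dts, is.null, logical(1))))
    stop("all clusters are degenerate (collinear or < 3 points)",
         call. = FALSE)

  ## areas in um^2: rows = clusters, cols = alphas
  A <- t(vapply(dts, function(dt) {
    if (is.null(dt)) return(numeric(length(alphas)))
    vapply(alphas, function(a) sum(dt$area[dt$r2 <= a]), numeric(1)) / 1e6
  }, numeric(length(alphas))))

  med <- apply(A, 2, median)
  q25 <- apply(A, 2, quantile, probs = 0.25, names = FALSE)
  q75 <- apply(A, 2, quantile, probs = 0.75, names = FALSE)
  pct <- c(NA_real_, ifelse(med[-length(med)] > 0,
                            100 * diff(med) / med[-length(med)], NA_real_))
  new("AlphaSweepResult", alphas = alphas, medianArea = med, q25 = q25,
      q75 = q75, pctIncrease = pct, nClusters = length(clusters))
}

#' Select alpha by the small-increase stopping rule
#'
#' Returns the first alpha on the grid whose step increase of the median
#' cluster area falls strictly below the threshold (5 percent by default) —
#' the point where further growing alpha stops adding appreciable area. The
#' first grid alpha has no predecessor step and is never selectable.
#'
#' @param r an [AlphaSweepResult-class].
#' @param thresholdPct percent-increase threshold (default 5).
#' @return the selected alpha in nm^2.
#' @examples
#' sq <- rbind(c(0, 0), c(300, 0), c(300, 300), c(0, 300), c(150, 150))
#' sw <- areaVsAlphaSweep(list(sq))
#' selectAlpha(sw)
#' @export
selectAlpha <- function(r, thresholdPct = 5) {
  stopifnot(is(r, "AlphaSweepResult"))
  hit <- which(!is.na(r@pctIncrease) & r@pctIncrease < thresholdPct)
  if (!length(hit))
    stop("no alpha step increased the median area by less than ",
         thresholdPct, "%; widen the alpha sweep", call. = FALSE)
  r@alphas[hit[1L]]
}
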