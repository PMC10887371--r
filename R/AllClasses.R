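#' @useDynLib smlmFields, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats median quantile rgeom rnorm rpois runif setNames complete.cases
#' @importFrom graphics hist
#' @importFrom utils head read.csv write.csv
NULL

## polygon helpers used by validity methods (defined before the classes so
## validity can call them during package load)

.shoelace <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  n <- nrow(v)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

## segment intersection test for simple-polygon validation; touching at
## shared endpoints of adjacent edges is allowed
.segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  for (i in seq_len(n)) {
    a1 <- v[i, ]; a2 <- v[if (i == n) 1L else i + 1L, ]
    for (j in seq_len(n)) {
      if (j == i) next
      ## skip edges sharing a vertex with edge i
      if (abs(i - j) == 1L || abs(i - j) == n - 1L) next
      b1 <- v[j, ]; b2 <- v[if (j == n) 1L else j + 1L, ]
      if (.segments_cross(a1, a2, b1, b2)) return(FALSE)
    }
  }
  TRUE
}

#' LocalizationTable: a dSTORM point cloud
#'
#' Container for single-molecule localizations as produced by a localization
#' engine such as rapidSTORM: planar positions in nanometres, the acquisition
#' frame in which each spot was fitted, and the fitted fluorescence amplitude
#' in camera A/D counts.
#'
#' Coordinates follow the image convention: origin at the top-left corner of
#' the reconstructed image, x increasing rightward and y increasing downward,
#' both non-negative and continuous.
#'
#' @slot x,y numeric, localization positions in nm.
#' @slot frame integer, zero-based acquisition frame index.
#' @slot adcount numeric, fitted amplitude in A/D counts.
#' @slot channelPx numeric(1), camera pixel size of the acquisition channel in
#'   nm per pixel (127 for the red and 130 for the green channel of the
#'   reference setup).
#' @slot nFrames integer(1), number of frames in the acquisition (default
#'   15000).
#'
#' @seealso [localizationTable()], [readLocalizations()], [filterByAdcount()]
#' @exportClass LocalizationTable
setClass("LocalizationTable",
  representation(
    x = "numeric", y = "numeric",
    frame = "integer", adcount = "numeric",
    channelPx = "numeric", nFrames = "integer"
  ),
  prototype(channelPx = 127, nFrames = 15000L)
)

setValidity("LocalizationTable", function(object) {
  n <- length(object@x)
  msg <- character()
  if (length(object@y) != n || length(object@frame) != n ||
      length(object@adcount) != n)
    msg <- c(msg, "x, y, frame and adcount must have equal length")
  else {
    if (n && (anyNA(object@x) || anyNA(object@y) ||
              !all(is.finite(object@x)) || !all(is.finite(object@y))))
      msg <- c(msg, "coordinates must be finite and non-missing")
    if (n && any(object@frame < 0L, na.rm = TRUE))
      msg <- c(msg, "frame indices must be >= 0")
    if (n && any(object@frame >= object@nFrames, na.rm = TRUE))
      msg <- c(msg, "frame indices must be < nFrames")
    if (n && any(object@adcount < 0, na.rm = TRUE))
      msg <- c(msg, "adcount must be >= 0")
  }
  if (length(object@channelPx) != 1L || object@channelPx <= 0)
    msg <- c(msg, "channelPx must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' RoiPolygon: a region of interest in nm coordinates
#'
#' A closed, simple polygon delimiting one analysis region (typically the
#' terminal type Ib boutons of one neuromuscular junction), stored with
#' vertices in nm. Polygons drawn on reconstructed binned images (10 nm per
#' pixel by default) are converted to nm on construction.
#'
#' @slot vertices two-column numeric matrix of polygon vertices (nm), in
#'   drawing order; the polygon is implicitly closed.
#' @slot label character(1) identifier, e.g. a bouton or NMJ index.
#' @slot sourcePx numeric(1), pixel size (nm/px) of the annotation image the
#'   polygon was drawn on; 10 for the standard reconstruction.
#'
#' @seealso [roiPolygon()], [clipToRoi()]
#' @exportClass RoiPolygon
setClass("RoiPolygon",
  representation(vertices = "matrix", label = "character",
                 sourcePx = "numeric"),
  prototype(label = "roi", sourcePx = 10)
)

setValidity("RoiPolygon", function(object) {
  v <- object@vertices
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 2L)
    return("vertices must be a numeric matrix with two columns")
  if (nrow(v) < 3L) msg <- c(msg, "a polygon needs at least 3 vertices")
  else {
    if (anyNA(v) || !all(is.finite(v)))
      msg <- c(msg, "vertices must be finite")
    else {
      if (.shoelace(v) <= 0)
        msg <- c(msg, "polygon must enclose a positive area")
      if (!.is_simple_polygon(v))
        msg <- c(msg, "polygon must be simple (non-self-intersecting)")
    }
  }
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(object@sourcePx) != 1L || object@sourcePx <= 0)
    msg <- c(msg, "sourcePx must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' BinnedImage: a reconstructed localization-count image
#'
#' 2D histogram of localizations on a square grid, the representation used to
#' draw ROIs. Bins are half-open: a localization at position p falls in bin
#' floor((p - origin) / px).
#'
#' @slot counts integer matrix of localization counts; rows index y (downward),
#'   columns index x.
#' @slot px numeric(1), bin edge length in nm (default 10).
#' @slot origin numeric(2), nm position of the top-left grid corner.
#'
#' @seealso [renderBinned()]
#' @exportClass BinnedImage
setClass("BinnedImage",
  representation(counts = "matrix", px = "numeric", origin = "numeric"),
  prototype(px = 10, origin = c(0, 0))
)

setValidity("BinnedImage", function(object) {
  msg <- character()
  if (length(object@px) != 1L || object@px <= 0)
    msg <- c(msg, "px must be a single positive number")
  if (length(object@origin) != 2L)
    msg <- c(msg, "origin must have length 2")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ClusterParams: HDBSCAN parameter pair
#'
#' The two free parameters of hierarchical density-based clustering:
#' the minimum number of localizations a cluster must contain and the
#' minimum-samples smoothing parameter controlling core distances.
#'
#' @slot minClusterSize integer(1), >= 2.
#' @slot minSamples integer(1), >= 1.
#'
#' @seealso [clusterParams()], [extractClusters()]
#' @exportClass ClusterParams
setClass("ClusterParams",
  representation(minClusterSize = "integer", minSamples = "integer"),
  prototype(minClusterSize = 40L, minSamples = 10L)
)

setValidity("ClusterParams", function(object) {
  msg <- character()
  if (length(object@minClusterSize) != 1L || object@minClusterSize < 2L)
    msg <- c(msg, "minClusterSize must be a single integer >= 2")
  if (length(object@minSamples) != 1L || object@minSamples < 1L)
    msg <- c(msg, "minSamples must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' ClusterSet: a labelled partition of ROI localizations
#'
#' Per-localization cluster labels from density-based clustering: -1 marks
#' unclustered noise, ids 0..K-1 mark clusters ordered by decreasing size
#' (ties broken by smallest member index).
#'
#' @slot labels integer vector, one label per localization of the clustered
#'   table.
#' @slot params the [ClusterParams-class] used.
#' @slot roiLabel character(1), label of the ROI the localizations came from.
#'
#' @seealso [extractClusters()], [clusterPoints()]
#' @exportClass ClusterSet
setClass("ClusterSet",
  representation(labels = "integer", params = "ClusterParams",
                 roiLabel = "character"),
  prototype(roiLabel = "roi")
)

setValidity("ClusterSet", function(object) {
  lab <- object@labels
  msg <- character()
  if (length(lab) && any(lab < -1L)) msg <- c(msg, "labels must be >= -1")
  ids <- lab[lab >= 0L]
  if (length(ids)) {
    tab <- table(ids)
    if (!identical(sort(as.integer(names(tab))), seq_len(length(tab)) - 1L))
      msg <- c(msg, "cluster ids must be consecutive starting at 0")
    if (any(tab < object@params@minClusterSize))
      msg <- c(msg, "every cluster must have >= minClusterSize members")
  }
  if (length(msg)) msg else TRUE
})

#' SweepGrid: median cluster counts over the HDBSCAN parameter grid
#'
#' Result of the two-parameter sweep: for every combination of minimum cluster
#' size (10 to 100 in steps of 10) and minimum samples (2, 5 to 25 in steps of
#' 5, 30 to 100 in steps of 10), the median over images of the number of
#' detected clusters. 10 x 14 = 140 combinations.
#'
#' @slot mcsValues integer, the minimum-cluster-size axis (rows).
#' @slot msValues integer, the minimum-samples axis (columns).
#' @slot cells numeric matrix (length(mcsValues) x length(msValues)) of median
#'   cluster counts per image.
#' @slot nImages integer(1), number of images the medians were taken over.
#'
#' @seealso [runSweep()], [selectStableParams()]
#' @exportClass SweepGrid
setClass("SweepGrid",
  representation(mcsValues = "integer", msValues = "integer",
                 cells = "matrix", nImages = "integer")
)

setValidity("SweepGrid", function(object) {
  if (!identical(dim(object@cells),
                 c(length(object@mcsValues), length(object@msValues))))
    return("cells must be a length(mcsValues) x length(msValues) matrix")
  TRUE
})

#' AlphaShape: a 2D alpha shape of one cluster
#'
#' The union of Delaunay triangles whose squared circumradius is at most
#' alpha (nm^2), the convention in which alpha = x^2 nm^2 corresponds to a
#' length scale of x nm. Its total area measures the cluster footprint.
#'
#' @slot alpha numeric(1), squared-circumradius threshold in nm^2.
#' @slot triangles integer matrix (m x 3) of point indices of the retained
#'   Delaunay triangles.
#' @slot area numeric(1), summed area of retained triangles in nm^2.
#' @slot boundary integer matrix (b x 2) of point-index pairs: edges belonging
#'   to exactly one retained triangle.
#' @slot degenerate logical(1), TRUE when the point set had fewer than three
#'   points or was collinear (area 0).
#'
#' @seealso [alphaShapeArea()]
#' @exportClass AlphaShape
setClass("AlphaShape",
  representation(alpha = "numeric", triangles = "matrix", area = "numeric",
                 boundary = "matrix", degenerate = "logical"),
  prototype(degenerate = FALSE)
)

setValidity("AlphaShape", function(object) {
  if (object@area < 0) return("area must be >= 0")
  TRUE
})

#' AlphaSweepResult: median cluster area as a function of alpha
#'
#' Areas of a cluster population evaluated on the alpha grid
#' alpha = x^2 nm^2, x = 5, 10, ..., 200 (40 values), summarised by the
#' median and quartiles across clusters, together with the percent increase
#' of the median from each alpha step to the next.
#'
#' @slot alphas numeric(40), the alpha grid in nm^2 (25 to 40000).
#' @slot medianArea,q25,q75 numeric(40), per-alpha area summaries in um^2.
#' @slot pctIncrease numeric(40), percent change of the median area relative
#'   to the previous step; NA at the first alpha.
#' @slot nClusters integer(1), number of clusters entering the sweep.
#'
#' @seealso [areaVsAlphaSweep()], [selectAlpha()]
#' @exportClass AlphaSweepResult
setClass("AlphaSweepResult",
  representation(alphas = "numeric", medianArea = "numeric",
                 q25 = "numeric", q75 = "numeric",
                 pctIncrease = "numeric", nClusters = "integer")
)

setValidity("AlphaSweepResult", function(object) {
  k <- length(object@alphas)
  if (length(object@medianArea) != k || length(object@q25) != k ||
      length(object@q75) != k || length(object@pctIncrease) != k)
    return("summary vectors must match the alpha grid length")
  if (is.unsorted(object@alphas, strictly = TRUE))
    return("alphas must be strictly increasing")
  TRUE
})

#' FieldSummary: distribution summary of receptor fields
#'
#' Box-plot statistics (median, 25th/75th percentiles, 10th/90th percentile
#' whiskers) of the area and localization count of a receptor-field
#' population, plus a histogram normalized so the bin heights sum to one.
#'
#' @slot nFields integer(1), number of fields summarised.
#' @slot area named numeric: median, q25, q75, p10, p90 (um^2).
#' @slot locs named numeric: median, q25, q75, p10, p90 (counts).
#' @slot histBreaks numeric, area histogram bin edges (um^2).
#' @slot histHeights numeric, normalized bin heights (sum 1).
#'
#' @seealso [summarizeFields()]
#' @exportClass FieldSummary
setClass("FieldSummary",
  representation(nFields = "integer", area = "numeric", locs = "numeric",
                 histBreaks = "numeric", histHeights = "numeric")
)

setValidity("FieldSummary", function(object) {
  if (length(object@histHeights) &&
      abs(sum(object@histHeights) - 1) > 1e-12)
    return("histogram heights must sum to 1")
  TRUE
})

#' EphysCell: one voltage-clamped muscle cell
#'
#' Event-amplitude summary of one two-electrode voltage-clamp recording:
#' spontaneous (miniature) EPSC amplitudes recorded at the mini holding
#' potential, evoked EPSC amplitudes at the evoked holding potential, and
#' optional paired-pulse amplitude pairs. Inward currents are negative.
#'
#' @slot cellId character(1).
#' @slot vm numeric(1), initial membrane potential in mV (negative).
#' @slot rm numeric(1), membrane resistance in MOhm.
#' @slot mepscAmps numeric, mEPSC amplitudes in nA at `holdM`.
#' @slot eepscAmps numeric, eEPSC amplitudes in nA at `holdE`.
#' @slot holdM numeric(1), holding potential for minis in mV (default -80).
#' @slot holdE numeric(1), holding potential for evoked currents (default -60).
#' @slot pprPairs numeric matrix (p x 2) of first/second evoked amplitudes of
#'   paired-pulse traces.
#' @slot ipi numeric(1), interstimulus interval of the paired pulses in ms
#'   (default 30).
#'
#' @seealso [ephysCell()], [quantalContent()], [includeCell()]
#' @exportClass EphysCell
setClass("EphysCell",
  representation(cellId = "character", vm = "numeric", rm = "numeric",
                 mepscAmps = "numeric", eepscAmps = "numeric",
                 holdM = "numeric", holdE = "numeric",
                 pprPairs = "matrix", ipi = "numeric"),
  prototype(holdM = -80, holdE = -60, ipi = 30,
            pprPairs = matrix(numeric(), ncol = 2))
)

setValidity("EphysCell", function(object) {
  msg <- character()
  if (object@holdM >= 0 || object@holdE >= 0)
    msg <- c(msg, "holding potentials must be below the 0 mV reversal")
  amps <- c(object@mepscAmps, object@eepscAmps)
  if (length(amps) && length(unique(sign(amps[amps != 0]))) > 1L)
    msg <- c(msg, "amplitudes must carry a consistent sign")
  if (ncol(object@pprPairs) != 2L)
    msg <- c(msg, "pprPairs must have two columns")
  if (length(msg)) msg else TRUE
})

#' QuantalResult: derived synaptic transmission measures of one cell
#'
#' @slot cellId character(1).
#' @slot meanEepsc numeric(1), mean evoked EPSC amplitude (nA).
#' @slot meanMepscScaled numeric(1), mean mEPSC amplitude scaled to the evoked
#'   holding potential (nA).
#' @slot quantalContent numeric(1), meanEepsc / meanMepscScaled.
#' @slot ppr numeric(1), paired-pulse ratio (mean second over mean first
#'   amplitude); NA when no pairs were recorded.
#'
#' @seealso [quantalContent()]
#' @exportClass QuantalResult
setClass("QuantalResult",
  representation(cellId = "character", meanEepsc = "numeric",
                 meanMepscScaled = "numeric", quantalContent = "numeric",
                 ppr = "numeric")
)
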