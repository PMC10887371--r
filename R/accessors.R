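#' Construct a LocalizationTable
#'
#' @param x,y numeric, positions in nm.
#' @param frame integer frame indices (zero-based); defaults to 0.
#' @param adcount fitted amplitudes in A/D counts; defaults to Inf-free large
#'   values are not assumed — the default 0 keeps the filter explicit.
#' @param channelPx camera pixel size in nm/px.
#' @param nFrames number of acquisition frames.
#' @return a [LocalizationTable-class].
#' @examples
#' localizationTable(x = c(100, 200), y = c(50, 60), adcount = c(15000, 9000))
#' @export
localizationTable <- function(x, y, frame = integer(length(x)),
                              adcount = numeric(length(x)),
                              channelPx = 127, nFrames = 15000L) {
  new("LocalizationTable", x = as.numeric(x), y = as.numeric(y),
      frame = as.integer(frame), adcount = as.numeric(adcount),
      channelPx = as.numeric(channelPx), nFrames = as.integer(nFrames))
}

#' Construct an ROI polygon
#'
#' Vertices may be given in nm or in pixel coordinates of the annotation
#' image; pixel coordinates are converted to nm by `sourcePx`.
#'
#' @param vertices two-column matrix (or data.frame) of vertices.
#' @param label ROI identifier.
#' @param units `"nm"` or `"px"`; `"px"` vertices are multiplied by
#'   `sourcePx`.
#' @param sourcePx pixel size of the annotation image in nm/px (default 10).
#' @return a [RoiPolygon-class] with vertices in nm.
#' @examples
#' roiPolygon(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)))
#' @export
roiPolygon <- function(vertices, label = "roi", units = c("nm", "px"),
                       sourcePx = 10) {
  units <- match.arg(units)
  v <- as.matrix(vertices)
  storage.mode(v) <- "double"
  dimnames(v) <- NULL
  if (units == "px") v <- v * sourcePx
  new("RoiPolygon", vertices = v, label = as.character(label),
      sourcePx = as.numeric(sourcePx))
}

#' Construct an HDBSCAN parameter pair
#'
#' @param minClusterSize minimum number of localizations per cluster
#'   (default 40).
#' @param minSamples minimum-samples smoothing parameter (default 10).
#' @return a [ClusterParams-class].
#' @export
clusterParams <- function(minClusterSize = 40L, minSamples = 10L) {
  new("ClusterParams", minClusterSize = as.integer(minClusterSize),
      minSamples = as.integer(minSamples))
}

#' Construct an EphysCell
#'
#' @param cellId cell identifier.
#' @param vm initial membrane potential (mV).
#' @param rm membrane resistance (MOhm).
#' @param mepscAmps mEPSC amplitudes (nA) at `holdM`.
#' @param eepscAmps eEPSC amplitudes (nA) at `holdE`.
#' @param holdM,holdE holding potentials (mV) for minis and evoked currents.
#' @param pprPairs two-column matrix of paired-pulse amplitudes.
#' @param ipi paired-pulse interstimulus interval (ms).
#' @return an [EphysCell-class].
#' @export
ephysCell <- function(cellId, vm, rm, mepscAmps = numeric(),
                      eepscAmps = numeric(), holdM = -80, holdE = -60,
                      pprPairs = matrix(numeric(), ncol = 2), ipi = 30) {
  pp <- as.matrix(pprPairs)
  if (length(pp) == 0L) pp <- matrix(numeric(), ncol = 2)
  dimnames(pp) <- NULL
  new("EphysCell", cellId = as.character(cellId), vm = as.numeric(vm),
      rm = as.numeric(rm), mepscAmps = as.numeric(mepscAmps),
      eepscAmps = as.numeric(eepscAmps), holdM = as.numeric(holdM),
      holdE = as.numeric(holdE), pprPairs = pp, ipi = as.numeric(ipi))
}

#' Number of localizations
#' @param object a [LocalizationTable-class].
#' @return integer count.
#' @export
setGeneric("nLocs", function(object) standardGeneric("nLocs"))

#' @rdname nLocs
#' @export
setMethod("nLocs", "LocalizationTable", function(object) length(object@x))

#' Localization coordinates as a matrix
#' @param object a [LocalizationTable-class].
#' @return n x 2 numeric matrix of (x, y) in nm.
#' @export
setGeneric("locCoords", function(object) standardGeneric("locCoords"))

#' @rdname locCoords
#' @export
setMethod("locCoords", "LocalizationTable",
          function(object) cbind(x = object@x, y = object@y))

#' @describeIn nLocs length of a table is its localization count.
#' @export
setMethod("length", "LocalizationTable", function(x) length(x@x))

#' Subset a LocalizationTable by row
#' @param x a [LocalizationTable-class].
#' @param i numeric or logical row index.
#' @param j,drop,... ignored.
#' @return the subset [LocalizationTable-class].
#' @export
setMethod("[", "LocalizationTable", function(x, i, j, ..., drop = FALSE) {
  initialize(x, x = x@x[i], y = x@y[i], frame = x@frame[i],
             adcount = x@adcount[i])
})

#' Coerce a LocalizationTable to a data.frame
#'
#' Columns `x_nm, y_nm, frame, adcount`.
#'
#' @param x a [LocalizationTable-class].
#' @param row.names,optional,... ignored, present for the generic's signature.
#' @return a data.frame with one row per localization.
#' @exportS3Method base::as.data.frame
as.data.frame.LocalizationTable <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(x_nm = x@x, y_nm = x@y, frame = x@frame, adcount = x@adcount)
}

setMethod("as.data.frame", "LocalizationTable", as.data.frame.LocalizationTable)

setMethod("show", "LocalizationTable", function(object) {
  cat("LocalizationTable with", length(object@x), "localizations\n")
  if (length(object@x)) {
    cat(sprintf("  x: [%.1f, %.1f] nm   y: [%.1f, %.1f] nm\n",
                min(object@x), max(object@x), min(object@y), max(object@y)))
    cat(sprintf("  frames: %d-%d of %d   adcount median: %.0f\n",
                min(object@frame), max(object@frame), object@nFrames,
                median(object@adcount)))
  }
  cat(sprintf("  channel pixel size: %g nm/px\n", object@channelPx))
})

#' ROI vertices
#' @param object a [RoiPolygon-class].
#' @return two-column matrix of vertices in nm.
#' @export
setGeneric("roiVertices", function(object) standardGeneric("roiVertices"))

#' @rdname roiVertices
#' @export
setMethod("roiVertices", "RoiPolygon", function(object) object@vertices)

#' ROI label
#' @param object a [RoiPolygon-class] or [ClusterSet-class].
#' @return character(1).
#' @export
setGeneric("roiLabel", function(object) standardGeneric("roiLabel"))

#' @rdname roiLabel
#' @export
setMethod("roiLabel", "RoiPolygon", function(object) object@label)

#' @rdname roiLabel
#' @export
setMethod("roiLabel", "ClusterSet", function(object) object@roiLabel)

#' Enclosed area of an ROI polygon
#' @param object a [RoiPolygon-class].
#' @param units `"nm2"` or `"um2"`.
#' @return numeric(1) area.
#' @export
setGeneric("roiArea", function(object, units = c("um2", "nm2"))
  standardGeneric("roiArea"))

#' @rdname roiArea
#' @export
setMethod("roiArea", "RoiPolygon", function(object, units = c("um2", "nm2")) {
  units <- match.arg(units)
  a <- .shoelace(object@vertices)
  if (units == "um2") a / 1e6 else a
})

setMethod("show", "RoiPolygon", function(object) {
  cat(sprintf("RoiPolygon '%s': %d vertices, area %.3f um^2\n",
              object@label, nrow(object@vertices), roiArea(object)))
})

setMethod("show", "BinnedImage", function(object) {
  cat(sprintf("BinnedImage %d x %d bins at %g nm/px, %d localizations\n",
              nrow(object@counts), ncol(object@counts), object@px,
              sum(object@counts)))
})

#' Per-localization cluster labels
#' @param object a [ClusterSet-class].
#' @return integer vector; -1 is noise, 0..K-1 are cluster ids.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterSet", function(object) object@labels)

#' Number of clusters in a ClusterSet
#' @param object a [ClusterSet-class].
#' @return integer(1).
#' @export
setGeneric("nClusters", function(object) standardGeneric("nClusters"))

#' @rdname nClusters
#' @export
setMethod("nClusters", "ClusterSet", function(object) {
  ids <- object@labels[object@labels >= 0L]
  if (length(ids)) max(ids) + 1L else 0L
})

setMethod("show", "ClusterSet", function(object) {
  k <- nClusters(object)
  cat(sprintf(
    "ClusterSet '%s': %d clusters over %d localizations (%d noise)\n",
    object@roiLabel, k, length(object@labels), sum(object@labels == -1L)))
  cat(sprintf("  params: minClusterSize=%d, minSamples=%d\n",
              object@params@minClusterSize, object@params@minSamples))
})

setMethod("show", "ClusterParams", function(object) {
  cat(sprintf("ClusterParams(minClusterSize=%d, minSamples=%d)\n",
              object@minClusterSize, object@minSamples))
})

#' Sweep grid as a long data.frame
#' @param object a [SweepGrid-class].
#' @return data.frame with columns mcs, ms, median_clusters.
#' @export
setGeneric("sweepTable", function(object) standardGeneric("sweepTable"))

#' @rdname sweepTable
#' @export
setMethod("sweepTable", "SweepGrid", function(object) {
  data.frame(
    mcs = rep(object@mcsValues, times = length(object@msValues)),
    ms = rep(object@msValues, each = length(object@mcsValues)),
    median_clusters = as.vector(object@cells)
  )
})

setMethod("show", "SweepGrid", function(object) {
  cat(sprintf("SweepGrid: %d x %d = %d parameter combinations over %d image(s)\n",
              length(object@mcsValues), length(object@msValues),
              length(object@cells), object@nImages))
  cat(sprintf("  median clusters per image: %g-%g\n",
              min(object@cells), max(object@cells)))
})

#' Area of an alpha shape
#' @param object an [AlphaShape-class].
#' @param units `"nm2"` (native) or `"um2"`.
#' @return numeric(1).
#' @export
setGeneric("shapeArea", function(object, units = c("nm2", "um2"))
  standardGeneric("shapeArea"))

#' @rdname shapeArea
#' @export
setMethod("shapeArea", "AlphaShape", function(object, units = c("nm2", "um2")) {
  units <- match.arg(units)
  if (units == "um2") object@area / 1e6 else object@area
})

setMethod("show", "AlphaShape", function(object) {
  cat(sprintf("AlphaShape (alpha = %g nm^2): area %.1f nm^2, %d triangles%s\n",
              object@alpha, object@area, nrow(object@triangles),
              if (object@degenerate) " [degenerate]" else ""))
})

#' Alpha sweep as a data.frame
#' @param object an [AlphaSweepResult-class].
#' @return data.frame with columns alpha_nm2, median_um2, q25, q75,
#'   pct_increase.
#' @export
setGeneric("sweepAreas", function(object) standardGeneric("sweepAreas"))

#' @rdname sweepAreas
#' @export
setMethod("sweepAreas", "AlphaSweepResult", function(object) {
  data.frame(alpha_nm2 = object@alphas, median_um2 = object@medianArea,
             q25 = object@q25, q75 = object@q75,
             pct_increase = object@pctIncrease)
})

setMethod("show", "AlphaSweepResult", function(object) {
  cat(sprintf("AlphaSweepResult over %d clusters, %d alpha values (%g-%g nm^2)\n",
              object@nClusters, length(object@alphas), min(object@alphas),
              max(object@alphas)))
  cat(sprintf("  median area at largest alpha: %.4f um^2\n",
              object@medianArea[length(object@medianArea)]))
})

setMethod("show", "FieldSummary", function(object) {
  cat(sprintf("FieldSummary of %d receptor fields\n", object@nFields))
  cat(sprintf("  area um^2: median %.4f [q25 %.4f, q75 %.4f] (p10 %.4f, p90 %.4f)\n",
              object@area["median"], object@area["q25"], object@area["q75"],
              object@area["p10"], object@area["p90"]))
  cat(sprintf("  locs:      median %.1f [q25 %.1f, q75 %.1f] (p10 %.1f, p90 %.1f)\n",
              object@locs["median"], object@locs["q25"], object@locs["q75"],
              object@locs["p10"], object@locs["p90"]))
})

setMethod("show", "EphysCell", function(object) {
  cat(sprintf("EphysCell '%s': Vm %.1f mV, Rm %.1f MOhm\n",
              object@cellId, object@vm, object@rm))
  cat(sprintf("  %d mEPSCs at %g mV, %d eEPSCs at %g mV, %d paired-pulse traces\n",
              length(object@mepscAmps), object@holdM,
              length(object@eepscAmps), object@holdE, nrow(object@pprPairs)))
})

setMethod("show", "QuantalResult", function(object) {
  cat(sprintf("QuantalResult '%s': quantal content %.2f (eEPSC %.2f nA / scaled mEPSC %.3f nA)",
              object@cellId, object@quantalContent, object@meanEepsc,
              object@meanMepscScaled))
  if (!is.na(object@ppr)) cat(sprintf(", PPR %.2f", object@ppr))
  cat("\n")
})
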