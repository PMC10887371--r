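#' Build the receptor-field table from a clustering
#'
#' One row per cluster: localization count, alpha-shape area at the given
#' alpha (um^2), centroid, and a degeneracy flag for clusters whose points
#' were collinear (area 0).
#'
#' @param t the clustered [LocalizationTable-class].
#' @param cs the matching [ClusterSet-class].
#' @param alpha alpha-shape threshold in nm^2 (study value 9025).
#' @return data.frame with columns `roi_label, cluster_id, n_locs, area_um2,
#'   centroid_x, centroid_y, degenerate`.
#' @seealso [applyExclusion()], [summarizeFields()]
#' @export
receptorFields <- function(t, cs, alpha = 9025) {
  pts <- clusterPoints(t, cs)
  if (!length(pts))
    return(data.frame(roi_label = character(), cluster_id = integer(),
                      n_locs = integer(), area_um2 = numeric(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      degenerate = logical()))
  shapes <- lapply(pts, alphaShapeArea, alpha = alpha)
  data.frame(
    roi_label = roiLabel(cs),
    cluster_id = seq_along(pts) - 1L,
    n_locs = vapply(pts, nrow, integer(1)),
    area_um2 = vapply(shapes, function(s) s@area, numeric(1)) / 1e6,
    centroid_x = vapply(pts, function(p) mean(p[, 1]), numeric(1)),
    centroid_y = vapply(pts, function(p) mean(p[, 2]), numeric(1)),
    degenerate = vapply(shapes, function(s) s@degenerate, logical(1))
  )
}

#' Apply the area exclusion criteria
#'
#' Drops receptor fields with area at or below the lower bound or at or above
#' the upper bound (the reference criteria exclude area <= 0.03 um^2 and
#' >= 0.3 um^2, so both boundaries are themselves excluded). Row order is
#' preserved; the excluded rows are attached as an audit table in attribute
#' `"excluded"` with an `exclusion_reason` column, and the excluded count is
#' reported with a message.
#'
#' @param fields data.frame from [receptorFields()] (needs column `area_um2`).
#' @param lo,hi exclusion bounds in um^2 (defaults 0.03 and 0.3); survivors
#'   satisfy `lo < area_um2 < hi`.
#' @param quiet suppress the message.
#' @return the retained data.frame, with attribute `"excluded"`.
#' @examples
#' f <- data.frame(area_um2 = c(0.02, 0.03, 0.05, 0.15, 0.3, 0.4))
#' applyExclusion(f, quiet = TRUE)$area_um2  # 0.05 0.15
#' @export
applyExclusion <- function(fields, lo = 0.03, hi = 0.3, quiet = FALSE) {
  if (lo >= hi) stop("lo must be smaller than hi", call. = FALSE)
  stopifnot("area_um2" %in% names(fields))
  keep <- fields$area_um2 > lo & fields$area_um2 < hi
  excluded <- fields[!keep, , drop = FALSE]
  if (nrow(excluded))
    excluded$exclusion_reason <- ifelse(excluded$area_um2 <= lo,
                                        sprintf("area <= %g um^2", lo),
                                        sprintf("area >= %g um^2", hi))
  out <- fields[keep, , drop = FALSE]
  if (!quiet)
    message(sum(!keep), " of ", nrow(fields),
            " receptor fields excluded by area criteria")
  attr(out, "excluded") <- excluded
  out
}

#' Excluded-field audit table
#'
#' @param fields the result of [applyExclusion()].
#' @return the audit data.frame of excluded fields.
#' @export
exclusionAudit <- function(fields) attr(fields, "excluded")

## percentile with linear interpolation between order statistics
## (quantile type 7, the convention used throughout)
.pctl <- function(x, p) quantile(x, probs = p, names = FALSE, type = 7)

#' Summarise a receptor-field population
#'
#' Box-plot statistics of field area and localization count — median, 25th and
#' 75th percentiles, and 10th/90th-percentile whiskers, all by linear
#' interpolation between order statistics — plus an equal-width area
#' histogram normalized so that the bin heights sum to 1 (each height is the
#' fraction of observed fields in that bin).
#'
#' @param fields data.frame with columns `area_um2` and `n_locs`.
#' @param nBins number of histogram bins over the observed area range
#'   (default 20).
#' @return a [FieldSummary-class].
#' @export
summarizeFields <- function(fields, nBins = 20L) {
  if (!nrow(fields)) stop("no receptor fields to summarise", call. = FALSE)
  stopifnot(all(c("area_um2", "n_locs") %in% names(fields)), nBins >= 1L)
  a <- fields$area_um2; l <- fields$n_locs
  stats5 <- function(x) c(median = median(x), q25 = .pctl(x, 0.25),
                          q75 = .pctl(x, 0.75), p10 = .pctl(x, 0.10),
                          p90 = .pctl(x, 0.90))
  rng <- range(a)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(rng[1], 1e-6)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- graphics::hist(a, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  new("FieldSummary", nFields = nrow(fields), area = stats5(a),
      locs = stats5(as.numeric(l)), histBreaks = breaks,
      histHeights = counts / sum(counts))
}

#' Normalized histogram of an arbitrary sample
#'
#' Equal-width histogram whose heights are normalized to the total number of
#' observed events (heights sum to 1).
#'
#' @param x numeric sample.
#' @param nBins number of bins (default 20).
#' @return list with `breaks` and `heights`.
#' @export
normalizedHistogram <- function(x, nBins = 20L) {
  stopifnot(length(x) >= 1L, nBins >= 1L)
  rng <- range(x)
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5) * max(abs(rng[1]), 1e-6)
  breaks <- seq(rng[1], rng[2], length.out = nBins + 1L)
  counts <- graphics::hist(x, breaks = breaks, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  list(breaks = breaks, heights = counts / sum(counts))
}

#' Quantify receptor fields end to end
#'
#' The full analysis chain on one localization table: amplitude filter
#' (> 12,000 A/D counts), optional ROI clip, HDBSCAN clustering, alpha-shape
#' areas with the alpha chosen by the small-increase rule (or a fixed alpha),
#' and area exclusion.
#'
#' @param t a [LocalizationTable-class].
#' @param roi optional [RoiPolygon-class] to clip to.
#' @param params [ClusterParams-class] (default `clusterParams(40, 10)`).
#' @param alpha fixed alpha in nm^2, or `NULL` (default) to select it from
#'   the cluster population via [areaVsAlphaSweep()] and [selectAlpha()].
#' @param lo,hi exclusion bounds in um^2.
#' @param adThreshold amplitude threshold in A/D counts.
#' @param quiet suppress progress messages.
#' @return list with elements `fields` (retained receptor-field table),
#'   `allFields` (pre-exclusion table), `clusters` (the [ClusterSet-class]),
#'   `alpha` (the alpha used, nm^2) and `summary` (a [FieldSummary-class],
#'   or NULL if nothing survived exclusion).
#' @export
quantifyReceptorFields <- function(t, roi = NULL, params = clusterParams(),
                                   alpha = NULL, lo = 0.03, hi = 0.3,
                                   adThreshold = 12000, quiet = TRUE) {
  t <- filterByAdcount(t, adThreshold)
  if (!is.null(roi)) t <- clipToRoi(t, roi)
  cs <- extractClusters(t, params,
                        roiLabel = if (is.null(roi)) "roi" else roiLabel(roi))
  if (is.null(alpha)) {
    pts <- clusterPoints(t, cs)
    if (!length(pts)) stop("no clusters found; cannot select alpha",
                           call. = FALSE)
    alpha <- selectAlpha(areaVsAlphaSweep(pts))
  }
  all_fields <- receptorFields(t, cs, alpha = alpha)
  fields <- applyExclusion(all_fields, lo = lo, hi = hi, quiet = quiet)
  list(fields = fields, allFields = all_fields, clusters = cs, alpha = alpha,
       summary = if (nrow(fields)) summarizeFields(fields) else NULL)
}
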