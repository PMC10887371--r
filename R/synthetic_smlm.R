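#' GroundTruthCluster: a simulated receptor field
#'
#' Ground-truth specification of one simulated cluster: a planar shape
#' (disk, ellipse or polygon) holding a number of fluorophores, each of which
#' emits one or more localizations (blinks) jittered by an isotropic Gaussian
#' localization error.
#'
#' @slot shape `"disk"`, `"ellipse"` or `"polygon"`.
#' @slot center numeric(2), shape center in nm (ignored for polygons).
#' @slot radius numeric(1), disk radius in nm.
#' @slot axes numeric(2), ellipse semi-axes (a, b) in nm.
#' @slot angle numeric(1), ellipse rotation in radians.
#' @slot vertices two-column matrix of polygon vertices in nm.
#' @slot nFluorophores integer(1), number of fluorophore positions, >= 1.
#' @slot blinkMean numeric(1), mean localizations per fluorophore, >= 1.
#' @slot blinkDist `"geometric"` (counts on \{1, 2, ...\} with the stated
#'   mean, the minimal blinking model) or `"fixed"` (every fluorophore emits
#'   exactly `round(blinkMean)` localizations).
#' @slot sigma numeric(1), localization precision (nm, isotropic Gaussian sd).
#'
#' @seealso [diskCluster()], [truthArea()], [simulateScene()]
#' @exportClass GroundTruthCluster
setClass("GroundTruthCluster",
  representation(shape = "character", center = "numeric", radius = "numeric",
                 axes = "numeric", angle = "numeric", vertices = "matrix",
                 nFluorophores = "integer", blinkMean = "numeric",
                 blinkDist = "character", sigma = "numeric"),
  prototype(shape = "disk", center = c(0, 0), radius = 200,
            axes = c(200, 100), angle = 0,
            vertices = matrix(numeric(), ncol = 2),
            nFluorophores = 20L, blinkMean = 4, blinkDist = "geometric",
            sigma = 10)
)

setValidity("GroundTruthCluster", function(object) {
  msg <- character()
  if (!object@shape %in% c("disk", "ellipse", "polygon"))
    msg <- c(msg, "shape must be disk, ellipse or polygon")
  if (object@nFluorophores < 1L) msg <- c(msg, "nFluorophores must be >= 1")
  if (object@blinkMean < 1) msg <- c(msg, "blinkMean must be >= 1")
  if (!object@blinkDist %in% c("geometric", "fixed"))
    msg <- c(msg, "blinkDist must be 'geometric' or 'fixed'")
  if (object@sigma < 0) msg <- c(msg, "sigma must be >= 0")
  if (object@shape == "disk" && object@radius < 0)
    msg <- c(msg, "radius must be >= 0")
  if (object@shape == "ellipse" && any(object@axes < 0))
    msg <- c(msg, "ellipse axes must be >= 0")
  if (object@shape == "polygon" && nrow(object@vertices) < 3L)
    msg <- c(msg, "polygon clusters need >= 3 vertices")
  if (length(msg)) msg else TRUE
})

#' Construct a disk-shaped ground-truth cluster
#'
#' @param center cluster center (nm).
#' @param area disk area in um^2; mutually exclusive with `radius`.
#' @param radius disk radius in nm (used when `area` is missing).
#' @param nFluorophores fluorophores in the disk.
#' @param blinkMean mean blinks (localizations) per fluorophore.
#' @param blinkDist blink-count model, `"geometric"` (default) or `"fixed"`.
#' @param sigma localization precision (nm).
#' @return a [GroundTruthCluster-class].
#' @examples
#' diskCluster(c(1000, 1000), area = 0.15)  # radius ~218.5 nm
#' @export
diskCluster <- function(center, area = NULL, radius = NULL,
                        nFluorophores = 20L, blinkMean = 4,
                        blinkDist = c("geometric", "fixed"), sigma = 10) {
  if (is.null(radius)) {
    stopifnot(!is.null(area))
    radius <- sqrt(area * 1e6 / pi)
  }
  new("GroundTruthCluster", shape = "disk", center = as.numeric(center),
      radius = as.numeric(radius), nFluorophores = as.integer(nFluorophores),
      blinkMean = as.numeric(blinkMean), blinkDist = match.arg(blinkDist),
      sigma = as.numeric(sigma))
}

#' Construct an ellipse-shaped ground-truth cluster
#'
#' @param center cluster center (nm).
#' @param axes semi-axes (a, b) in nm.
#' @param angle rotation in radians.
#' @inheritParams diskCluster
#' @return a [GroundTruthCluster-class].
#' @export
ellipseCluster <- function(center, axes, angle = 0, nFluorophores = 20L,
                           blinkMean = 4, blinkDist = c("geometric", "fixed"),
                           sigma = 10) {
  new("GroundTruthCluster", shape = "ellipse", center = as.numeric(center),
      axes = as.numeric(axes), angle = as.numeric(angle),
      nFluorophores = as.integer(nFluorophores),
      blinkMean = as.numeric(blinkMean), blinkDist = match.arg(blinkDist),
      sigma = as.numeric(sigma))
}

#' Construct a polygon-shaped ground-truth cluster
#'
#' @param vertices two-column matrix of vertices (nm).
#' @inheritParams diskCluster
#' @return a [GroundTruthCluster-class].
#' @export
polygonCluster <- function(vertices, nFluorophores = 20L, blinkMean = 4,
                           blinkDist = c("geometric", "fixed"), sigma = 10) {
  v <- as.matrix(vertices); dimnames(v) <- NULL; storage.mode(v) <- "double"
  new("GroundTruthCluster", shape = "polygon", center = colMeans(v),
      vertices = v, nFluorophores = as.integer(nFluorophores),
      blinkMean = as.numeric(blinkMean), blinkDist = match.arg(blinkDist),
      sigma = as.numeric(sigma))
}

#' Analytic area of a ground-truth cluster
#'
#' pi r^2 for disks, pi a b for ellipses, the shoelace formula for polygons.
#'
#' @param c a [GroundTruthCluster-class].
#' @return area in um^2.
#' @examples
#' truthArea(diskCluster(c(0, 0), radius = 218.5))  # ~0.15 um^2
#' @export
setGeneric("truthArea", function(c) standardGeneric("truthArea"))

#' @rdname truthArea
#' @export
setMethod("truthArea", "GroundTruthCluster", function(c) {
  a_nm2 <- switch(c@shape,
    disk = pi * c@radius^2,
    ellipse = pi * c@axes[1] * c@axes[2],
    polygon = .shoelace(c@vertices))
  a_nm2 / 1e6
})

setMethod("show", "GroundTruthCluster", function(object) {
  cat(sprintf(
    "GroundTruthCluster (%s): area %.4f um^2, %d fluorophores x %.1f blinks, sigma %g nm\n",
    object@shape, truthArea(object), object@nFluorophores, object@blinkMean,
    object@sigma))
})

#' SyntheticScene: a simulated dSTORM acquisition
#'
#' A set of ground-truth clusters inside an ROI, a homogeneous Poisson
#' background, and the acquisition parameters needed to emit a
#' [LocalizationTable-class] with known per-localization origin.
#'
#' @slot clusters list of [GroundTruthCluster-class].
#' @slot backgroundDensity numeric(1), background localizations per um^2.
#' @slot roi a [RoiPolygon-class] containing the scene.
#' @slot seed integer(1); identical seed and parameters give bit-identical
#'   output.
#' @slot nFrames integer(1), acquisition frames (default 15000).
#' @slot adcountAboveFrac numeric(1) in \[0, 1\]: fraction of localizations
#'   drawn above the 12,000 A/D quality threshold (default 1, so the
#'   amplitude filter is a no-op unless a test lowers it).
#'
#' @seealso [syntheticScene()], [simulateScene()], [paperLikeScene()]
#' @exportClass SyntheticScene
setClass("SyntheticScene",
  representation(clusters = "list", backgroundDensity = "numeric",
                 roi = "RoiPolygon", seed = "integer", nFrames = "integer",
                 adcountAboveFrac = "numeric"),
  prototype(backgroundDensity = 0, seed = 1L, nFrames = 15000L,
            adcountAboveFrac = 1)
)

setValidity("SyntheticScene", function(object) {
  msg <- character()
  if (object@backgroundDensity < 0)
    msg <- c(msg, "backgroundDensity must be >= 0")
  if (object@adcountAboveFrac < 0 || object@adcountAboveFrac > 1)
    msg <- c(msg, "adcountAboveFrac must be in [0, 1]")
  if (!all(vapply(object@clusters, is, logical(1), "GroundTruthCluster")))
    msg <- c(msg, "clusters must be GroundTruthCluster objects")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticScene
#'
#' @param clusters list of [GroundTruthCluster-class] objects.
#' @param roi a [RoiPolygon-class]; background is sown uniformly inside it.
#' @param backgroundDensity background localizations per um^2 (default 0).
#' @param seed RNG seed (default 1).
#' @param nFrames acquisition frames (default 15000).
#' @param adcountAboveFrac fraction of amplitudes drawn above 12,000 A/D
#'   counts (default 1).
#' @return a [SyntheticScene-class].
#' @export
syntheticScene <- function(clusters, roi, backgroundDensity = 0, seed = 1L,
                           nFrames = 15000L, adcountAboveFrac = 1) {
  new("SyntheticScene", clusters = clusters, roi = roi,
      backgroundDensity = as.numeric(backgroundDensity),
      seed = as.integer(seed), nFrames = as.integer(nFrames),
      adcountAboveFrac = as.numeric(adcountAboveFrac))
}

setMethod("show", "SyntheticScene", function(object) {
  cat(sprintf(
    "SyntheticScene: %d clusters, background %g um^-2, ROI %.1f um^2, seed %d\n",
    length(object@clusters), object@backgroundDensity, roiArea(object@roi),
    object@seed))
})

## uniform sample inside a shape; returns n x 2 matrix (nm)
.sample_in_shape <- function(cl, n) {
  if (n == 0L) return(matrix(numeric(), ncol = 2))
  if (cl@shape == "disk") {
    r <- cl@radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(cl@center[1] + r * cos(th), cl@center[2] + r * sin(th))
  } else if (cl@shape == "ellipse") {
    r <- sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
    u <- r * cos(th) * cl@axes[1]; v <- r * sin(th) * cl@axes[2]
    ca <- cos(cl@angle); sa <- sin(cl@angle)
    cbind(cl@center[1] + u * ca - v * sa, cl@center[2] + u * sa + v * ca)
  } else {
    .sample_in_polygon(cl@vertices, n)
  }
}

## rejection sampling from a polygon's bounding box
.sample_in_polygon <- function(v, n) {
  out <- matrix(numeric(), ncol = 2)
  bx <- range(v[, 1]); by <- range(v[, 2])
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    px <- runif(m, bx[1], bx[2]); py <- runif(m, by[1], by[2])
    keep <- sp::point.in.polygon(px, py, v[, 1], v[, 2]) > 0L
    out <- rbind(out, cbind(px[keep], py[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

## blink counts: geometric on {1, 2, ...} with the requested mean, or fixed
.draw_blinks <- function(n, mean_blinks, dist = "geometric") {
  if (dist == "fixed") return(rep(as.integer(round(mean_blinks)), n))
  if (mean_blinks <= 1) return(rep(1L, n))
  rgeom(n, prob = 1 / mean_blinks) + 1L
}

#' Simulate a localization table from a synthetic scene
#'
#' Places each cluster's fluorophores uniformly inside its shape, draws a
#' geometric number of blinks per fluorophore, jitters every blink by the
#' cluster's isotropic Gaussian localization error, assigns random frames,
#' and adds a homogeneous Poisson background over the ROI. A/D counts are
#' drawn above 12,000 for a configurable fraction of localizations (all, by
#' default) and uniformly below for the rest. Output is bit-reproducible for
#' a fixed seed; the caller's RNG state is left untouched.
#'
#' @param scene a [SyntheticScene-class].
#' @return a list with elements
#'   \describe{
#'     \item{locs}{the emitted [LocalizationTable-class];}
#'     \item{truth}{data.frame `loc_index, cluster_id` mapping each row of
#'       `locs` to its generating cluster (1-based) or -1 for background.}
#'   }
#' @examples
#' roi <- roiPolygon(rbind(c(0, 0), c(4000, 0), c(4000, 4000), c(0, 4000)))
#' sc <- syntheticScene(list(diskCluster(c(2000, 2000), area = 0.15)), roi)
#' sim <- simulateScene(sc)
#' nLocs(sim$locs)
#' @export
simulateScene <- function(scene) {
  stopifnot(is(scene, "SyntheticScene"))
  validObject(scene)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(scene@seed)

  xs <- list(); ids <- list()
  for (k in seq_along(scene@clusters)) {
    cl <- scene@clusters[[k]]
    fl <- .sample_in_shape(cl, cl@nFluorophores)
    blinks <- .draw_blinks(cl@nFluorophores, cl@blinkMean, cl@blinkDist)
    pos <- fl[rep(seq_len(cl@nFluorophores), blinks), , drop = FALSE]
    if (cl@sigma > 0)
      pos <- pos + matrix(rnorm(2 * nrow(pos), sd = cl@sigma), ncol = 2)
    xs[[k]] <- pos
    ids[[k]] <- rep(k, nrow(pos))
  }
  nbg <- rpois(1, scene@backgroundDensity * roiArea(scene@roi))
  if (nbg > 0) {
    xs[[length(xs) + 1L]] <- .sample_in_polygon(roiVertices(scene@roi), nbg)
    ids[[length(ids) + 1L]] <- rep(-1L, nbg)
  }
  pos <- do.call(rbind, xs)
  if (is.null(pos) || nrow(pos) == 0L)
    stop("scene produced no localizations", call. = FALSE)
  id <- as.integer(unlist(ids))
  n <- nrow(pos)
  ## coordinates must stay non-negative under the image convention
  pos <- pmax(pos, 0)
  frame <- sample.int(scene@nFrames, n, replace = TRUE) - 1L
  above <- runif(n) < scene@adcountAboveFrac
  adc <- ifelse(above, runif(n, 12001, 30000), runif(n, 0, 12000))
  locs <- localizationTable(pos[, 1], pos[, 2], frame = frame, adcount = adc,
                            nFrames = scene@nFrames)
  list(locs = locs, truth = data.frame(loc_index = seq_len(n),
                                       cluster_id = id))
}

#' A study-condition scene preset
#'
#' Builds a scene mirroring the measured receptor-field statistics: cluster
#' areas log-normal with median 0.15 um^2 truncated to (0.03, 0.3) um^2,
#' about 80 localizations per cluster (20 fluorophores, mean 4 blinks),
#' 10 nm localization precision, and a sparse uniform background. Clusters
#' are laid out on a grid with 4 um pitch so neighbouring fields stay far
#' apart relative to their diameters.
#'
#' @param nClusters number of clusters (default 12).
#' @param seed RNG seed for both the area draws and the emission.
#' @param backgroundDensity background localizations per um^2 (default 1).
#' @param sdlog log-sd of the area distribution (default 0.4).
#' @param nFluorophores,blinkMean,sigma per-cluster emission parameters.
#' @return a [SyntheticScene-class].
#' @seealso [simulateScene()]
#' @export
paperLikeScene <- function(nClusters = 12L, seed = 1L, backgroundDensity = 1,
                           sdlog = 0.4, nFluorophores = 20L, blinkMean = 4,
                           sigma = 10) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  areas <- numeric(0)
  while (length(areas) < nClusters) {
    a <- exp(rnorm(2L * nClusters, log(0.15), sdlog))
    areas <- c(areas, a[a > 0.03 & a < 0.3])
  }
  areas <- areas[seq_len(nClusters)]
  pitch <- 4000
  ncol_grid <- ceiling(sqrt(nClusters))
  nrow_grid <- ceiling(nClusters / ncol_grid)
  k <- seq_len(nClusters) - 1L
  cx <- (k %% ncol_grid) * pitch + pitch / 2
  cy <- (k %/% ncol_grid) * pitch + pitch / 2
  clusters <- lapply(seq_len(nClusters), function(i)
    diskCluster(c(cx[i], cy[i]), area = areas[i],
                nFluorophores = nFluorophores, blinkMean = blinkMean,
                sigma = sigma))
  w <- ncol_grid * pitch; h <- nrow_grid * pitch
  roi <- roiPolygon(rbind(c(0, 0), c(w, 0), c(w, h), c(0, h)),
                    label = "synthetic")
  syntheticScene(clusters, roi, backgroundDensity = backgroundDensity,
                 seed = seed)
}

#' Write the ground-truth assignment table
#'
#' @param truth data.frame from [simulateScene()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTruth <- function(truth, path) {
  write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
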