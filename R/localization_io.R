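## Column-name synonyms accepted when mapping a header onto the canonical
## columns. rapidSTORM writes verbose names such as "Position-0-0" (x) and
## "Amplitude-0-0"; exported CSVs commonly use x_nm / y_nm.
.col_synonyms <- list(
  x = c("x", "x_nm", "x[nm]", "position-0-0", "position-0-0-nm", "pos_x"),
  y = c("y", "y_nm", "y[nm]", "position-1-0", "position-1-0-nm", "pos_y"),
  frame = c("frame", "frame_idx", "imagenumber-0-0", "t"),
  adcount = c("adcount", "amplitude", "amp", "amplitude-0-0", "a_d_count",
              "intensity")
)

.match_columns <- function(nms) {
  key <- tolower(gsub("[[:space:]]", "", nms))
  idx <- vapply(.col_synonyms, function(syn) {
    hit <- which(key %in% syn)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  missing <- names(idx)[is.na(idx)]
  if (length(missing))
    stop("localization table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  idx
}

#' Read a localization table
#'
#' Reads single-molecule localization tables in either a comma-separated
#' dialect with header (canonical columns `x_nm,y_nm,frame,adcount`, common
#' synonyms accepted) or a rapidSTORM-style whitespace-separated dialect whose
#' first line is a `#` comment naming the columns. Positions must be in nm.
#' Malformed rows (wrong field count or non-numeric values) are dropped with
#' a message; the number of rejected rows is attached as attribute
#' `"rejected"` to the returned object.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"rapidstorm_txt"`; `"auto"` (default) decides by
#'   inspecting the first line.
#' @param channelPx camera pixel size in nm/px recorded on the table.
#' @param nFrames number of acquisition frames (default 15000).
#' @return a [LocalizationTable-class]; row order of the file is preserved.
#' @seealso [writeLocalizations()], [filterByAdcount()]
#' @export
readLocalizations <- function(path, dialect = c("auto", "csv", "rapidstorm_txt"),
                              channelPx = 127, nFrames = 15000L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty localization file: ", path, call. = FALSE)
  if (dialect == "auto")
    dialect <- if (startsWith(trimws(lines[1]), "#")) "rapidstorm_txt" else "csv"

  if (dialect == "rapidstorm_txt") {
    if (!startsWith(trimws(lines[1]), "#"))
      stop("rapidstorm_txt dialect requires a '#' header line naming columns",
           call. = FALSE)
    header <- strsplit(trimws(sub("^#\\s*", "", lines[1])), "[[:space:]]+")[[1]]
    body <- lines[-1]
    fields <- strsplit(trimws(body), "[[:space:]]+")
  } else {
    header <- strsplit(lines[1], ",")[[1]]
    body <- lines[-1]
    fields <- strsplit(body, ",", fixed = TRUE)
  }
  header <- trimws(header)
  idx <- .match_columns(header)
  if (!length(body))
    stop("localization file has a header but no rows: ", path, call. = FALSE)

  ncol_expected <- length(header)
  ok <- lengths(fields) == ncol_expected
  vals <- matrix(NA_real_, nrow = length(fields), ncol = 4L)
  for (r in which(ok)) {
    v <- suppressWarnings(as.numeric(fields[[r]][idx]))
    vals[r, ] <- v
  }
  good <- ok & !apply(is.na(vals), 1L, any)
  rejected <- sum(!good)
  if (rejected)
    message(rejected, " malformed row(s) rejected while reading ", path)
  vals <- vals[good, , drop = FALSE]
  if (!nrow(vals)) stop("no valid localization rows in ", path, call. = FALSE)
  out <- localizationTable(x = vals[, 1], y = vals[, 2],
                           frame = as.integer(vals[, 3]), adcount = vals[, 4],
                           channelPx = channelPx, nFrames = nFrames)
  attr(out, "rejected") <- rejected
  out
}

#' Write a localization table
#'
#' Writes either the CSV dialect (header `x_nm,y_nm,frame,adcount`) or the
#' rapidSTORM-style whitespace dialect (`# x y frame adcount` comment header).
#' Coordinates are printed with 17 significant digits so that a read/write
#' round trip reproduces the table bit-exactly.
#'
#' @param t a [LocalizationTable-class].
#' @param path output file path.
#' @param dialect `"csv"` (default) or `"rapidstorm_txt"`.
#' @return `path`, invisibly.
#' @export
writeLocalizations <- function(t, path, dialect = c("csv", "rapidstorm_txt")) {
  dialect <- match.arg(dialect)
  stopifnot(is(t, "LocalizationTable"))
  num <- function(v) formatC(v, digits = 17, format = "g", width = 1)
  rows <- paste(num(t@x), num(t@y), t@frame, num(t@adcount),
                sep = if (dialect == "csv") "," else " ")
  header <- if (dialect == "csv") "x_nm,y_nm,frame,adcount" else
    "# x y frame adcount"
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Filter localizations by fitted amplitude
#'
#' Retains only localizations whose fluorescence amplitude is strictly above
#' the threshold ("over" 12,000 A/D counts in the reference protocol), the
#' quality gate applied before any spatial analysis. Row order is preserved.
#'
#' @param t a [LocalizationTable-class].
#' @param threshold A/D count threshold (default 12000); rows with
#'   `adcount > threshold` survive.
#' @return the filtered [LocalizationTable-class].
#' @examples
#' t <- localizationTable(1:3, 1:3, adcount = c(11999, 12000, 12001))
#' nLocs(filterByAdcount(t))  # 1
#' @export
filterByAdcount <- function(t, threshold = 12000) {
  stopifnot(is(t, "LocalizationTable"), threshold >= 0)
  t[t@adcount > threshold]
}

#' Clip localizations to an ROI polygon
#'
#' Keeps localizations lying inside the polygon; points exactly on an edge or
#' vertex are retained. Containment is evaluated with the even-odd rule via
#' [sp::point.in.polygon()].
#'
#' @param t a [LocalizationTable-class].
#' @param roi a [RoiPolygon-class].
#' @return the clipped [LocalizationTable-class] (row order preserved).
#' @export
clipToRoi <- function(t, roi) {
  stopifnot(is(t, "LocalizationTable"), is(roi, "RoiPolygon"))
  validObject(roi)
  v <- roi@vertices
  inside <- sp::point.in.polygon(t@x, t@y, v[, 1], v[, 2]) > 0L
  t[inside]
}

#' Render a binned localization-count image
#'
#' Reconstructs the 2D histogram image used for ROI annotation. Bins are
#' half-open intervals `[k*px, (k+1)*px)` relative to the origin, so a
#' localization at exactly 10 nm with 10 nm bins falls in bin index 1.
#'
#' @param t a non-empty [LocalizationTable-class].
#' @param px bin edge length in nm (default 10).
#' @param origin nm position of the top-left grid corner (default `c(0, 0)`).
#' @param dim optional `c(nrow, ncol)` grid size; by default the grid is just
#'   large enough to contain every localization.
#' @return a [BinnedImage-class]; the grid total equals the number of
#'   localizations inside the grid extent.
#' @export
renderBinned <- function(t, px = 10, origin = c(0, 0), dim = NULL) {
  stopifnot(is(t, "LocalizationTable"), px > 0)
  if (length(t) == 0L) stop("cannot render an empty localization table",
                            call. = FALSE)
  j <- floor((t@x - origin[1]) / px)   # column (x)
  i <- floor((t@y - origin[2]) / px)   # row (y)
  if (is.null(dim)) {
    keep <- i >= 0 & j >= 0
    dim <- c(max(i[keep]) + 1L, max(j[keep]) + 1L)
  }
  keep <- i >= 0 & j >= 0 & i < dim[1] & j < dim[2]
  counts <- matrix(0L, nrow = dim[1], ncol = dim[2])
  if (any(keep)) {
    tab <- table(i[keep] * dim[2] + j[keep])
    flat <- as.integer(names(tab))
    counts[cbind(flat %/% dim[2] + 1L, flat %% dim[2] + 1L)] <- as.integer(tab)
  }
  new("BinnedImage", counts = counts, px = px, origin = as.numeric(origin))
}

#' Convert pixel coordinates to nm
#'
#' @param coords numeric vector, matrix or data.frame of pixel coordinates.
#' @param px pixel size in nm per pixel (127/130 nm for the camera channels,
#'   10 nm for reconstructed images).
#' @return coordinates multiplied by `px`.
#' @examples
#' pxToNm(c(2, 3), 127)  # 254 381
#' @export
pxToNm <- function(coords, px) {
  stopifnot(px > 0)
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  coords * px
}

#' Convert nm coordinates to pixels
#'
#' Exact inverse of [pxToNm()]; returns continuous pixel coordinates.
#'
#' @inheritParams pxToNm
#' @export
nmToPx <- function(coords, px) {
  stopifnot(px > 0)
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  coords / px
}

#' Read ROI polygons from CSV
#'
#' Expects columns `label, vertex_index, x, y` and optionally `units`
#' (`"nm"` or `"px"`, default nm). Vertices with the same label form one
#' polygon, ordered by `vertex_index`.
#'
#' @param path CSV file path.
#' @param sourcePx pixel size (nm/px) used to convert `"px"` vertices.
#' @return a named list of [RoiPolygon-class] objects.
#' @seealso [writeRois()]
#' @export
readRois <- function(path, sourcePx = 10) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "vertex_index", "x", "y")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("ROI file is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"units" %in% names(df)) df$units <- "nm"
  out <- lapply(split(df, df$label), function(d) {
    d <- d[order(d$vertex_index), ]
    roiPolygon(cbind(d$x, d$y), label = d$label[1],
               units = if (d$units[1] == "px") "px" else "nm",
               sourcePx = sourcePx)
  })
  out[unique(df$label)]
}

#' Write ROI polygons to CSV
#'
#' @param rois a list of [RoiPolygon-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeRois <- function(rois, path) {
  if (is(rois, "RoiPolygon")) rois <- list(rois)
  df <- do.call(rbind, lapply(rois, function(r) {
    v <- r@vertices
    data.frame(label = r@label, vertex_index = seq_len(nrow(v)),
               x = v[, 1], y = v[, 2], units = "nm")
  }))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
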