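#' @title Cell-count-based tumour purity
#' @description Purity is the tumour cell fraction among all detected
#'   cells inside pathologist-marked regions of interest, on a 0-100%
#'   scale. Coordinates are planar microns (0.5 microns/pixel frame).
#' @name purity
NULL

.class_synonyms <- c(
  tumour = "tumour", tumor = "tumour", tc = "tumour",
  background = "background", bc = "background",
  "non-tumour" = "background", "non-tumor" = "background",
  nontumour = "background", nontumor = "background")

#' Read a cell-detection table
#'
#' CSV with header `x,y,class,confidence`. Class labels are matched
#' case-insensitively against the synonyms tumour/tumor/tc and
#' background/bc/non-tumour; non-canonical labels are normalised with a
#' message.
#'
#' @param path Path to the CSV.
#' @return Data frame with columns `x`, `y`, `cls` (factor
#'   tumour/background), `confidence`.
#' @export
read_detections <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y", "class", "confidence")
  if (!all(need %in% names(df)))
    stop("detection file must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  raw <- tolower(trimws(df$class))
  cls <- unname(.class_synonyms[raw])
  if (anyNA(cls))
    stop("unknown detection class label(s): ",
         paste(unique(raw[is.na(cls)]), collapse = ", "), call. = FALSE)
  if (!all(raw %in% c("tumour", "background")))
    message("normalised non-canonical class labels: ",
            paste(setdiff(unique(raw), c("tumour", "background")),
                  collapse = ", "))
  if (any(df$confidence < 0 | df$confidence > 1))
    stop("confidence must be in [0, 1]", call. = FALSE)
  data.frame(x = as.numeric(df$x), y = as.numeric(df$y),
             cls = factor(cls, levels = c("tumour", "background")),
             confidence = as.numeric(df$confidence))
}

# shoelace area of one ring (n x 2 matrix), unsigned
.ring_area <- function(ring) {
  x <- ring[, 1L]; y <- ring[, 2L]
  n <- nrow(ring)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

.validate_ring <- function(ring) {
  ring <- as.matrix(ring)
  if (ncol(ring) != 2L || nrow(ring) < 3L)
    stop("polygon ring must be an n x 2 matrix with n >= 3", call. = FALSE)
  # drop an explicit closing vertex
  if (all(ring[1L, ] == ring[nrow(ring), ])) ring <- ring[-nrow(ring), , drop = FALSE]
  if (nrow(ring) < 3L) stop("degenerate polygon ring", call. = FALSE)
  ring
}

#' Construct a region-of-interest set
#'
#' @param polygons A list of polygons; each polygon is either an n x 2
#'   coordinate matrix (outer ring) or a list of rings (first outer,
#'   rest holes). Coordinates in microns.
#' @return A `roi_set` with elements `polygons` and `area_mm2` (union
#'   area assuming disjoint outer rings; holes subtracted).
#' @export
roi_set <- function(polygons) {
  if (length(polygons) == 0L) stop("empty RoiSet", call. = FALSE)
  polygons <- lapply(polygons, function(p) {
    if (is.list(p) && !is.data.frame(p)) lapply(p, .validate_ring)
    else list(.validate_ring(p))
  })
  area <- sum(vapply(polygons, function(rings) {
    a <- vapply(rings, .ring_area, 0)
    a[1L] - sum(a[-1L])
  }, 0))
  if (area <= 0) stop("RoiSet area must be > 0", call. = FALSE)
  structure(list(polygons = polygons, area_mm2 = area / 1e6),
            class = "roi_set")
}

#' Read ROIs from a GeoJSON FeatureCollection
#'
#' Accepts Polygon and MultiPolygon features in the detection coordinate
#' frame (microns).
#'
#' @param path Path to the GeoJSON file.
#' @return A `roi_set`.
#' @export
read_roi_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  polys <- list()
  for (f in feats) {
    g <- if (!is.null(f$geometry)) f$geometry else f
    ring_mat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (identical(g$type, "Polygon")) {
      polys[[length(polys) + 1L]] <- lapply(g$coordinates, ring_mat)
    } else if (identical(g$type, "MultiPolygon")) {
      for (p in g$coordinates)
        polys[[length(polys) + 1L]] <- lapply(p, ring_mat)
    } else {
      stop("unsupported GeoJSON geometry: ", g$type, call. = FALSE)
    }
  }
  roi_set(polys)
}

# Vectorised even-odd ray casting with inclusive boundaries.
# Returns logical vector over points; a point on any edge counts inside.
.points_in_rings <- function(x, y, rings, tol = 1e-9) {
  inside <- rep(FALSE, length(x))
  boundary <- rep(FALSE, length(x))
  for (ring in rings) {
    xi <- ring[, 1L]; yi <- ring[, 2L]
    n <- length(xi)
    xj <- xi[c(n, seq_len(n - 1L))]; yj <- yi[c(n, seq_len(n - 1L))]
    for (k in seq_len(n)) {
      x1 <- xj[k]; y1 <- yj[k]; x2 <- xi[k]; y2 <- yi[k]
      # boundary: point within the edge's bounding box and collinear
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      scale <- max(abs(c(x1, x2, y1, y2)), 1)
      on_edge <- abs(cross) <= tol * scale &
        x >= pmin(x1, x2) - tol & x <= pmax(x1, x2) + tol &
        y >= pmin(y1, y2) - tol & y <= pmax(y1, y2) + tol
      boundary <- boundary | on_edge
      # even-odd crossing of a rightward ray
      crosses <- ((y1 > y) != (y2 > y)) &
        (x < (x2 - x1) * (y - y1) / (y2 - y1) + x1)
      inside <- xor(inside, crosses)
    }
  }
  inside | boundary
}

#' Test which detections fall inside an ROI set
#'
#' Membership is the union over polygons; inside each polygon the
#' even-odd rule is applied over its rings, so holes are excluded.
#' Boundary points count as inside.
#'
#' @param detections Detection data frame (`x`, `y`, ...).
#' @param rois A `roi_set`.
#' @return Logical vector, one element per detection.
#' @export
points_in_roi <- function(detections, rois) {
  stopifnot(inherits(rois, "roi_set"))
  inside <- rep(FALSE, nrow(detections))
  for (rings in rois$polygons)
    inside <- inside | .points_in_rings(detections$x, detections$y, rings)
  inside
}

#' Count tumour and background cells inside the ROI
#'
#' @param detections Detection data frame as from [read_detections()].
#' @param rois A `roi_set`; counting is restricted to its union.
#' @param slide_id Identifier for the slide.
#' @param min_confidence Detections below this confidence are dropped
#'   before counting (default 0: the detector's own post-processing is
#'   trusted).
#' @return One-row data frame: `slide_id`, `tc`, `bc`, `area_mm2`,
#'   `density` (cells/mm^2 inside the ROI).
#' @export
count_cells_in_roi <- function(detections, rois, slide_id,
                               min_confidence = 0) {
  stopifnot(inherits(rois, "roi_set"))
  detections <- detections[detections$confidence >= min_confidence, ,
                           drop = FALSE]
  keep <- if (nrow(detections)) points_in_roi(detections, rois) else logical(0)
  tc <- sum(keep & detections$cls == "tumour")
  bc <- sum(keep & detections$cls == "background")
  if (tc + bc == 0L)
    warning("no detections inside ROI for slide ", slide_id, call. = FALSE)
  data.frame(slide_id = as.character(slide_id), tc = tc, bc = bc,
             area_mm2 = rois$area_mm2,
             density = (tc + bc) / rois$area_mm2,
             stringsAsFactors = FALSE)
}

#' Tumour purity from cell counts
#'
#' Purity in percent: 100 * TC / (TC + BC), the tumour cell count
#' divided by the total cell count.
#'
#' @param tc Tumour cell count(s), or a summary data frame from
#'   [count_cells_in_roi()] (then `bc` is ignored).
#' @param bc Background cell count(s).
#' @return Purity in percent, in \[0, 100\]. Vectorised.
#' @export
#' @examples
#' tumour_purity(60, 40)  # 60
tumour_purity <- function(tc, bc) {
  if (is.data.frame(tc)) { bc <- tc$bc; tc <- tc$tc }
  if (any(tc < 0 | bc < 0)) stop("cell counts must be >= 0", call. = FALSE)
  if (any(tc + bc == 0))
    stop("undefined purity: no cells counted (TC + BC = 0)", call. = FALSE)
  100 * tc / (tc + bc)
}

#' Paired-slide purity concordance
#'
#' Pearson correlation (with Fisher-z 95% CI) between purity estimates
#' from two serial sections of the same blocks.
#'
#' @param values_a,values_b Matched numeric vectors of purities
#'   (percent). If both are named, they are aligned by name and any
#'   mismatch is an error listing the missing sample IDs.
#' @return A `pearson_ci` result (see [pearson_ci()]).
#' @export
paired_slide_concordance <- function(values_a, values_b) {
  if (!is.null(names(values_a)) && !is.null(names(values_b))) {
    miss_a <- setdiff(names(values_b), names(values_a))
    miss_b <- setdiff(names(values_a), names(values_b))
    if (length(miss_a) || length(miss_b))
      stop("unmatched sample IDs; missing from a: ",
           paste(miss_a, collapse = ", "), "; missing from b: ",
           paste(miss_b, collapse = ", "), call. = FALSE)
    values_b <- values_b[names(values_a)]
  }
  if (length(values_a) != length(values_b))
    stop("paired purity vectors must have equal length", call. = FALSE)
  pearson_ci(values_a, values_b)
}
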