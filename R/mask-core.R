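#' @useDynLib amodalgrape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn .data
NULL

# ---- binary mask basics -----------------------------------------------------

#' Coerce to a binary mask
#'
#' Masks are plain integer matrices with values in \{0, 1\}, indexed
#' `[row, col]` with row 1 at the top (y grows downward). All pixel
#' coordinates in the package are 0-based; boxes are half-open.
#'
#' @param x A logical, integer or numeric matrix.
#' @return An integer matrix of 0s and 1s.
#' @export
as_mask <- function(x) {
  if (!is.matrix(x)) abort("a mask must be a matrix")
  if (is.logical(x)) return(matrix(as.integer(x), nrow(x), ncol(x)))
  v <- as.numeric(x)
  if (any(is.na(v)) || any(v != 0 & v != 1)) {
    abort("mask values must be exactly 0 or 1")
  }
  matrix(as.integer(x), nrow(x), ncol(x))
}

mask_area <- function(m) sum(m != 0)

check_same_shape <- function(a, b) {
  if (nrow(a) != nrow(b) || ncol(a) != ncol(b)) {
    abort(sprintf(
      "mask shapes differ: %dx%d vs %dx%d",
      nrow(a), ncol(a), nrow(b), ncol(b)
    ))
  }
}

#' Tight bounding box of a mask
#'
#' @param m A binary mask.
#' @return Named numeric vector `c(x0, y0, x1, y1)`, 0-based, half-open
#'   (`[x0, x1) x [y0, y1)`), or `NULL` for an empty mask.
#' @export
mask_bbox <- function(m) {
  m <- as_mask(m)
  idx <- which(m != 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(NULL)
  c(
    x0 = min(idx[, 2]) - 1, y0 = min(idx[, 1]) - 1,
    x1 = max(idx[, 2]), y1 = max(idx[, 1])
  )
}

bbox_diagonal <- function(bb) sqrt((bb["x1"] - bb["x0"])^2 + (bb["y1"] - bb["y0"])^2)

bbox_intersects <- function(a, b) {
  a["x0"] < b["x1"] && b["x0"] < a["x1"] && a["y0"] < b["y1"] && b["y0"] < a["y1"]
}

# Crop a matrix by a half-open 0-based box, clipped to the image.
crop_box <- function(m, box) {
  x0 <- max(0, floor(box[["x0"]])); y0 <- max(0, floor(box[["y0"]]))
  x1 <- min(ncol(m), ceiling(box[["x1"]])); y1 <- min(nrow(m), ceiling(box[["y1"]]))
  if (x1 <= x0 || y1 <= y0) return(NULL)
  m[(y0 + 1):y1, (x0 + 1):x1, drop = FALSE]
}

# ---- bilinear resize --------------------------------------------------------

# Interpolation weight matrix mapping `n` source samples to `t` output
# samples, evaluated at output pixel centers: src = (i + 0.5) * n / t - 0.5,
# clamped to [0, n - 1].
bilinear_weights <- function(n, t) {
  src <- pmin(pmax(((seq_len(t) - 0.5) * n / t) - 0.5, 0), n - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n - 1)
  w <- matrix(0, t, n)
  w[cbind(seq_len(t), lo + 1)] <- w[cbind(seq_len(t), lo + 1)] + (1 - frac)
  w[cbind(seq_len(t), hi + 1)] <- w[cbind(seq_len(t), hi + 1)] + frac
  w
}

# Continuous-valued bilinear resample of a numeric matrix.
bilinear_resample <- function(m, target_h, target_w) {
  ry <- bilinear_weights(nrow(m), target_h)
  rx <- bilinear_weights(ncol(m), target_w)
  ry %*% m %*% t(rx)
}

#' Resize a binary mask by bilinear interpolation
#'
#' The downsampling (D) and upsampling (U) operators used throughout the
#' incoherent-region machinery. The mask is bilinearly resampled at output
#' pixel centers and binarized at 0.5, with ties counted as foreground.
#'
#' @param m A binary mask.
#' @param target_h,target_w Output size in pixels (>= 1).
#' @return A binary mask of size `target_h` x `target_w`.
#' @export
resize_mask <- function(m, target_h, target_w) {
  m <- as_mask(m)
  if (target_h < 1 || target_w < 1) abort("target size must be >= 1")
  if (target_h == nrow(m) && target_w == ncol(m)) return(m)
  v <- bilinear_resample(m, target_h, target_w)
  matrix(as.integer(v >= 0.5), target_h, target_w)
}

# Nearest-neighbour resize for label maps (ids must not be interpolated).
resize_labels <- function(labels, target_h, target_w) {
  src_y <- pmin(pmax(round(((seq_len(target_h) - 0.5) * nrow(labels) / target_h) + 0.5), 1), nrow(labels))
  src_x <- pmin(pmax(round(((seq_len(target_w) - 0.5) * ncol(labels) / target_w) + 0.5), 1), ncol(labels))
  labels[src_y, src_x, drop = FALSE]
}

# ---- metrics ----------------------------------------------------------------

metric_result <- function(value, kind, d = NA_real_) {
  tibble::tibble(metric = kind, value = value, d = d)
}

#' Plain intersection-over-union of two masks
#'
#' @param a,b Binary masks of equal shape.
#' @return A one-row tibble with columns `metric`, `value`, `d`. Two empty
#'   masks score 1 (perfect agreement).
#' @export
plain_iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  un <- sum(a | b)
  value <- if (un == 0) 1 else sum(a & b) / un
  metric_result(value, "iou")
}

#' Amodal IoU between a ground-truth complete mask and a prediction
#'
#' IoU between the predicted amodal mask of an occluded instance and its
#' ground-truth complete mask; values near 1 indicate accurate completion.
#'
#' @param ga Ground-truth amodal (complete) mask.
#' @param pa Predicted amodal mask, same shape.
#' @return A one-row tibble with columns `metric`, `value`, `d`.
#' @export
amodal_iou <- function(ga, pa) {
  r <- plain_iou(ga, pa)
  r$metric <- "amodal_iou"
  r
}

# Inner boundary band of a mask: pixels of m whose Euclidean distance to the
# nearest background pixel (within the frame) is <= d. A mask with no
# background has an empty band.
mask_inner_band <- function(m, d) {
  if (!any(m == 0)) return(matrix(0L, nrow(m), ncol(m)))
  dm <- EBImage::distmap(m, metric = "euclidean")
  matrix(as.integer(m != 0 & dm <= d), nrow(m), ncol(m))
}

#' Boundary IoU of a ground-truth and predicted mask
#'
#' IoU restricted to the inner boundary bands of both masks: the band of a
#' mask X is the set of pixels of X within Euclidean distance `d` of X's
#' outer contour. With `d` at least the image diagonal this reduces to the
#' plain IoU.
#'
#' @param g Ground-truth mask.
#' @param p Predicted mask, same shape.
#' @param d Band width in pixels (>= 1), or `"auto"` for 2% of the
#'   ground-truth instance's bounding-box diagonal (floor 1 px).
#' @return A one-row tibble with columns `metric`, `value`, `d`.
#' @export
boundary_iou <- function(g, p, d = "auto") {
  g <- as_mask(g); p <- as_mask(p)
  check_same_shape(g, p)
  if (identical(d, "auto")) {
    bb <- mask_bbox(g)
    d <- if (is.null(bb)) 1 else max(1, round(0.02 * bbox_diagonal(bb)))
  }
  if (!is.numeric(d) || d < 1) abort("d must be >= 1 or \"auto\"")
  if (mask_area(g) == 0 && mask_area(p) == 0) {
    return(metric_result(1, "boundary_iou", d))
  }
  gb <- mask_inner_band(g, d)
  pb <- mask_inner_band(p, d)
  un <- sum(gb | pb)
  value <- if (un == 0) 1 else sum(gb & pb) / un
  metric_result(value, "boundary_iou", d)
}

#' Boundary mask via a 3x3 Laplacian
#'
#' The boundary-supervision baseline: pixels of the mask with a nonzero
#' response under the 4-neighbour 3x3 Laplacian kernel, i.e. the
#' one-pixel-wide inner perimeter.
#'
#' @param m A binary mask.
#' @return A binary mask of the same shape marking boundary pixels of `m`.
#' @export
laplacian_boundary <- function(m) {
  m <- as_mask(m)
  h <- nrow(m); w <- ncol(m)
  if (h == 0 || w == 0 || mask_area(m) == 0) return(m)
  # zero-padded shifts; Laplacian response = up + down + left + right - 4*center
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  resp <- pad[1:h, 2:(w + 1)] + pad[3:(h + 2), 2:(w + 1)] +
    pad[2:(h + 1), 1:w] + pad[2:(h + 1), 3:(w + 2)] - 4L * m
  matrix(as.integer(resp != 0 & m != 0), h, w)
}

# ---- tidy evaluation interface ----------------------------------------------

#' Evaluate mask metrics over a table of instance pairs
#'
#' @param pairs A data frame with columns `instance_id`, `gt` and `pred`
#'   (list-columns of binary masks).
#' @param metrics Character vector among `"iou"`, `"boundary_iou"`,
#'   `"amodal_iou"`.
#' @param d Band width passed to [boundary_iou()].
#' @return A tibble with one row per instance and metric:
#'   `instance_id`, `metric`, `value`, `d`.
#' @export
mask_metrics <- function(pairs, metrics = c("iou", "boundary_iou", "amodal_iou"),
                         d = "auto") {
  metrics <- match.arg(metrics, several.ok = TRUE)
  purrr::pmap_dfr(
    list(pairs$instance_id, pairs$gt, pairs$pred),
    function(id, g, p) {
      res <- purrr::map_dfr(metrics, function(k) {
        switch(k,
          iou = plain_iou(g, p),
          boundary_iou = boundary_iou(g, p, d),
          amodal_iou = amodal_iou(g, p)
        )
      })
      dplyr::mutate(res, instance_id = id, .before = 1)
    }
  )
}

#' Write metric records as JSON
#'
#' @param metrics A tibble from [mask_metrics()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  atomic_write(path, function(tmp) {
    jsonlite::write_json(metrics, tmp, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  })
  invisible(path)
}
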