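# Annotation I/O: LabelMe polygon JSON, COCO instance JSON, polygon
# rasterization, and the instance-pool builder. Polygon coordinates are
# continuous; rasterization uses even-odd scanline filling sampled at pixel
# centers, 0-based output.

#' Rasterize a polygon to a binary mask
#'
#' Even-odd fill evaluated at pixel centers `(col + 0.5, row + 0.5)`.
#'
#' @param vertices An `n x 2` matrix of `(x, y)` coordinates (continuous,
#'   0-based).
#' @param h,w Output mask size.
#' @return A binary mask.
#' @export
rasterize_polygon <- function(vertices, h, w) {
  m <- matrix(0L, h, w)
  if (is.null(vertices) || nrow(vertices) < 3) return(m)
  vx <- vertices[, 1]; vy <- vertices[, 2]
  n <- length(vx)
  nxt <- c(2:n, 1)
  for (i in seq_len(h)) {
    yc <- i - 0.5
    cross <- (vy > yc) != (vy[nxt] > yc)
    if (!any(cross)) next
    a <- which(cross)
    xint <- vx[a] + (yc - vy[a]) * (vx[nxt][a] - vx[a]) / (vy[nxt][a] - vy[a])
    xint <- sort(xint)
    for (k in seq_len(length(xint) %/% 2)) {
      lo <- xint[2 * k - 1]; hi <- xint[2 * k]
      j_lo <- max(0, ceiling(lo - 0.5 + 1e-9))
      j_hi <- min(w - 1, floor(hi - 0.5 - 1e-9))
      if (j_lo <= j_hi) m[i, (j_lo + 1):(j_hi + 1)] <- 1L
    }
  }
  m
}

polygon_area <- function(vertices) {
  x <- vertices[, 1]; y <- vertices[, 2]
  n <- nrow(vertices)
  nxt <- c(2:n, 1)
  abs(sum(x * y[nxt] - x[nxt] * y)) / 2
}

#' Read LabelMe polygon annotations
#'
#' One record per polygon shape; non-polygon shapes are skipped with a
#' warning. Coordinates outside the image bounds are clipped with a
#' warning.
#'
#' @param path Path to a LabelMe JSON file.
#' @return A tibble with columns `image_path`, `instance_id`, `label`,
#'   `complete` (shape flag, default `TRUE`), `polygon` (list of `n x 2`
#'   matrices), `image_height`, `image_width`.
#' @export
read_labelme <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("malformed JSON in %s: %s", path, conditionMessage(e)))
  )
  h <- doc$imageHeight %||% NA_integer_
  w <- doc$imageWidth %||% NA_integer_
  shapes <- doc$shapes %||% list()
  rows <- list()
  for (k in seq_along(shapes)) {
    sh <- shapes[[k]]
    if (!identical(sh$shape_type %||% "polygon", "polygon")) {
      warn(sprintf("skipping non-polygon shape %d (%s) in %s",
                   k, sh$shape_type %||% "?", path))
      next
    }
    pts <- do.call(rbind, lapply(sh$points, function(p) c(p[[1]], p[[2]])))
    if (!is.na(w) && (any(pts[, 1] < 0 | pts[, 1] > w) ||
                      any(pts[, 2] < 0 | pts[, 2] > h))) {
      warn(sprintf("clipping out-of-bounds polygon %d in %s", k, path))
      pts[, 1] <- pmin(pmax(pts[, 1], 0), w)
      pts[, 2] <- pmin(pmax(pts[, 2], 0), h)
    }
    flags <- sh$flags %||% list()
    rows[[length(rows) + 1]] <- tibble::tibble(
      image_path = doc$imagePath %||% NA_character_,
      instance_id = length(rows) + 1L,
      label = sh$label %||% "instance",
      complete = isTRUE(flags$complete) || length(flags) == 0,
      polygon = list(pts),
      image_height = as.integer(h), image_width = as.integer(w)
    )
  }
  if (length(rows) == 0) {
    return(tibble::tibble(
      image_path = character(), instance_id = integer(), label = character(),
      complete = logical(), polygon = list(),
      image_height = integer(), image_width = integer()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Rasterize annotation records into an instance label map
#'
#' Later shapes paint over earlier ones, matching LabelMe layering.
#'
#' @param records A tibble from [read_labelme()] (or compatible).
#' @param h,w Label map size; defaults to the records' image size.
#' @return An integer matrix, 0 = background, k = `instance_id`.
#' @export
records_to_label_map <- function(records, h = NULL, w = NULL) {
  h <- h %||% records$image_height[1]
  w <- w %||% records$image_width[1]
  labels <- matrix(0L, h, w)
  for (k in seq_len(nrow(records))) {
    m <- rasterize_polygon(records$polygon[[k]], h, w)
    labels[m != 0] <- records$instance_id[k]
  }
  labels
}

# ---- COCO -------------------------------------------------------------------

#' Convert between half-open boxes and COCO boxes
#'
#' The package's boxes are 0-based half-open `c(x0, y0, x1, y1)`; COCO
#' boxes are `[x, y, w, h]`.
#'
#' @param bbox A half-open box or a COCO box.
#' @return The converted box.
#' @export
bbox_to_coco <- function(bbox) {
  c(bbox[["x0"]], bbox[["y0"]], bbox[["x1"]] - bbox[["x0"]], bbox[["y1"]] - bbox[["y0"]])
}

#' @rdname bbox_to_coco
#' @export
coco_to_bbox <- function(bbox) {
  c(x0 = bbox[1], y0 = bbox[2], x1 = bbox[1] + bbox[3], y1 = bbox[2] + bbox[4])
}

#' Write annotation records as COCO instance JSON
#'
#' @param records A tibble of annotation records (see [read_labelme()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(records, path) {
  imgs <- unique(records[c("image_path", "image_height", "image_width")])
  imgs$id <- seq_len(nrow(imgs))
  images <- purrr::pmap(imgs, function(image_path, image_height, image_width, id) {
    list(id = id, file_name = image_path, height = image_height, width = image_width)
  })
  annotations <- purrr::pmap(
    list(records$instance_id, records$image_path, records$polygon,
         records$label, records$complete),
    function(iid, ipath, poly, label, complete) {
      img_id <- imgs$id[match(ipath, imgs$image_path)]
      xs <- poly[, 1]; ys <- poly[, 2]
      bb <- c(x0 = min(xs), y0 = min(ys), x1 = max(xs), y1 = max(ys))
      list(
        id = iid, image_id = img_id, category_id = 1L,
        segmentation = list(as.numeric(t(poly))),
        bbox = as.numeric(bbox_to_coco(bb)),
        area = polygon_area(poly), iscrowd = 0L,
        attributes = list(label = label, complete = complete)
      )
    }
  )
  doc <- list(
    images = images,
    annotations = annotations,
    categories = list(list(id = 1L, name = "grape_cluster"))
  )
  atomic_write(path, function(tmp) {
    jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(path)
}

#' Read COCO instance JSON into annotation records
#'
#' @param path Path to a COCO JSON file.
#' @return A tibble of annotation records.
#' @export
read_coco <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) abort(sprintf("malformed JSON in %s: %s", path, conditionMessage(e)))
  )
  for (field in c("images", "annotations")) {
    if (is.null(doc[[field]])) abort(sprintf("COCO schema violation: missing \"%s\"", field))
  }
  imgs <- purrr::map_dfr(doc$images, function(im) {
    for (field in c("id", "height", "width")) {
      if (is.null(im[[field]])) {
        abort(sprintf("COCO schema violation: image missing \"%s\"", field))
      }
    }
    tibble::tibble(id = im$id, file_name = im$file_name %||% NA_character_,
                   height = im$height, width = im$width)
  })
  purrr::map_dfr(doc$annotations, function(an) {
    for (field in c("id", "image_id", "segmentation")) {
      if (is.null(an[[field]])) {
        abort(sprintf("COCO schema violation: annotation missing \"%s\"", field))
      }
    }
    im <- imgs[match(an$image_id, imgs$id), ]
    seg <- unlist(an$segmentation[[1]])
    poly <- matrix(seg, ncol = 2, byrow = TRUE)
    attrs <- an$attributes %||% list()
    tibble::tibble(
      image_path = im$file_name, instance_id = an$id,
      label = attrs$label %||% "instance",
      complete = attrs$complete %||% TRUE,
      polygon = list(poly),
      image_height = as.integer(im$height), image_width = as.integer(im$width)
    )
  })
}

# ---- instance pool from annotations -----------------------------------------

#' Build an instance pool from images and polygon annotations
#'
#' Rasterizes each complete-instance polygon, tight-crops the image and
#' mask to the polygon's extent and appends the item to the pool.
#' Degenerate polygons (< 3 vertices or zero rasterized area) are skipped
#' with a warning.
#'
#' @param images A named list of RGB arrays (`h x w x 3`), keyed by the
#'   records' `image_path`.
#' @param annotations A tibble of annotation records.
#' @return An instance pool tibble (see [pool_from_fixtures()]).
#' @export
build_pool <- function(images, annotations) {
  items <- list()
  for (k in seq_len(nrow(annotations))) {
    rec <- annotations[k, ]
    if (!isTRUE(rec$complete)) next
    poly <- rec$polygon[[1]]
    img <- images[[rec$image_path]]
    if (is.null(img)) {
      warn(sprintf("no image for record %d (%s); skipped", k, rec$image_path))
      next
    }
    if (is.null(poly) || nrow(poly) < 3) {
      warn(sprintf("degenerate polygon in record %d (< 3 vertices); skipped", k))
      next
    }
    m <- rasterize_polygon(poly, nrow(img), ncol(img))
    if (mask_area(m) == 0) {
      warn(sprintf("degenerate polygon in record %d (zero area); skipped", k))
      next
    }
    bb <- mask_bbox(m)
    rows <- (bb[["y0"]] + 1):bb[["y1"]]; cols <- (bb[["x0"]] + 1):bb[["x1"]]
    msk <- m[rows, cols, drop = FALSE]
    rgb <- img[rows, cols, , drop = FALSE]
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[msk == 0] <- 0
      # keep foreground strictly positive so grayscale > 0 recovers the mask
      plane[msk != 0] <- pmax(plane[msk != 0], 1 / 255)
      rgb[, , ch] <- plane
    }
    items[[length(items) + 1]] <- list(mask = msk, rgb = rgb)
  }
  tibble::tibble(
    id = seq_along(items),
    w = vapply(items, function(i) ncol(i$mask), integer(1)),
    h = vapply(items, function(i) nrow(i$mask), integer(1)),
    rgb = lapply(items, `[[`, "rgb"),
    mask = lapply(items, `[[`, "mask")
  )
}

# ---- configuration ----------------------------------------------------------

#' Read a YAML run configuration with overrides
#'
#' @param path Path to a YAML file, or `NULL` for an empty base.
#' @param overrides A named list merged over the file's values.
#' @return A named list.
#' @export
read_config <- function(path = NULL, overrides = list()) {
  base <- if (!is.null(path)) yaml::read_yaml(path) else list()
  utils::modifyList(base, overrides)
}
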