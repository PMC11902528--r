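# Procedural grape-like fixtures: irregular cluster silhouettes built as
# unions of jittered circles ("berries") and multi-instance scenes with a
# known depth order, so every downstream component has ground truth with no
# dataset download.

#' Generate one grape-cluster-like instance
#'
#' The silhouette is the union of 15-40 overlapping circles with radii
#' around `scale / 6`, centers drawn inside an ellipse; the largest
#' connected component is kept so the silhouette is a single irregular
#' blob. The RGB patch shades each berry with a per-berry tint and radial
#' gradient (all foreground pixel values are kept strictly positive so a
#' grayscale > 0 test recovers the mask).
#'
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @param scale Nominal instance extent in pixels (>= 16).
#' @return A list with `mask` (binary matrix, tight-cropped), `rgb`
#'   (h x w x 3 array in `[0, 1]`, zero outside the mask).
#' @export
make_grape_instance <- function(rng_seed, scale = 48) {
  if (scale < 16) abort("scale must be >= 16")
  with_preserved_rng(rng_seed, {
    side <- as.integer(ceiling(scale * 1.5))
    n_berry <- sample(15:40, 1)
    # ellipse of centers: slightly taller than wide, like a hanging cluster
    cx <- side / 2; cy <- side / 2
    ax <- scale * 0.33; ay <- scale * 0.43
    theta <- stats::runif(n_berry, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_berry))
    bx <- cx + ax * rad * cos(theta)
    by <- cy + ay * rad * sin(theta)
    br <- (scale / 7) * stats::runif(n_berry, 0.6, 1.2)

    ys <- matrix(seq_len(side) - 0.5, side, side)
    xs <- t(ys)
    mask <- matrix(0L, side, side)
    owner <- matrix(0L, side, side)  # which berry painted the pixel last
    for (k in seq_len(n_berry)) {
      inside <- (xs - bx[k])^2 + (ys - by[k])^2 <= br[k]^2
      mask[inside] <- 1L
      owner[inside] <- k
    }
    # keep the largest connected component
    lab <- EBImage::bwlabel(mask)
    if (max(lab) > 1) {
      sizes <- tabulate(lab[lab > 0])
      keep <- which.max(sizes)
      mask <- matrix(as.integer(lab == keep), side, side)
      owner[mask == 0] <- 0L
    }

    # shading: per-berry green-purple tint + radial falloff, floor 0.1
    base_h <- stats::runif(1)  # cluster-level hue mix
    tint <- cbind(
      0.25 + 0.3 * stats::runif(n_berry) * base_h,
      0.45 + 0.4 * stats::runif(n_berry),
      0.2 + 0.25 * stats::runif(n_berry)
    )
    rgb <- array(0, c(side, side, 3))
    on_idx <- which(mask != 0)
    ok <- owner[on_idx]
    dist_r <- sqrt((xs[on_idx] - bx[ok])^2 + (ys[on_idx] - by[ok])^2) / br[ok]
    shade <- pmax(0.35, 1 - 0.55 * dist_r^2)
    for (ch in 1:3) {
      plane <- rgb[, , ch]
      plane[on_idx] <- pmin(1, pmax(0.1, tint[ok, ch] * shade))
      rgb[, , ch] <- plane
    }

    bb <- mask_bbox(mask)
    rows <- (bb[["y0"]] + 1):bb[["y1"]]; cols <- (bb[["x0"]] + 1):bb[["x1"]]
    list(mask = mask[rows, cols, drop = FALSE],
         rgb = rgb[rows, cols, , drop = FALSE])
  })
}

#' Generate a multi-instance scene with known occlusion structure
#'
#' Instances are placed sequentially on a canvas; placement order is depth
#' order (later instances paint over earlier ones). Approximately
#' `overlap_fraction` of instances after the first are placed overlapping a
#' previously placed instance. The scene records, for every instance, its
#' full amodal mask, its visible mask, and the list of occlusion edges
#' (occluder id, occludee id) with nonempty hidden area - the ground truth
#' for all downstream tests.
#'
#' @param n_instances Number of instances (>= 1).
#' @param overlap_fraction Target fraction of placements that overlap an
#'   earlier instance, in `[0, 1]`.
#' @param rng_seed Integer root seed.
#' @param canvas Canvas side in pixels.
#' @param scale Nominal instance scale passed to [make_grape_instance()].
#' @return An object of class `fixture_scene`: list with `label_map`,
#'   `amodal` and `visible` (lists of masks), `rgb` composite, `edges`
#'   (tibble occluder/occludee), `rng_seed`.
#' @export
make_scene <- function(n_instances, overlap_fraction = 0.5, rng_seed = 1L,
                       canvas = 192L, scale = 48) {
  if (n_instances < 1) abort("n_instances must be >= 1")
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    abort("overlap_fraction must be in [0, 1]")
  }
  insts <- lapply(seq_len(n_instances), function(k) {
    make_grape_instance(derive_seed(rng_seed, k), scale = scale)
  })
  with_preserved_rng(derive_seed(rng_seed, 0L), {
    h <- w <- as.integer(canvas)
    amodal <- vector("list", n_instances)
    rgb <- array(0, c(h, w, 3))
    label_map <- matrix(0L, h, w)

    place_at <- function(inst, x0, y0) {
      ih <- nrow(inst$mask); iw <- ncol(inst$mask)
      x0 <- max(0, min(w - iw, round(x0))); y0 <- max(0, min(h - ih, round(y0)))
      full <- matrix(0L, h, w)
      full[(y0 + 1):(y0 + ih), (x0 + 1):(x0 + iw)] <- inst$mask
      full
    }
    paint <- function(inst, full, k) {
      bb <- mask_bbox(full)
      rows <- (bb[["y0"]] + 1):bb[["y1"]]; cols <- (bb[["x0"]] + 1):bb[["x1"]]
      sub <- full[rows, cols]
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        patch <- plane[rows, cols]
        patch[sub != 0] <- inst$rgb[, , ch][inst$mask != 0]
        plane[rows, cols] <- patch
        rgb[, , ch] <<- plane
      }
      lm <- label_map
      lm[full != 0] <- k
      label_map <<- lm
    }

    for (k in seq_len(n_instances)) {
      inst <- insts[[k]]
      ih <- nrow(inst$mask); iw <- ncol(inst$mask)
      want_overlap <- k > 1 && stats::runif(1) < overlap_fraction
      placed <- FALSE
      for (attempt in 1:50) {
        if (want_overlap) {
          # anchor on a previous instance and offset so bounding boxes overlap
          j <- sample.int(k - 1, 1)
          bb <- mask_bbox(amodal[[j]])
          x0 <- stats::runif(1, bb[["x0"]] - 0.6 * iw, bb[["x1"]] - 0.4 * iw)
          y0 <- stats::runif(1, bb[["y0"]] - 0.6 * ih, bb[["y1"]] - 0.4 * ih)
        } else {
          x0 <- stats::runif(1, 0, max(1, w - iw))
          y0 <- stats::runif(1, 0, max(1, h - ih))
        }
        full <- place_at(inst, x0, y0)
        prev <- if (k > 1) Reduce(`|`, lapply(amodal[seq_len(k - 1)], `!=`, 0)) else NULL
        ov <- if (is.null(prev)) 0 else sum(full != 0 & prev)
        if (want_overlap && ov > 0 && ov < 0.9 * mask_area(full)) { placed <- TRUE; break }
        if (!want_overlap && ov == 0) { placed <- TRUE; break }
      }
      if (!placed) full <- place_at(inst, stats::runif(1, 0, w - iw), stats::runif(1, 0, h - ih))
      amodal[[k]] <- full
      paint(inst, full, k)
    }

    # visible mask = amodal minus union of amodal masks painted later
    visible <- lapply(seq_len(n_instances), function(k) {
      vis <- amodal[[k]]
      if (k < n_instances) {
        for (j in (k + 1):n_instances) vis <- vis * (1L - amodal[[j]])
      }
      vis
    })

    edges <- purrr::map_dfr(seq_len(n_instances), function(k) {
      if (k == n_instances) return(NULL)
      purrr::map_dfr((k + 1):n_instances, function(j) {
        hidden <- sum(amodal[[k]] != 0 & amodal[[j]] != 0)
        if (hidden > 0) {
          tibble::tibble(occluder = j, occludee = k, hidden_px = hidden)
        } else NULL
      })
    })
    if (nrow(edges) == 0) {
      edges <- tibble::tibble(occluder = integer(), occludee = integer(),
                              hidden_px = integer())
    }

    structure(
      list(label_map = label_map, amodal = amodal, visible = visible,
           rgb = rgb, edges = edges, rng_seed = rng_seed),
      class = "fixture_scene"
    )
  })
}

#' @export
print.fixture_scene <- function(x, ...) {
  cat(sprintf(
    "<fixture_scene> %d instances on %dx%d, %d occlusion edge(s), seed %d\n",
    length(x$amodal), nrow(x$label_map), ncol(x$label_map),
    nrow(x$edges), x$rng_seed
  ))
  invisible(x)
}

#' Held-out occlusion pairs from fixture scenes
#'
#' Extracts (visible occludee, visible occluder, amodal occludee) mask
#' triples from every occlusion edge of a set of scenes - the neutral
#' evaluation domain for the mask-completion model.
#'
#' @param n_scenes Number of scenes.
#' @param rng_seed Root seed.
#' @param size Masks are letterboxed and resized to `size` x `size`.
#' @param n_instances,overlap_fraction,... Passed to [make_scene()].
#' @return A tibble with list-columns `m_occ`, `m_occder`, `m_intact` and
#'   columns `scene`, `occluder`, `occludee`.
#' @export
scene_occlusion_pairs <- function(n_scenes, rng_seed = 1L, size = 64,
                                  n_instances = 6, overlap_fraction = 0.7, ...) {
  purrr::map_dfr(seq_len(n_scenes), function(s) {
    sc <- make_scene(n_instances, overlap_fraction,
                     rng_seed = derive_seed(rng_seed, s), ...)
    if (nrow(sc$edges) == 0) return(NULL)
    purrr::pmap_dfr(sc$edges, function(occluder, occludee, hidden_px) {
      vis <- sc$visible[[occludee]]
      if (mask_area(vis) == 0) return(NULL)
      # crop jointly to the pair's extent, letterbox to square, resize
      both <- matrix(as.integer(
        sc$amodal[[occludee]] != 0 | sc$amodal[[occluder]] != 0
      ), nrow(vis), ncol(vis))
      bb <- mask_bbox(both)
      fit <- function(m) {
        cropped <- crop_box(m, bb)
        resize_mask(letterbox_square(cropped), size, size)
      }
      tibble::tibble(
        scene = s, occluder = occluder, occludee = occludee,
        m_occ = list(fit(vis)),
        m_occder = list(fit(sc$visible[[occluder]])),
        m_intact = list(fit(sc$amodal[[occludee]]))
      )
    })
  })
}

# Pad a matrix (or h x w x c array) with zeros to a square.
letterbox_square <- function(m) {
  d <- dim(m); h <- d[1]; w <- d[2]
  side <- max(h, w)
  if (h == w) return(m)
  oy <- (side - h) %/% 2; ox <- (side - w) %/% 2
  if (length(d) == 2) {
    out <- matrix(if (is.integer(m)) 0L else 0, side, side)
    out[(oy + 1):(oy + h), (ox + 1):(ox + w)] <- m
  } else {
    out <- array(0, c(side, side, d[3]))
    out[(oy + 1):(oy + h), (ox + 1):(ox + w), ] <- m
  }
  out
}
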