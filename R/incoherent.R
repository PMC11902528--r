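# Incoherent-region supervision: the pixels whose mask value is not
# preserved under a downsample-upsample size transformation, and the subset
# of those lying where two instances meet. These drive the incoherent-region
# decoder of the segmentation heads.

#' Incoherent-region mask of a size transformation
#'
#' Marks the pixels of a mask whose value is lost when the mask is
#' downsampled and re-upsampled bilinearly: `D(m XOR U(D(m)))`, where `D`
#' resizes to `(down_h, down_w)` and `U` resizes back to the source size.
#' The result is returned at the downsampled size and concentrates on
#' instance boundaries and overlap regions.
#'
#' @param m A binary mask.
#' @param down_h,down_w Downsampled size; must not exceed `m`'s size.
#' @return A binary mask of size `down_h` x `down_w`.
#' @export
incoherent_mask <- function(m, down_h, down_w) {
  m <- as_mask(m)
  if (down_h > nrow(m) || down_w > ncol(m)) {
    abort("incoherent_mask requires a downsampling (or identity) target size")
  }
  if (down_h < 1 || down_w < 1) abort("target size must be >= 1")
  md <- resize_mask(m, down_h, down_w)
  mu <- resize_mask(md, nrow(m), ncol(m))
  x <- matrix(as.integer(xor(m != 0, mu != 0)), nrow(m), ncol(m))
  resize_mask(x, down_h, down_w)
}

#' Local incoherent region: incoherent pixels at instance-instance contact
#'
#' For every foreground point of the incoherent mask, three pixel pairs are
#' sampled symmetrically about the point at distance `pair_offset` along the
#' horizontal, vertical and main-diagonal directions. A pair straddles two
#' instances when both members carry nonzero, differing instance ids
#' (instance-versus-background pairs do not count); the point joins the
#' local incoherent region when at least two of its three pairs straddle.
#'
#' @param m_inc Incoherent mask (any size; the label map is registered to it
#'   by nearest-neighbour resize).
#' @param labels An instance label map: integer matrix, 0 = background,
#'   k >= 1 = instance id.
#' @param pair_offset Half-distance of each sampled pair, in pixels (>= 1).
#' @return A binary mask of `m_inc`'s shape.
#' @export
local_incoherent_mask <- function(m_inc, labels, pair_offset = 2) {
  m_inc <- as_mask(m_inc)
  if (pair_offset < 1) abort("pair_offset must be >= 1")
  if (!is.matrix(labels) || any(labels < 0)) abort("labels must be a nonnegative integer matrix")
  h <- nrow(m_inc); w <- ncol(m_inc)
  if (nrow(labels) != h || ncol(labels) != w) {
    labels <- resize_labels(labels, h, w)
  }
  r <- as.integer(pair_offset)

  # shift(labels, dy, dx): value at (y + dy, x + dx), NA out of bounds
  shift <- function(dy, dx) {
    out <- matrix(NA_integer_, h, w)
    ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
    keep_y <- ys >= 1 & ys <= h; keep_x <- xs >= 1 & xs <= w
    out[keep_y, keep_x] <- labels[ys[keep_y], xs[keep_x], drop = FALSE]
    out
  }
  pair_straddles <- function(dy, dx) {
    a <- shift(-dy, -dx); b <- shift(dy, dx)
    ok <- !is.na(a) & !is.na(b) & a > 0 & b > 0 & a != b
    ok[is.na(ok)] <- FALSE
    ok
  }
  n <- pair_straddles(0L, r) + pair_straddles(r, 0L) + pair_straddles(r, r)
  matrix(as.integer(m_inc != 0 & n >= 2), h, w)
}

#' Per-proposal supervision triple for the dual-decoder heads
#'
#' Builds the three supervision targets for one proposal: the instance mask
#' at the mask-decoder output size (`mpc`), the instance incoherent-region
#' mask at the incoherent-decoder output size (`mpi`), and the instance
#' local incoherent-region mask (`minc_oi`), obtained by intersecting the
#' proposal-cropped local incoherent region with `mpi`. The full-image
#' incoherent and local-incoherent masks are computed at the image
#' downscale transform, registered back to the image frame, then cropped by
#' the proposal.
#'
#' @param instance Binary mask of the target instance (full image frame).
#' @param labels Instance label map of the full scene, same frame.
#' @param proposal Half-open 0-based box `c(x0, y0, x1, y1)`; must intersect
#'   the instance's bounding box.
#' @param mask_out Mask-decoder output size (default 28).
#' @param inc_out Incoherent-decoder output size, 28 or 56 (default 56).
#' @param image_down Fraction by which the image frame is downscaled for the
#'   full-image incoherent mask (default 0.6, the model-input downscale).
#' @param pair_offset Pair offset for [local_incoherent_mask()].
#' @param minc_o_mode How the cropped local incoherent mask is brought to
#'   `inc_out`: `"resize"` (plain resize; default) or `"incoherent"`
#'   (re-apply the incoherent-mask transform).
#' @param supervision `"incoherent"` (default) or `"boundary"`; the latter
#'   substitutes Laplacian boundary masks for the incoherent targets, the
#'   boundary-supervision baseline.
#' @return An object of class `supervision_triple`: list with binary masks
#'   `mpc` (`mask_out` sq.), `mpi`, `minc_oi` (`inc_out` sq.), the
#'   `proposal`, and `empty_crop` flag. An empty crop yields all-zero masks
#'   with a warning.
#' @export
build_supervision_triple <- function(instance, labels, proposal,
                                     mask_out = 28, inc_out = 56,
                                     image_down = 0.6, pair_offset = 2,
                                     minc_o_mode = c("resize", "incoherent"),
                                     supervision = c("incoherent", "boundary")) {
  minc_o_mode <- match.arg(minc_o_mode)
  supervision <- match.arg(supervision)
  instance <- as_mask(instance)
  h <- nrow(instance); w <- ncol(instance)

  zero_triple <- function() {
    structure(
      list(
        mpc = matrix(0L, mask_out, mask_out),
        mpi = matrix(0L, inc_out, inc_out),
        minc_oi = matrix(0L, inc_out, inc_out),
        proposal = proposal, empty_crop = TRUE
      ),
      class = "supervision_triple"
    )
  }

  # (1) full-image incoherent + local incoherent masks at the image
  #     downscale, registered back to the image frame for cropping
  dh <- max(1, round(h * image_down)); dw <- max(1, round(w * image_down))
  if (supervision == "incoherent") {
    m_inc <- incoherent_mask(instance, dh, dw)
    m_inc_o <- local_incoherent_mask(m_inc, labels, pair_offset)
    m_inc_o_full <- resize_mask(m_inc_o, h, w)
  } else {
    # boundary baseline: Laplacian boundary of the instance, restricted to
    # instance-instance contact not required (the baseline supervises all
    # boundary pixels)
    m_inc_o_full <- laplacian_boundary(instance)
  }

  # (2) crop by proposal
  mpc_crop <- crop_box(instance, proposal)
  minc_crop <- crop_box(m_inc_o_full, proposal)
  if (is.null(mpc_crop) || mask_area(mpc_crop) == 0) {
    warn("proposal crop contains no instance pixels; returning all-zero supervision triple")
    return(zero_triple())
  }

  # (3) instance mask at mask-decoder size
  mpc <- resize_mask(mpc_crop, mask_out, mask_out)
  # (4) instance incoherent mask at incoherent-decoder size
  if (supervision == "incoherent") {
    mpc_inc_src <- if (nrow(mpc_crop) >= inc_out && ncol(mpc_crop) >= inc_out) {
      mpc_crop
    } else {
      # small crops are first brought above the decoder size so the
      # transform is a genuine downsampling
      resize_mask(mpc_crop, max(nrow(mpc_crop), 2 * inc_out),
                  max(ncol(mpc_crop), 2 * inc_out))
    }
    mpi <- incoherent_mask(mpc_inc_src, inc_out, inc_out)
  } else {
    mpi <- laplacian_boundary(resize_mask(mpc_crop, inc_out, inc_out))
  }
  # (5) cropped local incoherent mask at the decoder size
  minc_o_p <- if (minc_o_mode == "resize" || supervision == "boundary") {
    resize_mask(minc_crop, inc_out, inc_out)
  } else {
    src <- if (nrow(minc_crop) >= inc_out && ncol(minc_crop) >= inc_out) {
      minc_crop
    } else {
      resize_mask(minc_crop, max(nrow(minc_crop), 2 * inc_out),
                  max(ncol(minc_crop), 2 * inc_out))
    }
    incoherent_mask(src, inc_out, inc_out)
  }
  # (6) logical AND keeps only local incoherent pixels inside the
  #     instance-level incoherent mask
  minc_oi <- matrix(as.integer(minc_o_p != 0 & mpi != 0), inc_out, inc_out)

  structure(
    list(mpc = mpc, mpi = mpi, minc_oi = minc_oi,
         proposal = proposal, empty_crop = FALSE),
    class = "supervision_triple"
  )
}

#' @export
print.supervision_triple <- function(x, ...) {
  cat(sprintf(
    "<supervision_triple> mpc %dx%d (%d px), mpi %dx%d (%d px), minc_oi %d px%s\n",
    nrow(x$mpc), ncol(x$mpc), mask_area(x$mpc),
    nrow(x$mpi), ncol(x$mpi), mask_area(x$mpi),
    mask_area(x$minc_oi),
    if (x$empty_crop) " [empty crop]" else ""
  ))
  invisible(x)
}

#' Supervision triples for every instance of a scene
#'
#' Convenience wrapper: jitters each instance's bounding box into a
#' proposal and builds its supervision triple.
#'
#' @param scene A `fixture_scene` (see [make_scene()]) or a list with
#'   `label_map` and `visible` masks.  The scene harness defaults to a 2x
#'   image downscale: the procedurally smooth fixture boundaries only lose
#'   pixels at the exact resampling stride, whereas jagged real annotations
#'   shed incoherent pixels at any scale.
#' @param jitter Relative box jitter applied to each side (default 0.1).
#' @param seed Integer seed for the jitter.
#' @inheritParams build_supervision_triple
#' @return A tibble with columns `instance_id`, `proposal` (list) and
#'   `triple` (list of `supervision_triple`).
#' @export
supervision_triples <- function(scene, jitter = 0.1, seed = 1L,
                                mask_out = 28, inc_out = 56,
                                image_down = 0.5, pair_offset = 2,
                                supervision = c("incoherent", "boundary")) {
  supervision <- match.arg(supervision)
  labels <- scene$label_map
  masks <- scene$visible
  rows <- with_preserved_rng(seed, {
    purrr::imap(masks, function(m, k) {
      bb <- mask_bbox(m)
      if (is.null(bb)) return(NULL)
      wd <- bb[["x1"]] - bb[["x0"]]; ht <- bb[["y1"]] - bb[["y0"]]
      jx <- stats::runif(2, -jitter, jitter) * wd
      jy <- stats::runif(2, -jitter, jitter) * ht
      prop <- c(
        x0 = max(0, bb[["x0"]] + jx[1]), y0 = max(0, bb[["y0"]] + jy[1]),
        x1 = min(ncol(m), bb[["x1"]] + jx[2]), y1 = min(nrow(m), bb[["y1"]] + jy[2])
      )
      if (prop["x1"] <= prop["x0"] + 1) prop[c("x0", "x1")] <- bb[c("x0", "x1")]
      if (prop["y1"] <= prop["y0"] + 1) prop[c("y0", "y1")] <- bb[c("y0", "y1")]
      tibble::tibble(
        instance_id = k,
        proposal = list(prop),
        triple = list(build_supervision_triple(
          m, labels, prop,
          mask_out = mask_out, inc_out = inc_out, image_down = image_down,
          pair_offset = pair_offset, supervision = supervision
        ))
      )
    })
  })
  dplyr::bind_rows(rows)
}
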