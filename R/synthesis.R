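# Overlapping cover strategy: synthesizes occluded / occluder / intact
# training triples from a pool of complete instances. An occluder is chosen
# by rejection on a height match, the two instances are placed on blank
# canvases with a directional overlap controlled by the ratio beta (8
# angular cases, 45 degrees apart), the occluded content under the occluder
# is erased, and samples whose occlusion rate epsilon is <= 0.1 are retried
# with a larger beta. Reverse synthesis (gamma) emits identity-mapping
# samples that regularize the completion model against over-predicting
# occluders.

gray_of <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

bool_gray <- function(img) {
  g <- gray_of(img)
  matrix(as.integer(g > 0), nrow(g), ncol(g))
}

#' Build an instance pool from fixture instances
#'
#' @param n Number of instances.
#' @param rng_seed Root seed.
#' @param scale Nominal instance scale in pixels.
#' @param scale_jitter Relative spread of per-instance scales.
#' @return An instance pool: tibble with columns `id`, `w`, `h` and
#'   list-columns `rgb`, `mask` (each item tight-cropped to its mask).
#' @export
pool_from_fixtures <- function(n, rng_seed = 1L, scale = 40, scale_jitter = 0.25) {
  scales <- with_preserved_rng(derive_seed(rng_seed, 0L), {
    pmax(16, round(scale * stats::runif(n, 1 - scale_jitter, 1 + scale_jitter)))
  })
  items <- lapply(seq_len(n), function(k) {
    make_grape_instance(derive_seed(rng_seed, k), scale = scales[k])
  })
  tibble::tibble(
    id = seq_len(n),
    w = vapply(items, function(i) ncol(i$mask), integer(1)),
    h = vapply(items, function(i) nrow(i$mask), integer(1)),
    rgb = lapply(items, `[[`, "rgb"),
    mask = lapply(items, `[[`, "mask")
  )
}

#' Height compatibility of an occluded/occluder pair
#'
#' An occluder is rejected when `h_occ >= 1.2 * h_occder` or
#' `h_occ <= 0.9 * h_occder`; only height is constrained.
#'
#' @param h_occ,h_occder Instance heights in pixels.
#' @return `TRUE` when the pair may be combined.
#' @export
size_match <- function(h_occ, h_occder) {
  !(h_occ >= 1.2 * h_occder | h_occ <= 0.9 * h_occder)
}

#' Occlusion rate of a visible/intact mask pair
#'
#' `epsilon = 1 - |visible| / |intact|`: the fraction of the intact
#' instance's foreground hidden by the occluder.
#'
#' @param visible,intact Binary masks of equal shape; `intact` nonempty.
#' @return The occlusion rate in `[0, 1]`.
#' @export
occlusion_rate <- function(visible, intact) {
  visible <- as_mask(visible); intact <- as_mask(intact)
  check_same_shape(visible, intact)
  if (mask_area(intact) == 0) abort("intact mask must be nonempty")
  1 - mask_area(visible) / mask_area(intact)
}

# Placement geometry for the 8 occlusion cases. Case numbering follows the
# angular dial: case 1 centered at 0 degrees (occluder to the right of the
# occluded instance), advancing counterclockwise in 45-degree steps, so the
# even cases are corner overlaps (case 2 = upper right, the printed one)
# and the odd cases overlap along one axis with a jittered transverse
# placement. Returns origins (x0, y0) of each instance on the shared canvas.
case_placement <- function(case_alpha, beta, wocc, hocc, woccder, hoccder) {
  wb <- round(wocc * beta); hb <- round(hocc * beta)
  wb <- max(1, min(wb, min(wocc, woccder)))
  hb <- max(1, min(hb, min(hocc, hoccder)))
  corner <- function(horiz, vert) {
    ws <- wocc + woccder - wb
    hs <- hocc + hoccder - hb
    occ_x <- if (horiz == "right") 0 else ws - wocc
    od_x <- if (horiz == "right") wocc - wb else 0
    occ_y <- if (vert == "up") hoccder - hb else 0
    od_y <- if (vert == "up") 0 else hocc - hb
    list(ws = ws, hs = hs, occ = c(occ_x, occ_y), occder = c(od_x, od_y),
         wbeta = wb, hbeta = hb, corner = TRUE)
  }
  transverse <- function(extent_occ, extent_occder) {
    # centered, plus uniform jitter of +-10% of the transverse extent
    base <- (extent_occ - extent_occder) / 2
    round(base + stats::runif(1, -0.1, 0.1) * max(extent_occ, extent_occder))
  }
  cardinal_x <- function(occluder_right) {
    ws <- wocc + woccder - wb
    occ_x <- if (occluder_right) 0 else ws - wocc
    od_x <- if (occluder_right) wocc - wb else 0
    od_y0 <- transverse(hocc, hoccder)
    occ_y <- max(0, -od_y0); od_y <- max(0, od_y0)
    hs <- max(occ_y + hocc, od_y + hoccder)
    list(ws = ws, hs = hs, occ = c(occ_x, occ_y), occder = c(od_x, od_y),
         wbeta = wb, hbeta = hb, corner = FALSE)
  }
  cardinal_y <- function(occluder_up) {
    hs <- hocc + hoccder - hb
    occ_y <- if (occluder_up) hoccder - hb else 0
    od_y <- if (occluder_up) 0 else hocc - hb
    od_x0 <- transverse(wocc, woccder)
    occ_x <- max(0, -od_x0); od_x <- max(0, od_x0)
    ws <- max(occ_x + wocc, od_x + woccder)
    list(ws = ws, hs = hs, occ = c(occ_x, occ_y), occder = c(od_x, od_y),
         wbeta = wb, hbeta = hb, corner = FALSE)
  }
  switch(case_alpha,
    cardinal_x(TRUE),            # 1: right
    corner("right", "up"),       # 2: upper right (printed case)
    cardinal_y(TRUE),            # 3: above
    corner("left", "up"),        # 4: upper left
    cardinal_x(FALSE),           # 5: left
    corner("left", "down"),      # 6: lower left
    cardinal_y(FALSE),           # 7: below
    corner("right", "down")      # 8: lower right
  )
}

paint_canvas <- function(hs, ws, item, origin) {
  canvas <- array(0, c(hs, ws, 3))
  ih <- item$h; iw <- item$w
  rows <- (origin[2] + 1):(origin[2] + ih)
  cols <- (origin[1] + 1):(origin[1] + iw)
  msk <- item$mask != 0
  for (ch in 1:3) {
    patch <- canvas[rows, cols, ch]
    patch[msk] <- item$rgb[, , ch][msk]
    canvas[rows, cols, ch] <- patch
  }
  canvas
}

erase_region <- function(img, mask) {
  for (ch in 1:3) img[, , ch][mask != 0] <- 0
  img
}

pool_item <- function(pool, i) {
  list(id = pool$id[i], w = pool$w[i], h = pool$h[i],
       rgb = pool$rgb[[i]], mask = pool$mask[[i]])
}

finish_sample <- function(sample, out_size) {
  if (is.null(out_size)) return(sample)
  fit_rgb <- function(img) {
    sq <- letterbox_square(img)
    out <- array(0, c(out_size, out_size, 3))
    for (ch in 1:3) out[, , ch] <- bilinear_resample(sq[, , ch], out_size, out_size)
    out
  }
  fit_mask <- function(m) resize_mask(letterbox_square(m), out_size, out_size)
  sample$i_occ_s <- fit_rgb(sample$i_occ_s)
  sample$i_occder_s <- fit_rgb(sample$i_occder_s)
  sample$i_intact_s <- fit_rgb(sample$i_intact_s)
  sample$m_intact_s <- fit_mask(sample$m_intact_s)
  sample$m_occder_s <- fit_mask(sample$m_occder_s)
  sample$m_occ_s <- matrix(
    as.integer(sample$m_intact_s != 0 & sample$m_occder_s == 0),
    out_size, out_size
  )
  sample
}

#' Synthesize one occluded/occluder/intact triple (overlapping cover)
#'
#' Draws an occluded and an occluder instance from the pool (rejecting
#' occluders that fail [size_match()]), overlaps them per the case
#' geometry, erases the occluded content under the occluder, and retries
#' with `beta + 0.05` (capped at 0.85, then a fresh pair) until the
#' occlusion rate exceeds 0.1. With `gamma = TRUE` the roles are reversed:
#' the occluder is both input and target (an identity mapping), and the
#' erased occluded instance plays the occluder input channel.
#'
#' @param pool An instance pool (>= 2 items).
#' @param case_alpha Occlusion case 1-8, or `NULL` to draw uniformly.
#' @param beta Overlap ratio in `(0.2, 0.85]`, or `NULL` to draw uniformly.
#' @param gamma Reverse-synthesis flag, or `NULL` to draw Bernoulli(`gamma_prob`).
#' @param rng_seed Integer seed; identical seeds give byte-identical samples.
#' @param gamma_prob Probability of reverse synthesis when `gamma` is `NULL`.
#' @param out_size If non-`NULL`, letterbox to square and resize to this side.
#' @param max_attempts Bound on occluder reselection / pair resampling.
#' @return An object of class `synthesis_sample`: RGB canvases `i_occ_s`,
#'   `i_occder_s`, `i_intact_s`; masks `m_occ_s`, `m_occder_s`,
#'   `m_intact_s`; and `meta` (case, beta, gamma, epsilon, ids, dims).
#' @export
synthesize_pair <- function(pool, case_alpha = NULL, beta = NULL, gamma = NULL,
                            rng_seed = 1L, gamma_prob = 0.5, out_size = NULL,
                            max_attempts = 200L) {
  if (nrow(pool) < 2) abort("pool must contain at least 2 items")
  if (!is.null(beta) && (beta <= 0.2 || beta > 0.85)) {
    abort("beta must lie in (0.2, 0.85]")
  }
  with_preserved_rng(rng_seed, {
    for (resample in seq_len(max_attempts)) {
      occ_i <- sample.int(nrow(pool), 1)
      occ <- pool_item(pool, occ_i)
      # rejection-sample an occluder until the height match passes
      occder <- NULL
      for (try in seq_len(max_attempts)) {
        j <- sample.int(nrow(pool), 1)
        if (j == occ_i) next
        if (size_match(occ$h, pool$h[j])) { occder <- pool_item(pool, j); break }
      }
      if (is.null(occder)) next
      a <- if (is.null(case_alpha)) sample.int(8, 1) else as.integer(case_alpha)
      b <- if (is.null(beta)) stats::runif(1, 0.2, 0.85) else beta
      g <- if (is.null(gamma)) stats::runif(1) < gamma_prob else isTRUE(gamma)

      repeat {
        pl <- case_placement(a, b, occ$w, occ$h, occder$w, occder$h)
        i1 <- paint_canvas(pl$hs, pl$ws, occ, pl$occ)        # occluded canvas
        i2 <- paint_canvas(pl$hs, pl$ws, occder, pl$occder)  # occluder canvas
        m_occluder <- bool_gray(i2)
        if (!g) {
          i_occ <- erase_region(i1, m_occluder)
          i_intact <- i1
          i_occder <- i2
          visible_px <- sum(bool_gray(i_occ))
          intact_px <- sum(bool_gray(i_intact))
          m_intact <- bool_gray(i1)
          m_occder <- m_occluder
        } else {
          i_occ <- i2
          i_intact <- i2
          i_occder <- erase_region(i1, m_occluder)
          visible_px <- sum(bool_gray(i_occder))
          intact_px <- sum(bool_gray(i1))
          m_intact <- m_occluder
          m_occder <- bool_gray(i_occder)
        }
        eps <- 1 - visible_px / intact_px
        if (eps > 0.1) {
          m_occ <- matrix(as.integer(m_intact != 0 & m_occder == 0),
                          pl$hs, pl$ws)
          sample <- structure(
            list(
              i_occ_s = i_occ, i_occder_s = i_occder, i_intact_s = i_intact,
              m_occ_s = m_occ, m_occder_s = m_occder, m_intact_s = m_intact,
              meta = list(
                case_alpha = a, beta = b, gamma = g, epsilon = eps,
                strategy = "overlap",
                occluded_id = occ$id, occluder_id = occder$id,
                wocc = occ$w, hocc = occ$h,
                woccder = occder$w, hoccder = occder$h,
                wbeta = pl$wbeta, hbeta = pl$hbeta,
                ws = pl$ws, hs = pl$hs, corner = pl$corner,
                occ_origin = pl$occ, occder_origin = pl$occder,
                visible_px = visible_px, intact_px = intact_px
              )
            ),
            class = "synthesis_sample"
          )
          return(finish_sample(sample, out_size))
        }
        if (b >= 0.85) break   # cap reached: resample the pair
        b <- min(0.85, b + 0.05)
      }
    }
    abort("occlusion synthesis failed: pool exhausted by size/rate rejection")
  })
}

#' Random-cover baseline synthesis
#'
#' Pastes a random occluder over a random occluded instance at a uniformly
#' random integer offset under which their bounding boxes intersect; no
#' size match, no occlusion-rate filter, no case geometry. Output contract
#' identical to [synthesize_pair()] (forward mode).
#'
#' @inheritParams synthesize_pair
#' @return A `synthesis_sample`.
#' @export
random_cover <- function(pool, rng_seed = 1L, out_size = NULL) {
  if (nrow(pool) < 2) abort("pool must contain at least 2 items")
  with_preserved_rng(rng_seed, {
    idx <- sample.int(nrow(pool), 2)
    occ <- pool_item(pool, idx[1]); occder <- pool_item(pool, idx[2])
    # occluder origin relative to occluded origin; boxes must overlap
    dx <- sample(seq(-occder$w + 1, occ$w - 1), 1)
    dy <- sample(seq(-occder$h + 1, occ$h - 1), 1)
    occ_origin <- c(max(0, -dx), max(0, -dy))
    od_origin <- c(max(0, dx), max(0, dy))
    ws <- max(occ_origin[1] + occ$w, od_origin[1] + occder$w)
    hs <- max(occ_origin[2] + occ$h, od_origin[2] + occder$h)
    i1 <- paint_canvas(hs, ws, occ, occ_origin)
    i2 <- paint_canvas(hs, ws, occder, od_origin)
    m_occluder <- bool_gray(i2)
    i_occ <- erase_region(i1, m_occluder)
    eps <- 1 - sum(bool_gray(i_occ)) / sum(bool_gray(i1))
    m_intact <- bool_gray(i1)
    m_occ <- matrix(as.integer(m_intact != 0 & m_occluder == 0), hs, ws)
    sample <- structure(
      list(
        i_occ_s = i_occ, i_occder_s = i2, i_intact_s = i1,
        m_occ_s = m_occ, m_occder_s = m_occluder, m_intact_s = m_intact,
        meta = list(
          case_alpha = NA_integer_, beta = NA_real_, gamma = FALSE,
          epsilon = eps, strategy = "random",
          occluded_id = occ$id, occluder_id = occder$id,
          wocc = occ$w, hocc = occ$h, woccder = occder$w, hoccder = occder$h,
          wbeta = NA_integer_, hbeta = NA_integer_,
          ws = ws, hs = hs, corner = NA,
          occ_origin = occ_origin, occder_origin = od_origin
        )
      ),
      class = "synthesis_sample"
    )
    finish_sample(sample, out_size)
  })
}

#' @export
print.synthesis_sample <- function(x, ...) {
  m <- x$meta
  cat(sprintf(
    "<synthesis_sample> %s %dx%d case=%s beta=%s gamma=%s epsilon=%.3f\n",
    m$strategy, nrow(x$m_intact_s), ncol(x$m_intact_s),
    ifelse(is.na(m$case_alpha), "-", m$case_alpha),
    ifelse(is.na(m$beta), "-", sprintf("%.2f", m$beta)), m$gamma, m$epsilon
  ))
  invisible(x)
}

#' Synthesize a dataset of occlusion samples
#'
#' @param pool An instance pool.
#' @param n Number of samples.
#' @param strategy `"overlap"` (the overlapping cover strategy) or
#'   `"random"` (the random-cover baseline).
#' @param rng_seed Root seed; per-sample seeds are derived from it.
#' @param gamma_prob Reverse-synthesis proportion (overlap strategy only;
#'   0 disables reverse synthesis).
#' @param out_size Optional square output size.
#' @return A tibble manifest: `sample` (list-column of `synthesis_sample`)
#'   plus unnested metadata columns `case_alpha`, `beta`, `gamma`,
#'   `epsilon`, `strategy`.
#' @export
synthesize_dataset <- function(pool, n, strategy = c("overlap", "random"),
                               rng_seed = 1L, gamma_prob = 0.5,
                               out_size = NULL) {
  strategy <- match.arg(strategy)
  samples <- lapply(seq_len(n), function(k) {
    s <- derive_seed(rng_seed, k)
    if (strategy == "overlap") {
      synthesize_pair(pool, rng_seed = s, gamma_prob = gamma_prob,
                      out_size = out_size)
    } else {
      random_cover(pool, rng_seed = s, out_size = out_size)
    }
  })
  tibble::tibble(
    sample = samples,
    case_alpha = vapply(samples, function(s) as.integer(s$meta$case_alpha), integer(1)),
    beta = vapply(samples, function(s) as.numeric(s$meta$beta), numeric(1)),
    gamma = vapply(samples, function(s) s$meta$gamma, logical(1)),
    epsilon = vapply(samples, function(s) s$meta$epsilon, numeric(1)),
    strategy = strategy
  )
}

#' Write a synthesis dataset to disk
#'
#' Emits per-sample PNG triples and masks plus a JSONL manifest with the
#' case, beta, gamma and epsilon of every sample.
#'
#' @param manifest A tibble from [synthesize_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_synthesis_dataset <- function(manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  records <- purrr::imap(manifest$sample, function(s, k) {
    stem <- sprintf("sample_%04d", k)
    write_rgb_png(s$i_occ_s, file.path(dir, paste0(stem, "_occ.png")))
    write_rgb_png(s$i_occder_s, file.path(dir, paste0(stem, "_occder.png")))
    write_rgb_png(s$i_intact_s, file.path(dir, paste0(stem, "_intact.png")))
    write_mask_png(s$m_occ_s, file.path(dir, paste0(stem, "_mask_occ.png")))
    write_mask_png(s$m_occder_s, file.path(dir, paste0(stem, "_mask_occder.png")))
    write_mask_png(s$m_intact_s, file.path(dir, paste0(stem, "_mask_intact.png")))
    c(list(stem = stem),
      s$meta[c("case_alpha", "beta", "gamma", "epsilon", "strategy")])
  })
  write_jsonl(records, file.path(dir, "manifest.jsonl"))
  invisible(dir)
}
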