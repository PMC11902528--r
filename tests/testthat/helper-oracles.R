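# Independent straight-line oracles used across the suite. Each one is a
# direct transcription of the defining formula, kept free of the package's
# own implementation paths.

# bilinear resample + 0.5 threshold, evaluated pixel by pixel at output
# pixel centers with clamped source coordinates
oracle_resize <- function(m, th, tw) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, th, tw)
  for (i in seq_len(th)) {
    for (j in seq_len(tw)) {
      sy <- min(max((i - 0.5) * h / th - 0.5, 0), h - 1)
      sx <- min(max((j - 0.5) * w / tw - 0.5, 0), w - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      fy <- sy - y0; fx <- sx - x0
      y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
      v <- m[y0 + 1, x0 + 1] * (1 - fy) * (1 - fx) +
        m[y1 + 1, x0 + 1] * fy * (1 - fx) +
        m[y0 + 1, x1 + 1] * (1 - fy) * fx +
        m[y1 + 1, x1 + 1] * fy * fx
      out[i, j] <- as.integer(v >= 0.5)
    }
  }
  out
}

# step-by-step transcription of the incoherent-region definition
oracle_incoherent <- function(m, dh, dw) {
  md <- oracle_resize(m, dh, dw)
  mu <- oracle_resize(md, nrow(m), ncol(m))
  x <- matrix(as.integer(xor(m != 0, mu != 0)), nrow(m), ncol(m))
  oracle_resize(x, dh, dw)
}

# exhaustive Euclidean distance transform: inner band of X = pixels of X
# within distance d of some background pixel
oracle_inner_band <- function(m, d) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  bg <- which(m == 0, arr.ind = TRUE)
  if (nrow(bg) == 0) return(out)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      if (m[i, j] == 0) next
      if (min(sqrt((bg[, 1] - i)^2 + (bg[, 2] - j)^2)) <= d) out[i, j] <- 1L
    }
  }
  out
}

oracle_boundary_iou <- function(g, p, d) {
  gb <- oracle_inner_band(g, d)
  pb <- oracle_inner_band(p, d)
  un <- sum(gb | pb)
  if (un == 0) 1 else sum(gb & pb) / un
}

# 3x3 Laplacian by direct convolution, restricted to the mask
oracle_laplacian_boundary <- function(m) {
  kern <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- 0
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        v <- if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) m[ii, jj] else 0
        acc <- acc + v * kern[di + 2, dj + 2]
      }
      if (acc != 0 && m[i, j] != 0) out[i, j] <- 1L
    }
  }
  out
}

# per-pixel loss oracles
oracle_bce <- function(p, t, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  mean(-t * log(pc) - (1 - t) * log(1 - pc))
}

oracle_dice <- function(p, t) {
  1 - (2 * sum(p * t) + 1) / (sum(p^2) + sum(t^2) + 1)
}

oracle_incoherent_loss <- function(p, mpi, minc, lambda) {
  (oracle_dice(p, mpi) + oracle_bce(p, mpi)) +
    lambda * (oracle_dice(p * minc, minc) + oracle_bce(p * minc, minc))
}

oracle_amodal_loss <- function(p, intact, occder, lambda2) {
  oracle_bce(p * occder, intact * occder) +
    lambda2 * oracle_bce(p * (1 - occder), intact * (1 - occder))
}

# random blob mask: a few filled discs on a small grid
random_blob_mask <- function(h, w, n_blobs = 2) {
  m <- matrix(0L, h, w)
  for (b in seq_len(n_blobs)) {
    cy <- runif(1, 1, h); cx <- runif(1, 1, w)
    r <- runif(1, 1, min(h, w) / 3)
    for (i in seq_len(h)) for (j in seq_len(w)) {
      if ((i - cy)^2 + (j - cx)^2 <= r^2) m[i, j] <- 1L
    }
  }
  m
}

# two abutting rectangles sharing a vertical edge, ids 1 and 2
abutting_rectangles <- function(h = 12, w = 12, split = 6) {
  lab <- matrix(0L, h, w)
  lab[3:(h - 2), 2:split] <- 1L
  lab[3:(h - 2), (split + 1):(w - 1)] <- 2L
  lab
}
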