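# Incoherent-region and local incoherent-region supervision masks.

test_that("incoherent_mask marks exactly the pixels lost by the size transformation", {
  # constant mask survives resampling
  expect_identical(incoherent_mask(matrix(1L, 16, 16), 8, 8), matrix(0L, 8, 8))
  # identity transform loses nothing
  m <- matrix(rbinom(64, 1, 0.5), 8, 8)
  expect_identical(incoherent_mask(m, 8, 8), matrix(0L, 8, 8))
  # one-pixel-wide diagonal stripe: frozen against the composed oracle
  d <- diag(1L, 16, 16)
  expect_identical(incoherent_mask(d, 8, 8), oracle_incoherent(d, 8, 8))
  expect_gt(sum(incoherent_mask(d, 8, 8)), 0)
  expect_error(incoherent_mask(m, 16, 16), "downsampling")
})

test_that("incoherent_mask equals the straight-line oracle on random masks", {
  set.seed(14)
  for (r in 1:150) {
    m <- matrix(rbinom(32 * 32, 1, runif(1, 0.15, 0.85)), 32, 32)
    dh <- sample(8:32, 1); dw <- sample(8:32, 1)
    expect_identical(incoherent_mask(m, dh, dw), oracle_incoherent(m, dh, dw))
  }
})

test_that("local incoherent region requires two distinct nonzero instance ids", {
  # single-instance label map: nothing qualifies
  lab1 <- matrix(0L, 12, 12); lab1[4:9, 4:9] <- 1L
  m_inc <- matrix(1L, 12, 12)
  expect_identical(local_incoherent_mask(m_inc, lab1, 1),
                   matrix(0L, 12, 12))
  # two abutting rectangles sharing a vertical edge: every edge-column point
  # has horizontal and both diagonal pairs straddling (n = 3 >= 2)
  lab <- abutting_rectangles(12, 12, 6)
  edge <- matrix(0L, 12, 12); edge[3:10, 6] <- 1L
  out <- local_incoherent_mask(edge, lab, 1)
  # hand oracle: for each edge point check the three symmetric pairs
  expected <- matrix(0L, 12, 12)
  for (i in 3:10) {
    n <- 0
    for (off in list(c(0, 1), c(1, 0), c(1, 1))) {
      a <- c(i - off[1], 6 - off[2]); b <- c(i + off[1], 6 + off[2])
      ok <- all(a >= 1) && all(b <= 12) &&
        lab[a[1], a[2]] > 0 && lab[b[1], b[2]] > 0 &&
        lab[a[1], a[2]] != lab[b[1], b[2]]
      n <- n + ok
    }
    expected[i, 6] <- as.integer(n >= 2)
  }
  expect_identical(out, expected)
  # interior edge points straddle via the horizontal and main-diagonal
  # pairs (n = 2); the two end points lose their diagonal pair to the
  # rectangle corners and drop below the threshold
  expect_true(all(out[4:9, 6] == 1))
  expect_true(all(out[c(3, 10), 6] == 0))
  # instance-background border point is excluded
  border <- matrix(0L, 12, 12); border[4, 4] <- 1L  # left edge of rect 1
  expect_identical(local_incoherent_mask(border, lab, 1), matrix(0L, 12, 12))
  expect_error(local_incoherent_mask(edge, lab, 0), "pair_offset")
})

test_that("supervision triples keep the local incoherent mask inside the instance incoherent mask", {
  set.seed(27)
  for (r in 1:20) {
    sc <- make_scene(4, 0.8, rng_seed = 1000 + r, canvas = 128L, scale = 40)
    trips <- supervision_triples(sc, seed = r)
    for (k in seq_len(nrow(trips))) {
      tr <- trips$triple[[k]]
      expect_true(all(tr$minc_oi <= tr$mpi))
      expect_equal(dim(tr$mpc), c(28, 28))
      expect_equal(dim(tr$mpi), c(56, 56))
    }
  }
})

test_that("scenes without instance overlap yield empty local incoherent masks", {
  sc <- make_scene(3, 0, rng_seed = 5, canvas = 192L, scale = 40)
  expect_equal(nrow(sc$edges), 0)
  dh <- round(nrow(sc$label_map) * 0.6)
  for (k in seq_along(sc$visible)) {
    m_inc <- incoherent_mask(sc$visible[[k]], dh, dh)
    expect_identical(local_incoherent_mask(m_inc, sc$label_map, 2),
                     matrix(0L, dh, dh))
  }
})

test_that("a single isolated instance gives an all-zero local incoherent target", {
  sc <- make_scene(1, 0, rng_seed = 9, canvas = 96L, scale = 40)
  bb <- mask_bbox(sc$visible[[1]])
  tr <- build_supervision_triple(sc$visible[[1]], sc$label_map, bb)
  expect_identical(tr$minc_oi, matrix(0L, 56, 56))
  expect_gt(sum(tr$mpc), 0)
})

test_that("a background-only proposal returns an all-zero triple with a warning", {
  sc <- make_scene(1, 0, rng_seed = 10, canvas = 96L, scale = 32)
  # a corner far from the instance (instances are placed away from borders)
  prop <- c(x0 = 0, y0 = 0, x1 = 3, y1 = 3)
  expect_warning(
    tr <- build_supervision_triple(sc$visible[[1]], sc$label_map, prop),
    "no instance pixels"
  )
  expect_true(tr$empty_crop)
  expect_identical(tr$mpc, matrix(0L, 28, 28))
  expect_identical(tr$mpi, matrix(0L, 56, 56))
  expect_identical(tr$minc_oi, matrix(0L, 56, 56))
})

test_that("incoherent masks concentrate near label-map transitions", {
  # over random blob fixtures, at least 90% of incoherent pixels lie within
  # 2 px of a transition between labels (including background)
  set.seed(88)
  frac_near <- function(sc) {
    lab <- sc$label_map
    dh <- round(nrow(lab) * 0.6); dw <- round(ncol(lab) * 0.6)
    lab_d <- amodalgrape:::resize_labels(lab, dh, dw)
    # transition map: pixel differs from a 4-neighbour
    h <- nrow(lab_d); w <- ncol(lab_d)
    trans <- matrix(FALSE, h, w)
    trans[-h, ] <- trans[-h, ] | (lab_d[-h, ] != lab_d[-1, ])
    trans[-1, ] <- trans[-1, ] | (lab_d[-1, ] != lab_d[-h, ])
    trans[, -w] <- trans[, -w] | (lab_d[, -w] != lab_d[, -1])
    trans[, -1] <- trans[, -1] | (lab_d[, -1] != lab_d[, -w])
    near <- matrix(FALSE, h, w)
    idx <- which(trans, arr.ind = TRUE)
    for (dy in -2:2) for (dx in -2:2) {
      ii <- idx[, 1] + dy; jj <- idx[, 2] + dx
      keep <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
      near[cbind(ii[keep], jj[keep])] <- TRUE
    }
    tot <- 0; hit <- 0
    for (k in seq_along(sc$visible)) {
      mi <- incoherent_mask(sc$visible[[k]], dh, dw)
      tot <- tot + sum(mi)
      hit <- hit + sum(mi != 0 & near)
    }
    c(hit = hit, tot = tot)
  }
  acc <- c(hit = 0, tot = 0)
  for (r in 1:5) {
    acc <- acc + frac_near(make_scene(4, 0.6, rng_seed = 300 + r,
                                      canvas = 128L, scale = 40))
  }
  expect_gt(acc[["tot"]], 0)
  expect_gte(acc[["hit"]] / acc[["tot"]], 0.9)
})
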