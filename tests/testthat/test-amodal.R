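# Mask-completion network, its loss, training determinism, and the
# cross-prediction occlusion rule.

test_that("the completion network maps 2-channel masks to a same-size probability grid", {
  m <- amodal_unet(input_size = 32, depth = 3, base = 4, seed = 2)
  occ <- matrix(0L, 32, 32); occ[5:20, 5:20] <- 1L
  od <- matrix(0L, 32, 32); od[15:28, 15:28] <- 1L
  out <- amodal_forward(m, occ, od)
  expect_equal(dim(out$p_a), c(32, 32))
  expect_true(all(out$p_a >= 0 & out$p_a <= 1))
  expect_identical(out$m_a, matrix(as.integer(out$p_a >= 0.5), 32, 32))
  # all-zero input stays finite
  z <- amodal_forward(m, matrix(0L, 32, 32), matrix(0L, 32, 32))
  expect_true(all(is.finite(z$p_a)))
  # fixed seed reproducibility of the untrained forward pass
  m2 <- amodal_unet(input_size = 32, depth = 3, base = 4, seed = 2)
  expect_identical(amodal_forward(m2, occ, od)$p_a, out$p_a)
  expect_error(amodal_unet(input_size = 30, depth = 4), "divisible")
})

test_that("amodal loss matches the two-term region-weighted oracle", {
  set.seed(9)
  intact <- matrix(rbinom(256, 1, 0.5), 16, 16)
  occder <- matrix(rbinom(256, 1, 0.3), 16, 16)
  # hard labels at the optimum
  expect_lt(amodal_loss(matrix(as.numeric(intact), 16, 16), intact, occder), 1e-4)
  # empty occluder: first term is the BCE of two all-zero rasters, the
  # second is lambda2 * BCE of the full grids
  p <- matrix(runif(256), 16, 16)
  z <- matrix(0L, 16, 16)
  expect_equal(amodal_loss(p, intact, z, lambda2 = 5),
               oracle_bce(p * 0, z) + 5 * oracle_bce(p, intact),
               tolerance = 1e-9)
  for (r in 1:60) {
    p <- matrix(runif(256), 16, 16)
    expect_equal(amodal_loss(p, intact, occder, 5),
                 oracle_amodal_loss(p, intact, occder, 5), tolerance = 1e-9)
  }
  expect_error(amodal_loss(p, intact, matrix(0L, 4, 4)), "shapes")
})

test_that("training is seed-deterministic and sensitive to the loss weight", {
  pool <- pool_from_fixtures(8, rng_seed = 15)
  samples <- synthesize_dataset(pool, 12, rng_seed = 3, out_size = 32)
  args <- list(samples = samples, input_size = 32L, depth = 3L, base = 4L,
               iters = 12L, batch = 2L, lr = 1e-3, seed = 7L)
  m1 <- do.call(train_amodal, args)
  m2 <- do.call(train_amodal, args)
  expect_identical(tidy(m1)$loss, tidy(m2)$loss)
  m0 <- do.call(train_amodal, c(args[-8], list(lambda2 = 0, seed = 7L)))
  expect_false(identical(tidy(m0)$loss, tidy(m1)$loss))
  expect_error(train_amodal(list(), iters = 2), "empty")
  g <- glance(m1)
  expect_equal(g$iterations, 12)
  expect_true(g$trained)
})

test_that("model checkpoints round-trip through JSON", {
  pool <- pool_from_fixtures(6, rng_seed = 2)
  samples <- synthesize_dataset(pool, 6, rng_seed = 4, out_size = 32)
  m <- train_amodal(samples, input_size = 32, depth = 3, base = 4,
                    iters = 4, batch = 2, seed = 1)
  path <- file.path(tempdir(), "amodal.ckpt.json")
  save_amodal_model(m, path)
  m2 <- load_amodal_model(path)
  occ <- matrix(0L, 32, 32); occ[5:20, 5:20] <- 1L
  od <- matrix(0L, 32, 32); od[15:28, 15:28] <- 1L
  expect_equal(amodal_forward(m2, occ, od)$p_a,
               amodal_forward(m, occ, od)$p_a, tolerance = 1e-12)
})

test_that("the occlusion-relation rule follows the three-branch case table", {
  # completer stub with controllable growth
  stub <- function(grow_i, grow_j) {
    function(m, m_other) {
      # identify which instance by area
      target <- if (sum(m) == 100) grow_i else grow_j
      out <- m
      extra <- round(sum(m) * target)
      if (extra > 0) {
        off <- which(out == 0)[seq_len(extra)]
        out[off] <- 1L
      }
      out
    }
  }
  m_i <- matrix(0L, 30, 30); m_i[1:10, 1:10] <- 1L       # area 100
  m_j <- matrix(0L, 30, 30); m_j[21:25, 21:30] <- 1L     # area 50
  r1 <- occlusion_relation(m_i, m_j, stub(0.3, 0.05))
  expect_equal(r1$o, 1)      # delta_i > delta_j: m_j occludes m_i
  r0 <- occlusion_relation(m_i, m_j, stub(0.05, 0.3))
  expect_equal(r0$o, 0)      # inverse relationship
  rn <- occlusion_relation(m_i, m_j, stub(0, 0))
  expect_equal(rn$o, -1)     # both growths below tau: no occlusion
  expect_false(rn$ambiguous)
  rt <- occlusion_relation(m_i, m_j, stub(0.2, 0.2))
  expect_equal(rt$o, 0)      # tie above tau: flagged ambiguous
  expect_true(rt$ambiguous)
  expect_error(occlusion_relation(matrix(0L, 5, 5), m_j[1:5, 1:5], stub(0, 0)),
               "nonempty")
})

test_that("with ground-truth amodal masks the rule classifies pairs of known direction perfectly", {
  # two-instance scenes: the occlusion direction is unambiguous (the
  # occluder is fully visible), so the oracle-completer rule must be exact;
  # both argument orders and the no-overlap branch are exercised
  correct <- 0; total <- 0
  for (s in 1:12) {
    overlap <- s %% 2 == 0
    sc <- make_scene(2, as.numeric(overlap), rng_seed = 900 + s,
                     canvas = 160L, scale = 44)
    oracle <- function(m, m_other) {
      id <- which(vapply(sc$visible, function(v) identical(v, m), logical(1)))
      sc$amodal[[id]]
    }
    if (overlap && nrow(sc$edges) == 1) {
      dee <- sc$edges$occludee; der <- sc$edges$occluder
      r1 <- occlusion_relation(sc$visible[[dee]], sc$visible[[der]], oracle)
      r0 <- occlusion_relation(sc$visible[[der]], sc$visible[[dee]], oracle)
      total <- total + 2
      correct <- correct + (r1$o == 1) + (r0$o == 0)
    } else if (!overlap && nrow(sc$edges) == 0) {
      rn <- occlusion_relation(sc$visible[[1]], sc$visible[[2]], oracle)
      total <- total + 1
      correct <- correct + (rn$o == -1)
    }
  }
  expect_gt(total, 10)
  expect_equal(correct, total)
})

test_that("instances pair exactly when their bounding boxes intersect", {
  far_a <- matrix(0L, 40, 40); far_a[1:8, 1:8] <- 1L
  far_b <- matrix(0L, 40, 40); far_b[30:38, 30:38] <- 1L
  expect_equal(nrow(pair_instances(list(far_a, far_b))), 0)
  ov <- matrix(0L, 40, 40); ov[5:12, 5:12] <- 1L
  expect_equal(nrow(pair_instances(list(far_a, ov))), 1)
  # chain: boxes (1,2) and (2,3) intersect, (1,3) do not
  m1 <- matrix(0L, 40, 40); m1[1:10, 1:10] <- 1L
  m2 <- matrix(0L, 40, 40); m2[8:20, 8:20] <- 1L
  m3 <- matrix(0L, 40, 40); m3[18:30, 18:30] <- 1L
  pr <- pair_instances(list(m1, m2, m3))
  expect_equal(nrow(pr), 2)
  expect_true(all(paste(pr$i, pr$j) %in% c("1 2", "2 3")))
  # brute-force all-pairs oracle on random scenes
  set.seed(31)
  for (r in 1:10) {
    masks <- lapply(1:5, function(k) random_blob_mask(24, 24, 1))
    pr <- pair_instances(masks)
    expected <- 0
    for (i in 1:4) for (j in (i + 1):5) {
      bi <- mask_bbox(masks[[i]]); bj <- mask_bbox(masks[[j]])
      if (is.null(bi) || is.null(bj)) next
      ix <- min(bi["x1"], bj["x1"]) - max(bi["x0"], bj["x0"])
      iy <- min(bi["y1"], bj["y1"]) - max(bi["y0"], bj["y0"])
      expected <- expected + (ix > 0 && iy > 0)
    }
    expect_equal(nrow(pr), expected)
  }
})
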