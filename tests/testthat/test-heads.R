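# Dual-decoder heads, PALM, and their losses.

test_that("PALM preserves shapes and its branch weights sum to one", {
  f_m <- array(runif(8 * 8 * 6), c(8, 8, 6))
  f_i <- array(runif(8 * 8 * 6), c(8, 8, 6))
  out <- palm_forward(f_m, f_i, seed = 3)
  expect_equal(dim(out$f_m), dim(f_m))
  expect_equal(dim(out$f_i), dim(f_i))
  expect_equal(out$w1 + out$w2, array(1, dim(f_m)), tolerance = 1e-12)
  expect_error(palm_forward(f_m, array(0, c(4, 4, 6))), "match")
})

test_that("PALM with tied branch parameters is permutation-consistent", {
  ns <- asNamespace("amodalgrape")
  pp <- ns$with_preserved_rng(11, ns$palm_init(4))
  f_m <- array(runif(5 * 5 * 4), c(5, 5, 4))
  f_i <- array(runif(5 * 5 * 4), c(5, 5, 4))
  a <- palm_forward(f_m, f_i, params = pp)
  # swapping the branch inputs must swap the outputs when the (shared)
  # parameters are symmetric under the concat order; enforce symmetry by
  # averaging the two concat halves of each weight
  symm <- function(W) {
    d <- dim(W$value)
    if (d[3] == 8) {  # 2c input: swap the halves
      Wsw <- W$value[, , c(5:8, 1:4), , drop = FALSE]
      W$value <- (W$value + Wsw) / 2
    }
    if (d[4] == 8) {  # 2c output: swap the halves
      Wsw <- W$value[, , , c(5:8, 1:4), drop = FALSE]
      W$value <- (W$value + Wsw) / 2
    }
    W
  }
  pp$phi1$W <- symm(pp$phi1$W)
  pp$phi2$W <- symm(pp$phi2$W)
  pp$phi2$b$value <- rep(mean(pp$phi2$b$value), 8)
  pp$fuse$W <- symm(pp$fuse$W)
  b <- palm_forward(f_m, f_i, params = pp)
  d <- palm_forward(f_i, f_m, params = pp)
  expect_equal(b$f_m, d$f_i, tolerance = 1e-10)
  expect_equal(b$f_i, d$f_m, tolerance = 1e-10)
})

test_that("decoders produce 28x28 mask and configurable 28/56 incoherent predictions", {
  c <- 6
  f_m <- array(runif(14 * 14 * c), c(14, 14, c))
  f_i <- array(runif(28 * 28 * c), c(28, 28, c))
  out <- decoders_forward(f_m, f_i, head_config(channels = c), seed = 2)
  expect_equal(dim(out$p_m), c(28, 28))
  expect_equal(dim(out$p_i), c(56, 56))
  out28 <- decoders_forward(f_m, f_i, head_config(inc_out = 28L, channels = c),
                            seed = 2)
  expect_equal(dim(out28$p_i), c(28, 28))
  # PALM off still runs and keeps the contract
  out_np <- decoders_forward(f_m, f_i,
                             head_config(use_palm = FALSE, channels = c),
                             seed = 2)
  expect_equal(dim(out_np$p_m), c(28, 28))
  # all-zero features give finite probabilities
  z <- decoders_forward(array(0, c(14, 14, c)), array(0, c(28, 28, c)),
                        head_config(channels = c), seed = 2)
  expect_true(all(is.finite(z$p_m)) && all(z$p_m >= 0 & z$p_m <= 1))
  expect_true(all(is.finite(z$p_i)) && all(z$p_i >= 0 & z$p_i <= 1))
  expect_error(decoders_forward(f_i, f_i, head_config(channels = c)), "ROI")
  expect_error(head_config(inc_out = 42L), "28 or 56")
  expect_error(head_config(mask_out = 30L), "mask_roi")
})

test_that("mask loss matches the per-pixel BCE oracle", {
  set.seed(6)
  mpc <- matrix(rbinom(16, 1, 0.5), 4, 4)
  # hard labels at the optimum
  expect_lt(mask_loss(matrix(as.numeric(mpc), 4, 4), mpc), 1e-5)
  # maximum-entropy prediction
  expect_equal(mask_loss(matrix(0.5, 4, 4), mpc), log(2), tolerance = 1e-12)
  for (r in 1:60) {
    p <- matrix(runif(16), 4, 4)
    t <- matrix(rbinom(16, 1, 0.5), 4, 4)
    expect_equal(mask_loss(p, t), oracle_bce(p, t), tolerance = 1e-9)
  }
})

test_that("incoherent loss matches the two-term dice + BCE oracle", {
  set.seed(7)
  # hard labels: dice terms vanish
  t <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_lt(incoherent_loss(matrix(as.numeric(t), 8, 8), t, t), 1e-4)
  # all-zero prediction, empty local region: dice = 1 - 1/(S+1)
  s_ones <- matrix(0L, 8, 8); s_ones[2:4, 2:6] <- 1L
  S <- sum(s_ones)
  z <- matrix(0, 8, 8)
  got <- incoherent_loss(z, s_ones, matrix(0L, 8, 8), lambda_inc = 0)
  dice_expect <- 1 - 1 / (S + 1)
  expect_equal(got - oracle_bce(z, s_ones), dice_expect, tolerance = 1e-9)
  for (r in 1:60) {
    p <- matrix(runif(64), 8, 8)
    mpi <- matrix(rbinom(64, 1, 0.5), 8, 8)
    minc <- matrix(as.integer(mpi & rbinom(64, 1, 0.5)), 8, 8)
    expect_equal(incoherent_loss(p, mpi, minc, 2),
                 oracle_incoherent_loss(p, mpi, minc, 2), tolerance = 1e-9)
  }
})

test_that("boundary supervision swaps targets without changing tensor contracts", {
  sc <- make_scene(3, 0.8, rng_seed = 61, canvas = 128L, scale = 40)
  tr_inc <- supervision_triples(sc, seed = 1, supervision = "incoherent")
  tr_bnd <- supervision_triples(sc, seed = 1, supervision = "boundary")
  expect_equal(nrow(tr_inc), nrow(tr_bnd))
  for (k in seq_len(nrow(tr_bnd))) {
    expect_equal(dim(tr_bnd$triple[[k]]$mpi), dim(tr_inc$triple[[k]]$mpi))
    expect_true(all(tr_bnd$triple[[k]]$minc_oi <= tr_bnd$triple[[k]]$mpi))
  }
  # boundary target of a filled square is its perimeter ring
  sq <- matrix(0L, 60, 60); sq[10:49, 10:49] <- 1L
  lab <- sq
  tr <- build_supervision_triple(sq, lab, mask_bbox(sq), supervision = "boundary")
  expect_identical(tr$mpi, oracle_laplacian_boundary(resize_mask(
    amodalgrape:::crop_box(sq, mask_bbox(sq)), 56, 56
  )))
})

test_that("head checkpoints round-trip through JSON", {
  scenes <- list(make_scene(3, 0.8, rng_seed = 91, canvas = 128L, scale = 40))
  cfg <- head_config(channels = 4L)
  hm <- train_heads(scenes, cfg, iters = 4, batch = 2, lr = 1e-3, seed = 5)
  path <- file.path(tempdir(), "heads.ckpt.json")
  save_heads_model(hm, path)
  hm2 <- load_heads_model(path)
  crop <- scenes[[1]]$rgb[1:40, 1:40, , drop = FALSE]
  p1 <- predict(hm, crop)
  p2 <- predict(hm2, crop)
  expect_equal(p1$p_m, p2$p_m, tolerance = 1e-12)
  expect_equal(p1$p_i, p2$p_i, tolerance = 1e-12)
})

test_that("a short dual-decoder training run reduces the loss with PALM on or off", {
  scenes <- lapply(1:2, function(s) make_scene(4, 0.8, rng_seed = 70 + s,
                                               canvas = 128L, scale = 40))
  for (palm in c(TRUE, FALSE)) {
    cfg <- head_config(use_palm = palm, channels = 6L)
    hm <- train_heads(scenes, cfg, iters = 80, batch = 2, lr = 2e-3, seed = 3)
    g <- glance(hm)
    expect_lt(g$final_loss, mean(hm$log$loss[1:5]))
    expect_equal(nrow(tidy(hm)), 80)
  }
})
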