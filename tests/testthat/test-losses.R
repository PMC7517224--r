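test_that("groupwise SSD matches hand evaluation and its invariances", {
  # N = 2, one pixel, values 0 and 1: (1/2)((0-.5)^2 + (1-.5)^2) = 0.25
  reg <- array(c(0, 1), c(1, 1, 2))
  expect_equal(ssd_loss(reg), 0.25)
  # identical frames -> 0
  same <- array(rep(runif(16), 3), c(4, 4, 3))
  expect_equal(ssd_loss(same), 0)
  # adding a constant to every frame leaves the value unchanged
  set.seed(1)
  r <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_equal(ssd_loss(r + 7), ssd_loss(r), tolerance = 1e-10)
  # invariant to frame permutation
  expect_equal(ssd_loss(r[, , c(3, 1, 2)]), ssd_loss(r), tolerance = 1e-12)
  # region restriction
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  rbar <- rowMeans(r, dims = 2)
  expect_equal(ssd_loss(r, region_mask(m)),
               mean((r[1, 1, ] - rbar[1, 1])^2))
  expect_error(ssd_loss(r[, , 1, drop = FALSE]), "at least 2")
})

test_that("NCC score is 1 for affinely related images and near 0 for noise", {
  set.seed(2)
  tpl <- smooth_image(32)
  expect_equal(ncc_loss(tpl, tpl), -1, tolerance = 1e-9)
  expect_equal(ncc_loss(tpl, 2.3 * tpl + 0.7), -1, tolerance = 1e-9)
  # independent white noise: average squared correlation stays small
  scores <- vapply(1:20, function(s) {
    set.seed(100 + s)
    a <- matrix(runif(64 * 64), 64)
    b <- matrix(runif(64 * 64), 64)
    -ncc_loss(a, b)
  }, numeric(1))
  expect_lt(mean(scores), 0.2)
  expect_true(all(scores >= 0 & scores <= 1))
  expect_error(ncc_loss(tpl, tpl, window_px = 64), "window")
})

test_that("zero-variance windows contribute zero to the NCC score", {
  tpl <- matrix(0, 16, 16)         # constant: every window degenerate
  frm <- smooth_image(16)
  expect_equal(ncc_loss(tpl, frm), 0)
})

test_that("regularizers match hand-computed values on tiny fields", {
  cfg3 <- loss_config(lambda3 = 1)
  # N = 2, one pixel, one component alternating +d/-d: circular first
  # differences are -2d and +2d, so the penalty is 8 d^2
  d <- 0.7
  u <- array(0, c(1, 1, 2, 2))
  u[1, 1, 1, ] <- c(d, -d)
  expect_equal(regularization(u, cfg3), 8 * d^2)
  # constant field: all penalties vanish
  uc <- array(3, c(4, 4, 2, 3))
  cfg_all <- loss_config(lambda1 = 1, lambda2 = 1, lambda3 = 1, lambda4 = 1)
  expect_equal(regularization(uc, cfg_all), 0)
  # spatially linear displacement: second derivatives vanish
  ul <- array(0, c(6, 6, 2, 2))
  ul[, , 1, ] <- matrix(seq_len(6), 6, 6)       # u1 = x1
  expect_equal(regularization(ul, loss_config(lambda2 = 1)), 0)
  # but first derivatives do not
  expect_gt(regularization(ul, loss_config(lambda1 = 1)), 0)
})

test_that("temporal regularizers are sensitive to frame order", {
  set.seed(3)
  u <- array(rnorm(4 * 4 * 2 * 6), c(4, 4, 2, 6))
  cfg <- loss_config(lambda3 = 1)
  v1 <- regularization(u, cfg)
  v2 <- regularization(u[, , , c(4, 1, 6, 2, 5, 3)], cfg)
  expect_false(isTRUE(all.equal(v1, v2)))
})

test_that("cyclic constraint matches hand evaluation", {
  # N frames with constant displacement d in one component over P pixels:
  # lambda_c * P * d^2
  u <- array(0, c(3, 3, 2, 4))
  u[, , 1, ] <- 2.5
  expect_equal(periodicity_constraint(u, lambda_c = 1), 9 * 2.5^2)
  expect_equal(periodicity_constraint(u, lambda_c = 0), 0)
  # zero temporal mean: satisfied exactly
  uz <- array(0, c(3, 3, 2, 4))
  uz[, , 1, ] <- rep(c(1, -1, 2, -2), each = 9)
  expect_equal(periodicity_constraint(uz, lambda_c = 5), 0)
})

test_that("total loss is zero for a static sequence with zero fields", {
  frames <- array(rep(smooth_image(8), 3), c(8, 8, 3))
  seq <- cine_sequence(frames)
  fields <- deformation_sequence(array(0, c(8, 8, 2, 3)))
  tpl <- template_image(frames[, , 1], origin = "selected_frame", index = 1)
  lt <- total_loss(seq, tpl, fields, loss_config())
  expect_equal(lt$value, 0)
})

test_that("analytic field gradients match finite differences (SSD + NCC)", {
  set.seed(4)
  frames <- array(c(smooth_image(8), smooth_image(8)), c(8, 8, 2))
  seq <- cine_sequence(frames)
  u <- array(runif(8 * 8 * 2 * 2, -0.3, 0.3), c(8, 8, 2, 2))
  fields <- deformation_sequence(u)
  tpl <- template_image(rowMeans(frames, dims = 2), origin = "average")
  for (cfg in list(
    loss_config(lambda1 = 0.3, lambda2 = 0.2, lambda3 = 0.5,
                lambda4 = 0.1, lambda_c = 0.7),
    loss_config(similarity = "ncc", ncc_window_px = 5, lambda3 = 0.2))) {
    lg <- gwcine:::total_loss_grad_fields(seq, tpl, fields, cfg)
    num <- numeric_loss_grad(seq, tpl, u, cfg)
    expect_lt(max(abs(num - lg$grad)) / max(abs(num)), 1e-4)
  }
})

test_that("ground-truth fields beat zero fields on noiseless phantoms", {
  for (seed in 1:3) {
    ph <- generate_phantom(phantom_spec(image_size = 32, num_frames = 6,
                                        motion_amplitude_px = 2,
                                        noise_std = 0, seed = seed))
    cfg <- loss_config(lambda3 = 1e-7)
    tpl <- select_template(ph$sequence)$template
    zero <- deformation_sequence(array(0, c(32, 32, 2, 6)))
    v_gt <- total_loss(ph$sequence, tpl, gt_registration_fields(ph),
                       cfg)$value
    v_0 <- total_loss(ph$sequence, tpl, zero, cfg)$value
    expect_lt(v_gt, v_0)
  }
})

test_that("full-map regularization penalizes the identity as documented", {
  # with regularize_displacement = FALSE the first-order term acts on
  # T = x + u; at u = 0 each pixel/frame contributes |dT/dx1|^2 + |dT/dx2|^2
  # = 2 (the identity map's unit gradients)
  u0 <- array(0, c(5, 5, 2, 2))
  cfg_map <- loss_config(lambda1 = 1, lambda2 = 0.5,
                         regularize_displacement = FALSE)
  expect_equal(regularization(u0, cfg_map), 2 * 25 * 2)
  # analytic gradient still matches finite differences
  set.seed(9)
  frames <- array(c(smooth_image(8), smooth_image(8)), c(8, 8, 2))
  seq <- cine_sequence(frames)
  u <- array(runif(8 * 8 * 2 * 2, -0.2, 0.2), c(8, 8, 2, 2))
  cfg_fd <- loss_config(lambda1 = 0.4, lambda2 = 0.2,
                        regularize_displacement = FALSE)
  tpl <- template_image(rowMeans(frames, dims = 2), origin = "average")
  lg <- gwcine:::total_loss_grad_fields(seq, tpl,
                                        deformation_sequence(u), cfg_fd)
  num <- numeric_loss_grad(seq, tpl, u, cfg_fd)
  expect_lt(max(abs(num - lg$grad)) / max(abs(num)), 1e-4)
})

test_that("loss configuration validation", {
  expect_error(loss_config(lambda1 = -1), ">= 0")
  expect_error(loss_config(ncc_window_px = 4), "odd")
  expect_error(loss_config(ncc_window_px = 1), "odd")
})
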