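test_that("SSIM identity, degenerate and structural-change cases", {
  set.seed(1)
  a <- smooth_image(32)
  expect_equal(ssim(a, a), 1)
  expect_equal(ssim(matrix(0.4, 16, 16), matrix(0.4, 16, 16)), 1)
  b <- 1 - a   # structural inversion
  expect_lt(ssim(a, b), 1)
  expect_equal(ssim(a, b), ssim(b, a))   # symmetry
  expect_error(ssim(a, matrix(0, 8, 8)), "differ")
  expect_error(ssim(matrix(0, 8, 8), matrix(0, 8, 8)), "at least")
})

test_that("SER identity cap, closed form and asymmetry", {
  set.seed(2)
  ref <- smooth_image(16) + 0.1
  expect_equal(ser(ref, ref), 300)
  img <- ref + 0.05
  expect_equal(ser(ref, img),
               10 * log10(sum(ref^2) / sum((ref - img)^2)))
  expect_false(isTRUE(all.equal(ser(ref, img), ser(img, ref))))
})

test_that("mutual information identity and independence bounds", {
  set.seed(3)
  a <- matrix(runif(64 * 64), 64)
  # identical images: MI equals the marginal histogram entropy
  ia <- pmin(floor(a * 64) + 1, 64)
  p <- tabulate(ia, 64) / length(ia)
  h <- -sum(p[p > 0] * log2(p[p > 0]))
  expect_equal(mutual_information(a, a), h, tolerance = 1e-10)
  # independent noise: MI reduces to the finite-sample histogram bias,
  # approximately (B-1)^2 / (2 N ln 2) bits for B^2 joint bins over N
  # pixels — about 0.04 bits at 16 bins on a 64x64 image
  mis <- vapply(1:20, function(s) {
    set.seed(200 + s)
    mutual_information(matrix(runif(64 * 64), 64),
                       matrix(runif(64 * 64), 64), bins = 16)
  }, numeric(1))
  expect_lt(mean(mis), 0.15)
  expect_true(all(mis >= 0))
  expect_equal(mean(mis), 15^2 / (2 * 4096 * log(2)), tolerance = 0.25)
})

test_that("Pearson correlation identity, affine case and constant warning", {
  set.seed(4)
  a <- smooth_image(16)
  expect_equal(pearson_cc(a, a), 1)
  expect_equal(pearson_cc(a, a + 0.3), 1)        # shift-invariant
  expect_warning(v <- pearson_cc(a, matrix(1, 16, 16)), "constant")
  expect_equal(v, 0)
})

test_that("paired tests reproduce binomial closed forms", {
  # 4 of 5 positive differences: P(Bin(5, .5) >= 4) = 6/32
  a <- c(1, 1, 1, 0, 1) + 10
  b <- c(0, 0, 0, 1, 0) + 10
  pt <- paired_tests(a, b)
  expect_equal(pt$sign_p_value, 6 / 32)
  # constant +1 differences with tiny jitter, n = 20
  set.seed(5)
  base <- runif(20)
  pt2 <- paired_tests(base + 1 + rnorm(20, sd = 1e-4), base)
  expect_lt(pt2$t_p_value, 1e-4)
  expect_equal(pt2$sign_p_value, 2^-20)
  # identical samples: t boundary 0.5, sign test undefined -> 1
  expect_warning(pt3 <- paired_tests(base, base), "ties")
  expect_equal(pt3$t_p_value, 0.5)
  expect_equal(pt3$sign_p_value, 1.0)
  expect_error(paired_tests(1:3, 1:4), "paired")
})

test_that("sample_ssim evaluates registered frames against the template", {
  # static noiseless phantom: any near-identity model keeps both frames
  # equal to the template
  ph <- generate_phantom(phantom_spec(image_size = 32, num_frames = 4,
                                      motion_amplitude_px = 0,
                                      noise_std = 0, seed = 6))
  cfg <- gw_config(L = 1, loss = loss_config(),
                   net = net_config(depth = 2, base_filters = 2, seed = 1))
  res <- register_gw(build_network(cfg$net), ph$sequence, cfg)
  s <- sample_ssim(res, c(2, 1))
  expect_equal(s, c(1, 1), tolerance = 1e-4)
  # equal indices give two identical values
  s2 <- sample_ssim(res, c(3, 3))
  expect_equal(s2[1], s2[2])
  expect_error(sample_ssim(res, c(1, 9)), "range")
})

test_that("forward selection picks the single dominating parameter", {
  # mocked training: activating lambda3 (at either candidate value) adds a
  # constant +0.05 to every SSIM value; everything else is baseline noise
  set.seed(7)
  base_sample <- 0.8 + runif(20, -0.01, 0.01)
  calls <- 0
  train_fn <- function(lams) {
    calls <<- calls + 1
    boost <- if (!is.null(lams$lambda3) && lams$lambda3 > 0) 0.05 else 0
    base_sample + boost
  }
  grid <- list(lambda1 = c(1e-7, 5e-7), lambda2 = c(1e-7, 5e-7),
               lambda3 = c(1e-7, 5e-7), lambda4 = c(1e-7, 5e-7),
               lambda_c = c(1e-7, 1e-5))
  sel <- suppressWarnings(forward_select(train_fn, grid))  # tied cells
  expect_named(sel$selected, "lambda3")
  # Stage 1 trains 2 values x 5 parameters = 10 networks
  expect_equal(sum(sel$stages$stage == 1), 10)
  # procedure stops at Stage 2: remaining 4 parameters x 2 values tried,
  # none kept
  expect_equal(sum(sel$stages$stage == 2), 8)
  expect_false(any(sel$stages$kept[sel$stages$stage == 2]))
  expect_equal(max(sel$stages$stage), 2)
  expect_equal(sel$n_trained, 1 + 10 + 8)
})

test_that("forward selection returns empty when nothing helps", {
  set.seed(8)
  base_sample <- 0.8 + runif(20, -0.01, 0.01)
  train_fn <- function(lams) base_sample + rnorm(20, sd = 1e-5)
  sel <- suppressWarnings(
    forward_select(train_fn, list(lambda1 = c(1e-7, 5e-7),
                                  lambda3 = c(1e-7, 5e-7))))
  expect_length(sel$selected, 0)
  expect_equal(max(sel$stages$stage), 1)
})

test_that("forward selection skips failing cells with a warning", {
  set.seed(9)
  base_sample <- 0.8 + runif(10, -0.01, 0.01)
  train_fn <- function(lams) {
    if (!is.null(lams$lambda1)) stop("diverged")
    boost <- if (!is.null(lams$lambda3)) 0.05 else 0
    base_sample + boost
  }
  w <- capture_warnings(
    sel <- forward_select(train_fn, list(lambda1 = c(1e-7),
                                         lambda3 = c(1e-7))))
  expect_true(any(grepl("skipped", w)))
  expect_named(sel$selected, "lambda3")
})

test_that("pseudocolor overlay highlights differences", {
  a <- matrix(0.5, 8, 8)
  b <- a; b[3, 3] <- 1
  rgb_arr <- plot_overlay(a, b, plot = FALSE)
  expect_equal(dim(rgb_arr), c(8, 8, 3))
  # agreeing pixels gray (R == G == B), differing pixel green-dominant
  expect_equal(rgb_arr[1, 1, 1], rgb_arr[1, 1, 2])
  expect_gt(rgb_arr[3, 3, 2], rgb_arr[3, 3, 1])
})
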