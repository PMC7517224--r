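test_that("phantom spec validation rejects degenerate parameters", {
  expect_error(phantom_spec(num_frames = 1), "num_frames")
  expect_error(phantom_spec(motion_amplitude_px = -1), "amplitude")
  expect_error(phantom_spec(noise_std = -0.1), "noise_std")
})

test_that("zero amplitude and zero noise give identical frames", {
  ph <- generate_phantom(phantom_spec(image_size = 32, num_frames = 5,
                                      motion_amplitude_px = 0,
                                      noise_std = 0, seed = 1))
  for (n in 2:5)
    expect_identical(ph$sequence$frames[, , n], ph$sequence$frames[, , 1])
  expect_true(all(ph$fields$displacements == 0))
})

test_that("generation is bit-reproducible for a fixed seed", {
  a <- generate_phantom(phantom_spec(seed = 42))
  b <- generate_phantom(phantom_spec(seed = 42))
  expect_identical(a$sequence$frames, b$sequence$frames)
  expect_identical(a$fields$displacements, b$fields$displacements)
  c <- generate_phantom(phantom_spec(seed = 43))
  expect_false(identical(a$sequence$frames, c$sequence$frames))
})

test_that("ground-truth displacements sum to zero over an even cycle", {
  # closed form: sum_n sin(2*pi*n/N) = 0, so the per-pixel temporal sum of
  # A * sin(2*pi*n/N) * s(x) vanishes exactly
  ph <- generate_phantom(phantom_spec(image_size = 32, num_frames = 8,
                                      motion_amplitude_px = 3, seed = 2))
  sums <- apply(ph$fields$displacements, c(1, 2, 3), sum)
  expect_lt(max(abs(sums)), 1e-10)
  # and the temporal mean matches the cyclic-constraint ideal
  expect_equal(periodicity_constraint(ph$fields, lambda_c = 1), 0,
               tolerance = 1e-18)
})

test_that("phantom sequences are normalized and cardiac-like", {
  ph <- generate_phantom(phantom_spec(seed = 3))
  expect_equal(min(ph$sequence$frames), 0)
  expect_equal(max(ph$sequence$frames), 1)
  expect_equal(dim(ph$sequence$frames), c(64, 64, 10))
  # phase 0 is the rest phase: zero ground-truth displacement
  expect_true(all(ph$fields$displacements[, , , 1] == 0))
  # maximum displacement magnitude matches the requested amplitude
  nrm <- sqrt(ph$fields$displacements[, , 1, ]^2 +
                ph$fields$displacements[, , 2, ]^2)
  expect_equal(max(nrm), 3 * max(abs(sin(2 * pi * (0:9) / 10))),
               tolerance = 1e-8)
})

test_that("noiseless phantoms are recovered by negated-field warping", {
  # small amplitude keeps the inverse-consistency error of the negation
  # within the interpolation-error bound
  ph <- generate_phantom(phantom_spec(image_size = 48, num_frames = 6,
                                      motion_amplitude_px = 1,
                                      noise_std = 0, seed = 4))
  undone <- warp_sequence(ph$sequence, gt_registration_fields(ph))
  base <- normalize_sequence(cine_sequence(
    array(ph$base, c(48, 48, 6))))$frames
  inner <- 4:45
  mae <- mean(abs(undone$frames[inner, inner, ] - base[inner, inner, ]))
  # interpolation-error scale: MAE of a half-pixel bilinear resample
  half <- array(0, c(48, 48, 2)); half[, , 1] <- 0.5; half[, , 2] <- 0.5
  base_img <- base[, , 1]
  interp_err <- mean(abs(warp_image(warp_image(base_img, half), -half) -
                           base_img)[inner, inner])
  expect_lt(mae, 2 * interp_err)
})

test_that("generate_dataset is reproducible and validates inputs", {
  r <- list(motion_amplitude_px = c(2, 4), noise_std = c(0, 0.02))
  a <- generate_dataset(5, r, seed = 1)
  b <- generate_dataset(5, r, seed = 1)
  expect_length(a, 5)
  for (i in 1:5)
    expect_identical(a[[i]]$sequence$frames, b[[i]]$sequence$frames)
  # collapsed ranges: same spec but different noise realizations
  pt <- generate_dataset(3, list(motion_amplitude_px = 3), seed = 2)
  expect_false(identical(pt[[1]]$sequence$frames, pt[[2]]$sequence$frames))
  expect_error(generate_dataset(0), "n_sequences")
  expect_error(generate_dataset(2, list(noise_std = numeric(0))), "empty")
})

test_that("gaussian-bump motion and blob texture variants generate", {
  ph <- generate_phantom(phantom_spec(image_size = 32, num_frames = 4,
                                      motion_model = "gaussian_bumps",
                                      texture = "blobs", seed = 5))
  expect_equal(dim(ph$sequence$frames), c(32, 32, 4))
  nrm <- sqrt(ph$fields$displacements[, , 1, ]^2 +
                ph$fields$displacements[, , 2, ]^2)
  expect_gt(max(nrm), 0)
})
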