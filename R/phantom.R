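#' Phantom specification
#'
#' Parameters of the synthetic cine generator. The defaults emulate, at desk
#' scale, the statistical structure of short-axis cardiac cine acquisitions:
#' one full motion cycle sampled at `num_frames` equally spaced phases,
#' smooth (bandlimited) elastic motion of a few pixels concentrated on an
#' annular "myocardium" band, ring-like texture and additive Gaussian noise,
#' with the sequence jointly normalized to `[0, 1]`.
#'
#' @param image_size side length in pixels.
#' @param num_frames number of cardiac phases N (>= 2).
#' @param motion_amplitude_px peak displacement A in pixels (>= 0).
#' @param motion_model `"radial_contraction"` (systole-like inward motion of
#'   an annulus) or `"gaussian_bumps"` (2-4 random smooth bumps).
#' @param noise_std standard deviation of additive Gaussian noise, in
#'   intensity units of the noise-free base image (>= 0).
#' @param texture `"rings"` (concentric sinusoidal rings) or `"blobs"`
#'   (random Gaussian blobs).
#' @param seed integer RNG seed; the full generation is reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 64, num_frames = 10,
                         motion_amplitude_px = 3,
                         motion_model = c("radial_contraction",
                                          "gaussian_bumps"),
                         noise_std = 0.01,
                         texture = c("rings", "blobs"), seed = 1) {
  motion_model <- match.arg(motion_model)
  texture <- match.arg(texture)
  if (num_frames < 2) stop("`num_frames` must be >= 2")
  if (motion_amplitude_px < 0) stop("`motion_amplitude_px` must be >= 0")
  if (noise_std < 0) stop("`noise_std` must be >= 0")
  if (image_size < 8) stop("`image_size` must be >= 8")
  structure(list(image_size = as.integer(image_size),
                 num_frames = as.integer(num_frames),
                 motion_amplitude_px = motion_amplitude_px,
                 motion_model = motion_model, noise_std = noise_std,
                 texture = texture, seed = as.integer(seed)),
            class = "phantom_spec")
}

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

phantom_base_image <- function(size, texture) {
  ctr <- (size + 1) / 2
  r <- sqrt(outer((seq_len(size) - ctr)^2, (seq_len(size) - ctr)^2, "+"))
  disk <- 1 / (1 + exp((r - 0.42 * size) / (0.02 * size)))  # soft disk edge
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  # static low-contrast "parenchyma": smooth random bumps covering the whole
  # frame, as in real thoracic images where structured content surrounds the
  # heart; an empty background would hand the groupwise similarity a
  # degenerate optimum (warping every frame into the flat region)
  bg <- matrix(0.3, size, size)
  nbg <- 25L
  bx <- runif(nbg, 1, size); by <- runif(nbg, 1, size)
  bamp <- runif(nbg, -0.15, 0.25)
  bsig <- runif(nbg, 0.04 * size, 0.09 * size)
  for (i in seq_len(nbg))
    bg <- bg + bamp[i] *
      exp(-((rows - by[i])^2 + (cols - bx[i])^2) / (2 * bsig[i]^2))
  if (texture == "rings") {
    # wavy rings: moderate contrast, period well above the motion amplitude,
    # angular modulation so tangential motion is observable
    theta <- atan2(rows - ctr, cols - ctr)
    fg <- 0.55 + 0.3 * cos(2 * pi * r / (0.2 * size) + 0.8 * sin(2 * theta))
  } else {
    nb <- 6L
    cx <- runif(nb, 0.2 * size, 0.8 * size)
    cy <- runif(nb, 0.2 * size, 0.8 * size)
    amp <- runif(nb, 0.4, 1)
    sig <- runif(nb, 0.05 * size, 0.12 * size)
    fg <- matrix(0, size, size)
    for (i in seq_len(nb))
      fg <- fg + amp[i] *
        exp(-((rows - cy[i])^2 + (cols - cx[i])^2) / (2 * sig[i]^2))
  }
  disk * fg + (1 - disk) * bg
}

# smooth spatial motion profile s(x), H x W x 2, max vector norm 1
phantom_motion_profile <- function(size, model) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- t(rows)
  dy <- rows - ctr; dx <- cols - ctr
  r <- sqrt(dy^2 + dx^2)
  if (model == "radial_contraction") {
    # gaussian band centered on a mid-radius annulus, pointing inward
    band <- exp(-(r - 0.24 * size)^2 / (2 * (0.10 * size)^2))
    rn <- pmax(r, 1e-9)
    s <- array(c(-dy / rn * band, -dx / rn * band), c(size, size, 2))
  } else {
    nb <- sample(2:4, 1)
    s <- array(0, c(size, size, 2))
    for (i in seq_len(nb)) {
      cx <- runif(1, 0.25 * size, 0.75 * size)
      cy <- runif(1, 0.25 * size, 0.75 * size)
      sig <- runif(1, 0.08 * size, 0.15 * size)
      g <- exp(-((rows - cy)^2 + (cols - cx)^2) / (2 * sig^2))
      th <- runif(1, 0, 2 * pi)
      s[, , 1] <- s[, , 1] + sin(th) * g
      s[, , 2] <- s[, , 2] + cos(th) * g
    }
  }
  nrm <- sqrt(s[, , 1]^2 + s[, , 2]^2)
  s / max(nrm)
}

#' Generate a synthetic cine sequence with known ground-truth motion
#'
#' Frames are produced by pull-warping a fixed textured base image with
#' per-phase displacement fields `u_n(x) = A * sin(2*pi*n/N) * s(x)`,
#' `n = 0..N-1`, where `s` is a smooth spatial profile with maximum vector
#' norm 1, then adding Gaussian noise and jointly normalizing to `[0, 1]`.
#' Phase 0 is the rest phase (zero displacement); for even N the per-pixel
#' temporal sum of the ground-truth displacements is exactly zero (the sine
#' sums out), matching the ideal of the cyclic-motion constraint.
#'
#' The returned fields are the generating fields: frame n equals the base
#' image pulled by `u_n`, so warping frame n with the *negated* field
#' approximately recovers the base image, and a registration network aligning
#' frames to a base-like template should recover approximately `-u_n`
#' (see [gt_registration_fields()]).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `sequence` (a [cine_sequence()]), `fields`
#'   (a [deformation_sequence()] of ground-truth generating fields) and
#'   `base` (the noise-free base image).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    sz <- spec$image_size; N <- spec$num_frames
    base <- phantom_base_image(sz, spec$texture)
    s <- phantom_motion_profile(sz, spec$motion_model)
    u <- array(0, c(sz, sz, 2, N))
    frames <- array(0, c(sz, sz, N))
    for (n in seq_len(N)) {
      a <- spec$motion_amplitude_px * sin(2 * pi * (n - 1) / N)
      u[, , , n] <- a * s
      frames[, , n] <- warp_image(base, u[, , , n])
    }
    if (spec$noise_std > 0)
      frames <- frames + array(rnorm(length(frames), sd = spec$noise_std),
                               dim(frames))
    seq <- normalize_sequence(cine_sequence(
      frames, subject_id = sprintf("phantom-%d", spec$seed)))
    list(sequence = seq, fields = deformation_sequence(u), base = base)
  })
}

#' Registration-direction ground truth of a phantom
#'
#' The generating fields map template points into the base image that each
#' frame samples; the field a registration method should output for frame n
#' (pulling the frame back onto a base-like template) is their negation, up
#' to the usual inverse-consistency error of order `|u| * |grad u|`.
#'
#' @param phantom output of [generate_phantom()].
#' @return a [deformation_sequence()].
#' @export
gt_registration_fields <- function(phantom) {
  deformation_sequence(-phantom$fields$displacements)
}

#' Phantom evaluation frame pair
#'
#' The two "distant frames" used for SSIM sampling: the phase of maximum
#' contraction (largest |sin|, the systole analogue) and the rest phase
#' (phase 0, the diastole analogue). 1-based frame indices.
#'
#' @param num_frames number of phases N.
#' @return integer vector `c(max_contraction_frame, rest_frame)`.
#' @export
phantom_frame_pair <- function(num_frames) {
  phases <- abs(sin(2 * pi * (seq_len(num_frames) - 1) / num_frames))
  c(which.max(phases), 1L)
}

#' Generate a reproducible phantom dataset
#'
#' Draws per-sequence specs from parameter ranges (each range a length-2
#' `c(min, max)` vector, or a single value) and generates each phantom with
#' a seed derived from `seed` and the sequence index, so regeneration is
#' exact and sequences differ in their noise/texture draws even when all
#' ranges collapse to points.
#'
#' @param n_sequences number of phantoms (>= 1).
#' @param spec_ranges named list of ranges for any of `image_size`,
#'   `num_frames`, `motion_amplitude_px`, `noise_std`; unnamed parameters use
#'   the [phantom_spec()] defaults.
#' @param seed integer master seed.
#' @param motion_model,texture passed through to [phantom_spec()].
#' @return list of [generate_phantom()] outputs.
#' @export
generate_dataset <- function(n_sequences, spec_ranges = list(), seed = 1,
                             motion_model = "radial_contraction",
                             texture = "rings") {
  if (!is.numeric(n_sequences) || n_sequences < 1)
    stop("`n_sequences` must be >= 1")
  if (!is.list(spec_ranges)) stop("`spec_ranges` must be a list")
  bad <- vapply(spec_ranges, function(r) length(r) < 1 || anyNA(r),
                logical(1))
  if (any(bad)) stop("empty or NA range for: ",
                     paste(names(spec_ranges)[bad], collapse = ", "))
  draw <- function(name, default, i, integer = FALSE) {
    r <- spec_ranges[[name]]
    if (is.null(r)) return(default)
    v <- if (length(r) == 1) r else
      with_seed(seed * 1000L + i * 7L + match(name, names(spec_ranges)),
                runif(1, min(r), max(r)))
    if (integer) as.integer(round(v)) else v
  }
  lapply(seq_len(n_sequences), function(i) {
    spec <- phantom_spec(
      image_size = draw("image_size", 64L, i, integer = TRUE),
      num_frames = draw("num_frames", 10L, i, integer = TRUE),
      motion_amplitude_px = draw("motion_amplitude_px", 3, i),
      noise_std = draw("noise_std", 0.01, i),
      motion_model = motion_model, texture = texture,
      seed = seed + 131L * i)
    generate_phantom(spec)
  })
}
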