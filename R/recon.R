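#' Undersampled k-space reconstruction problem
#'
#' Container for per-frame Cartesian k-space data `y` (orthonormal 2D DFT of
#' each frame, zeroed outside the sampled rows), the per-frame boolean row
#' masks, and the acceleration factor AF (ratio of total to retained
#' k-space lines). Optional coil sensitivity maps are accepted; the default
#' is a single uniform coil.
#'
#' @param y complex `H x W x N` array.
#' @param masks logical `H x N` matrix of sampled rows.
#' @param AF acceleration factor.
#' @param coil_maps optional complex `H x W` (single-coil) sensitivity map.
#' @return an object of class `recon_problem`.
#' @export
recon_problem <- function(y, masks, AF, coil_maps = NULL) {
  if (!is.array(y) || length(dim(y)) != 3L)
    stop("`y` must be an H x W x N array")
  if (!is.matrix(masks) || !all(dim(masks) == dim(y)[c(1, 3)]))
    stop("`masks` must be an H x N logical matrix")
  for (n in seq_len(dim(y)[3]))
    if (any(y[!masks[, n], , n] != 0))
      stop("`y` must be zero outside the sampled rows")
  structure(list(y = y, masks = masks, AF = AF, coil_maps = coil_maps),
            class = "recon_problem")
}

fft2 <- function(x) stats::fft(x) / sqrt(length(x))
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / sqrt(length(x))

# frame-wise undersampled orthonormal Fourier encoding and its adjoint
e_forward <- function(m, masks) {
  d <- dim(m)
  y <- array(0i, d)
  for (n in seq_len(d[3])) {
    k <- fft2(m[, , n])
    k[!masks[, n], ] <- 0
    y[, , n] <- k
  }
  y
}

e_adjoint <- function(y, masks) {
  d <- dim(y)
  m <- array(0i, d)
  for (n in seq_len(d[3])) {
    k <- y[, , n]
    k[!masks[, n], ] <- 0
    m[, , n] <- ifft2(k)
  }
  m
}

# k-space row indices of the fully sampled central band (around DC, which
# the unshifted DFT places at row 1)
center_rows <- function(h, frac = 0.08) {
  nc <- max(1L, as.integer(round(frac * h)))
  off <- seq.int(-((nc - 1L) %/% 2L), nc %/% 2L)
  sort(((off %% h) + h) %% h + 1L)
}

#' Undersample a cine sequence in k-space
#'
#' Takes the orthonormal 2D Fourier transform of every frame and retains
#' `ceiling(H / AF)` horizontal lines (k-space rows) per frame, zeroing the
#' rest. The default pattern keeps a fixed fully sampled central band (8% of
#' rows, around DC) plus per-frame seeded uniform-random lines; `"uniform"`
#' draws all lines at random.
#'
#' @param seq a [cine_sequence()].
#' @param AF acceleration factor (>= 1).
#' @param pattern `"center_plus_uniform"` or `"uniform"`.
#' @param seed integer seed for the random line draws.
#' @return a [recon_problem()].
#' @export
undersample <- function(seq, AF, pattern = c("center_plus_uniform",
                                             "uniform"), seed = 1) {
  stopifnot(inherits(seq, "cine_sequence"))
  pattern <- match.arg(pattern)
  if (AF < 1) stop("`AF` must be >= 1")
  d <- dim(seq$frames)
  h <- d[1]; N <- d[3]
  keep <- min(h, as.integer(ceiling(h / AF)))
  masks <- matrix(FALSE, h, N)
  with_seed(seed, {
    for (n in seq_len(N)) {
      rows <- if (keep >= h) seq_len(h)
      else if (pattern == "uniform") sample.int(h, keep)
      else {
        ctr <- center_rows(h)
        ctr <- ctr[seq_len(min(length(ctr), keep))]
        extra <- setdiff(seq_len(h), ctr)
        c(ctr, sample(extra, keep - length(ctr)))
      }
      masks[rows, n] <- TRUE
    }
  })
  y <- e_forward(array(as.complex(seq$frames), d), masks)
  recon_problem(y, masks, AF)
}

#' Zero-filled reconstruction
#'
#' The adjoint applied to the data, `E^H y`: inverse Fourier transform with
#' the missing lines left at zero. This is the minimum-norm least-squares
#' solution of the data-fidelity term and the usual starting point of
#' iterative reconstruction.
#'
#' @param problem a [recon_problem()].
#' @return complex `H x W x N` array.
#' @export
zero_filled <- function(problem) {
  stopifnot(inherits(problem, "recon_problem"))
  e_adjoint(problem$y, problem$masks)
}

soft_complex <- function(v, t) {
  a <- Mod(v)
  sc <- pmax(a - t, 0) / pmax(a, 1e-15)
  v * sc
}

warp_complex_seq <- function(m, u) {
  d <- dim(m)
  out <- array(0i, d)
  for (n in seq_len(d[3]))
    out[, , n] <- complex(
      real = warp_image(Re(m[, , n]), u[, , , n]),
      imaginary = warp_image(Im(m[, , n]), u[, , , n]))
  out
}

dtime <- function(z) {
  N <- dim(z)[3]
  z[, , c(2:N, 1), drop = FALSE] - z
}

dtime_t <- function(z) {
  N <- dim(z)[3]
  z[, , c(N, 1:(N - 1)), drop = FALSE] - z
}

#' Motion-compensated compressed-sensing reconstruction
#'
#' Single outer motion-estimation / motion-compensation iteration of the
#' classical sparsity-regularized problem
#' `min_m 1/2 ||y - E m||^2 + lambda ||Phi T m||_1`, where `Phi T` is the
#' circular temporal finite difference of the motion-compensated (warped)
#' image sequence: (1) zero-filled reconstruction `m0 = E^H y`; (2) the
#' motion operator `T` is obtained by running groupwise registration on
#' `|m0|` (the complex phase is untouched by `T`); (3) with `T` fixed, the
#' problem is solved by an ADMM-style proximal splitting in which sampled
#' k-space lines are enforced exactly (hard data consistency) and the warp
#' adjoint is approximated by warping with the negated fields. With
#' `lambda = 0` the zero-filled solution is returned; with AF = 1 the data
#' consistency pins every line, so the output equals the fully sampled
#' reconstruction.
#'
#' @param problem a [recon_problem()].
#' @param motion_op `NULL` (no motion compensation: `T` is the identity) or
#'   a function mapping a magnitude [cine_sequence()] to a
#'   [deformation_sequence()], e.g. a closure around [register_gw()].
#' @param lambda sparsity weight (default 0.01).
#' @param rho ADMM penalty parameter (default 1).
#' @param max_iters outer ADMM iterations (default 25).
#' @param inner_iters gradient steps of the quadratic m-update (default 4).
#' @param tol relative-change stopping tolerance (default 1e-5); if still
#'   above `tol` after `max_iters` a warning with diagnostics is emitted and
#'   the best iterate is returned.
#' @return magnitude [cine_sequence()] with attribute `"complex"` carrying
#'   the complex reconstruction.
#' @export
reconstruct <- function(problem, motion_op = NULL, lambda = 0.01, rho = 1,
                        max_iters = 25, inner_iters = 4, tol = 1e-5) {
  stopifnot(inherits(problem, "recon_problem"))
  m0 <- zero_filled(problem)
  d <- dim(m0)
  as_seq <- function(m) cine_sequence(array(Mod(m), d))
  if (lambda == 0) {
    out <- as_seq(m0); attr(out, "complex") <- m0
    return(out)
  }
  u <- if (is.null(motion_op)) array(0, c(d[1], d[2], 2L, d[3]))
  else {
    f <- motion_op(normalize_sequence(as_seq(m0)))
    if (inherits(f, "deformation_sequence")) f$displacements else f
  }
  G <- function(m) dtime(warp_complex_seq(m, u))
  Gt <- function(z) warp_complex_seq(dtime_t(z), -u)
  dc <- function(m) {
    # exact data consistency on the sampled rows
    for (n in seq_len(d[3])) {
      k <- fft2(m[, , n])
      k[problem$masks[, n], ] <- problem$y[problem$masks[, n], , n]
      m[, , n] <- ifft2(k)
    }
    m
  }
  tau <- 1 / (8 * rho)   # 1 / (rho * ||G||^2 bound)
  m <- dc(m0)
  z <- soft_complex(G(m), lambda / rho)
  dual <- G(m) - z
  rel <- Inf
  for (it in seq_len(max_iters)) {
    m_old <- m
    for (j in seq_len(inner_iters)) {
      grad <- rho * Gt(G(m) - z + dual)
      m <- dc(m - tau * grad)
    }
    Gm <- G(m)
    z <- soft_complex(Gm + dual, lambda / rho)
    dual <- dual + Gm - z
    rel <- sqrt(sum(Mod(m - m_old)^2)) / max(sqrt(sum(Mod(m)^2)), 1e-12)
    if (rel < tol) break
  }
  if (rel >= tol)
    warning(sprintf(
      "reconstruction stopped after %d iterations (relative change %.3g > %.3g)",
      max_iters, rel, tol))
  out <- as_seq(m); attr(out, "complex") <- m
  out
}

#' Compare a reconstruction against a reference sequence
#'
#' @param recon,reference [cine_sequence()] objects of equal shape.
#' @return list with `per_frame` SSIM values and their `mean`.
#' @export
compare_recon <- function(recon, reference) {
  stopifnot(inherits(recon, "cine_sequence"),
            inherits(reference, "cine_sequence"))
  if (!all(dim(recon$frames) == dim(reference$frames)))
    stop("sequence shapes differ")
  per <- vapply(seq_len(n_frames(recon)), function(n)
    ssim(recon$frames[, , n], reference$frames[, , n]), numeric(1))
  list(per_frame = per, mean = mean(per))
}
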