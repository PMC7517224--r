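#' Loss configuration
#'
#' Weights and choices for the training loss: a similarity term (groupwise
#' SSD, or negative windowed normalized cross-correlation against the
#' template), four smoothness penalties on the displacement fields
#' (first/second order, spatial/temporal) and a cyclic-motion constraint.
#'
#' @param similarity `"ssd"` or `"ncc"`.
#' @param ncc_window_px odd window side for the local NCC (default 9).
#' @param lambda1 weight of the first-order spatial gradient penalty.
#' @param lambda2 weight of the second-order spatial gradient penalty
#'   (with doubled mixed term).
#' @param lambda3 weight of the first-order circular temporal difference
#'   penalty.
#' @param lambda4 weight of the second-order circular temporal difference
#'   penalty.
#' @param lambda_c weight of the cyclic-motion (zero temporal mean
#'   displacement) constraint.
#' @param region optional [region_mask()] restricting all terms; `NULL`
#'   means the whole image.
#' @param regularize_displacement penalize derivatives of the displacement
#'   `u` rather than of the full map `x + u`, so the identity transform has
#'   zero cost (default `TRUE`).
#' @return an object of class `loss_config`.
#' @export
loss_config <- function(similarity = c("ssd", "ncc"), ncc_window_px = 9,
                        lambda1 = 0, lambda2 = 0, lambda3 = 0, lambda4 = 0,
                        lambda_c = 0, region = NULL,
                        regularize_displacement = TRUE) {
  similarity <- match.arg(similarity)
  lam <- c(lambda1, lambda2, lambda3, lambda4, lambda_c)
  if (any(lam < 0)) stop("all loss weights must be >= 0")
  if (ncc_window_px < 3 || ncc_window_px %% 2 == 0)
    stop("`ncc_window_px` must be odd and >= 3")
  if (!is.null(region)) stopifnot(inherits(region, "region_mask"))
  structure(list(similarity = similarity,
                 ncc_window_px = as.integer(ncc_window_px),
                 lambda1 = lambda1, lambda2 = lambda2, lambda3 = lambda3,
                 lambda4 = lambda4, lambda_c = lambda_c, region = region,
                 regularize_displacement = isTRUE(regularize_displacement)),
            class = "loss_config")
}

seq_frames <- function(x) {
  if (inherits(x, "cine_sequence")) x$frames else x
}

#' Groupwise SSD of a registered sequence
#'
#' Sum over the region of the per-pixel temporal variance-like criterion
#' `(1/N) * sum_n (r_n(x) - rbar(x))^2`, where `rbar` is the per-pixel
#' temporal mean of the registered frames. Zero iff all registered frames
#' coincide on the region; invariant to adding a constant to every frame and
#' to frame permutation.
#'
#' @param registered a registered [cine_sequence()] or `H x W x N` array.
#' @param region optional [region_mask()].
#' @return scalar loss value (>= 0).
#' @export
ssd_loss <- function(registered, region = NULL) {
  r <- seq_frames(registered)
  N <- dim(r)[3]
  if (N < 2) stop("groupwise SSD needs at least 2 frames")
  m <- region_matrix(region, dim(r)[1:2])
  rbar <- rowMeans(r, dims = 2)
  dev2 <- rowSums((r - as.vector(rbar))^2, dims = 2) / N
  if (!is.null(m)) sum(dev2[m]) else sum(dev2)
}

ssd_loss_grad <- function(registered, region = NULL) {
  r <- seq_frames(registered)
  N <- dim(r)[3]
  rbar <- rowMeans(r, dims = 2)
  g <- (2 / N) * (r - as.vector(rbar))
  m <- region_matrix(region, dim(r)[1:2])
  if (!is.null(m)) g <- g * as.vector(m)
  g
}

# local sums over edge-clipped square windows (side 2*rad+1) via integral
# images; returns the summed matrix
box_sum <- function(x, rad) {
  h <- nrow(x); w <- ncol(x)
  cs <- apply(x, 2, cumsum)
  hi <- pmin(seq_len(h) + rad, h); lo <- seq_len(h) - rad - 1L
  y <- cs[hi, , drop = FALSE] -
    rbind(matrix(0, sum(lo < 1), w), cs[lo[lo >= 1], , drop = FALSE])
  cs2 <- t(apply(y, 1, cumsum))
  hj <- pmin(seq_len(w) + rad, w); lj <- seq_len(w) - rad - 1L
  cs2[, hj, drop = FALSE] -
    cbind(matrix(0, h, sum(lj < 1)), cs2[, lj[lj >= 1], drop = FALSE])
}

ncc_terms <- function(f, m, window) {
  rad <- (window - 1L) %/% 2L
  h <- nrow(f); w <- ncol(f)
  if (window > h || window > w) stop("NCC window larger than the image")
  n <- box_sum(matrix(1, h, w), rad)
  fbar <- box_sum(f, rad) / n
  mbar <- box_sum(m, rad) / n
  cross <- box_sum(f * m, rad) - n * fbar * mbar
  varf <- pmax(box_sum(f * f, rad) - n * fbar^2, 0)
  varm <- pmax(box_sum(m * m, rad) - n * mbar^2, 0)
  eps <- 1e-10
  valid <- varf > eps & varm > eps
  s <- matrix(0, h, w)
  s[valid] <- cross[valid]^2 / (varf[valid] * varm[valid])
  list(s = s, cross = cross, varf = varf, varm = varm, valid = valid,
       fbar = fbar, mbar = mbar, rad = rad)
}

#' Negative local normalized cross-correlation
#'
#' Squared NCC computed in square windows around every pixel (local means
#' subtracted, windows clipped at the image edge), averaged over pixels so
#' the score lies in `[0, 1]`; the returned loss is the negative score.
#' Windows where either image has (numerically) zero variance contribute 0.
#' The score is invariant to affine intensity changes `a*m + b`, `a > 0`, of
#' either image.
#'
#' @param template a [template_image()] or `H x W` matrix.
#' @param registered_frame `H x W` matrix.
#' @param window_px odd window side (default 9).
#' @return scalar in `[-1, 0]`.
#' @export
ncc_loss <- function(template, registered_frame, window_px = 9) {
  f <- template_matrix(template)
  if (!all(dim(f) == dim(registered_frame)))
    stop("template and frame shapes differ")
  t_ <- ncc_terms(f, registered_frame, window_px)
  -mean(t_$s)
}

# gradient of ncc_loss with respect to the registered frame
ncc_loss_grad <- function(template, registered_frame, window_px = 9) {
  f <- template_matrix(template)
  m <- registered_frame
  t_ <- ncc_terms(f, m, window_px)
  A <- matrix(0, nrow(f), ncol(f)); B <- A
  A[t_$valid] <- 2 * t_$cross[t_$valid] /
    (t_$varf[t_$valid] * t_$varm[t_$valid])
  B[t_$valid] <- t_$cross[t_$valid]^2 /
    (t_$varf[t_$valid] * t_$varm[t_$valid]^2)
  g <- f * box_sum(A, t_$rad) - box_sum(A * t_$fbar, t_$rad) -
    2 * (m * box_sum(B, t_$rad) - box_sum(B * t_$mbar, t_$rad))
  # score = mean(s); loss = -score
  -g / length(f)
}

# ---- finite-difference operators on fields (H x W x 2 x N) ----------------

# forward spatial difference along rows/cols; the last position replicates
# the preceding difference (one-sided derivative at the boundary), so
# spatially affine fields have constant first and vanishing second
# derivatives everywhere, boundary included
dfwd <- function(u, dim) {
  d <- base::dim(u); out <- array(0, d)
  if (dim == 1L) {
    out[seq_len(d[1] - 1), , , ] <- u[2:d[1], , , , drop = FALSE] -
      u[seq_len(d[1] - 1), , , , drop = FALSE]
    out[d[1], , , ] <- out[d[1] - 1, , , , drop = FALSE]
  } else {
    out[, seq_len(d[2] - 1), , ] <- u[, 2:d[2], , , drop = FALSE] -
      u[, seq_len(d[2] - 1), , , drop = FALSE]
    out[, d[2], , ] <- out[, d[2] - 1, , , drop = FALSE]
  }
  out
}

# transpose of dfwd (the replicated last row folds into rows H-1 and H)
dfwd_t <- function(v, dim) {
  d <- base::dim(v)
  out <- array(0, d)
  if (dim == 1L) {
    h <- d[1]
    out[seq_len(h - 1), , , ] <- -v[seq_len(h - 1), , , , drop = FALSE]
    out[2:h, , , ] <- out[2:h, , , , drop = FALSE] +
      v[seq_len(h - 1), , , , drop = FALSE]
    out[h, , , ] <- out[h, , , , drop = FALSE] + v[h, , , , drop = FALSE]
    out[h - 1, , , ] <- out[h - 1, , , , drop = FALSE] -
      v[h, , , , drop = FALSE]
  } else {
    w <- d[2]
    out[, seq_len(w - 1), , ] <- -v[, seq_len(w - 1), , , drop = FALSE]
    out[, 2:w, , ] <- out[, 2:w, , , drop = FALSE] +
      v[, seq_len(w - 1), , , drop = FALSE]
    out[, w, , ] <- out[, w, , , drop = FALSE] + v[, w, , , drop = FALSE]
    out[, w - 1, , ] <- out[, w - 1, , , drop = FALSE] -
      v[, w, , , drop = FALSE]
  }
  out
}

# circular temporal differences (frame indices mod N)
dtemp1 <- function(u) {
  N <- dim(u)[4]
  u[, , , c(2:N, 1), drop = FALSE] - u
}

dtemp1_t <- function(v) {
  N <- dim(v)[4]
  v[, , , c(N, 1:(N - 1)), drop = FALSE] - v
}

dtemp2 <- function(u) {
  N <- dim(u)[4]
  u[, , , c(2:N, 1), drop = FALSE] - 2 * u +
    u[, , , c(N, 1:(N - 1)), drop = FALSE]
}

mask_field <- function(x, m) if (is.null(m)) x else x * as.vector(m)

#' Smoothness regularization of a deformation sequence
#'
#' Weighted sum of four quadratic penalties over the region, each summed over
#' both displacement components and all frames: first-order spatial
#' gradients, second-order spatial gradients (with the mixed derivative
#' counted twice), and first/second-order *circular* temporal differences
#' (frame indices mod N, so the last frame couples to the first — the
#' sequence spans one full motion cycle). Spatial derivatives act on the
#' displacement, so the identity transform costs zero (set
#' `regularize_displacement = FALSE` in [loss_config()] to penalize the full
#' map `x + u`, whose identity part contributes its unit gradients — 2 per
#' pixel and frame — to the first-order term).
#'
#' @param fields a [deformation_sequence()] or `H x W x 2 x N` array.
#' @param cfg a [loss_config()] (its lambdas and region are used).
#' @param region optional override of `cfg$region`.
#' @return scalar (>= 0).
#' @export
regularization <- function(fields, cfg, region = NULL) {
  u <- if (inherits(fields, "deformation_sequence")) fields$displacements
       else fields
  region <- region %||% cfg$region
  m <- region_matrix(region, dim(u)[1:2])
  if (!cfg$regularize_displacement) {
    d <- dim(u)
    u <- u + array(c(rep(seq_len(d[1]), d[2]),
                     rep(seq_len(d[2]), each = d[1])),
                   c(d[1], d[2], 2, 1))[, , , rep(1, d[4]), drop = FALSE]
  }
  N <- dim(u)[4]
  if ((cfg$lambda3 > 0 || cfg$lambda4 > 0) && N < 2)
    stop("temporal regularization needs at least 2 frames")
  total <- 0
  if (cfg$lambda1 > 0) {
    r1 <- dfwd(u, 1)^2 + dfwd(u, 2)^2
    total <- total + cfg$lambda1 * sum(mask_field(r1, m))
  }
  if (cfg$lambda2 > 0) {
    r2 <- dfwd(dfwd(u, 1), 1)^2 + dfwd(dfwd(u, 2), 2)^2 +
      2 * dfwd(dfwd(u, 1), 2)^2
    total <- total + cfg$lambda2 * sum(mask_field(r2, m))
  }
  if (cfg$lambda3 > 0)
    total <- total + cfg$lambda3 * sum(mask_field(dtemp1(u)^2, m))
  if (cfg$lambda4 > 0)
    total <- total + cfg$lambda4 * sum(mask_field(dtemp2(u)^2, m))
  total
}

regularization_grad <- function(fields, cfg, region = NULL) {
  u <- if (inherits(fields, "deformation_sequence")) fields$displacements
       else fields
  region <- region %||% cfg$region
  m <- region_matrix(region, dim(u)[1:2])
  g <- array(0, dim(u))
  uu <- u
  if (!cfg$regularize_displacement) {
    d <- dim(u)
    uu <- u + array(c(rep(seq_len(d[1]), d[2]),
                      rep(seq_len(d[2]), each = d[1])),
                    c(d[1], d[2], 2, 1))[, , , rep(1, d[4]), drop = FALSE]
  }
  if (cfg$lambda1 > 0)
    g <- g + 2 * cfg$lambda1 *
      (dfwd_t(mask_field(dfwd(uu, 1), m), 1) +
       dfwd_t(mask_field(dfwd(uu, 2), m), 2))
  if (cfg$lambda2 > 0)
    g <- g + 2 * cfg$lambda2 *
      (dfwd_t(dfwd_t(mask_field(dfwd(dfwd(uu, 1), 1), m), 1), 1) +
       dfwd_t(dfwd_t(mask_field(dfwd(dfwd(uu, 2), 2), m), 2), 2) +
       2 * dfwd_t(dfwd_t(mask_field(dfwd(dfwd(uu, 1), 2), m), 2), 1))
  if (cfg$lambda3 > 0)
    g <- g + 2 * cfg$lambda3 * dtemp1_t(mask_field(dtemp1(uu), m))
  if (cfg$lambda4 > 0)
    g <- g + 2 * cfg$lambda4 * dtemp2(mask_field(dtemp2(uu), m))
  g
}

#' Cyclic-motion constraint
#'
#' Penalizes the squared *temporal mean* displacement per pixel and
#' component: `lambda_c * sum_x sum_comp ((1/N) sum_n u_n(x))^2`. For a
#' closed motion cycle the displacements of a material point sum to zero
#' over the cycle, so the penalty vanishes; it does not penalize motion
#' itself, only a net drift.
#'
#' @param fields a [deformation_sequence()] or `H x W x 2 x N` array.
#' @param lambda_c constraint weight (>= 0).
#' @param region optional [region_mask()].
#' @return scalar (>= 0).
#' @export
periodicity_constraint <- function(fields, lambda_c, region = NULL) {
  if (lambda_c == 0) return(0)
  u <- if (inherits(fields, "deformation_sequence")) fields$displacements
       else fields
  ubar <- rowMeans(u, dims = 3)    # H x W x 2
  m <- region_matrix(region, dim(u)[1:2])
  v <- ubar^2
  if (!is.null(m)) v <- v * as.vector(m)
  lambda_c * sum(v)
}

periodicity_constraint_grad <- function(fields, lambda_c, region = NULL) {
  u <- if (inherits(fields, "deformation_sequence")) fields$displacements
       else fields
  d <- dim(u)
  if (lambda_c == 0) return(array(0, d))
  ubar <- rowMeans(u, dims = 3)
  m <- region_matrix(region, d[1:2])
  if (!is.null(m)) ubar <- ubar * as.vector(m)
  g0 <- (2 * lambda_c / d[4]) * ubar
  array(g0, d)  # same gradient for every frame
}

#' Total registration loss
#'
#' Similarity + regularization + constraint, evaluated for a sequence, a
#' template and candidate deformation fields. The similarity acts on the
#' registered (warped) frames: groupwise SSD about their temporal mean, or
#' the accumulated negative windowed NCC of each registered frame against
#' the template. The whole quantity is differentiable in the fields (see
#' `gwcine:::total_loss_grad_fields`), which is what the training loop
#' backpropagates through the network.
#'
#' @param seq a [cine_sequence()].
#' @param template a [template_image()] or `H x W` matrix.
#' @param fields a [deformation_sequence()].
#' @param cfg a [loss_config()].
#' @return list with `value` and the individual `similarity`,
#'   `regularization`, `constraint` components plus the `registered`
#'   sequence.
#' @export
total_loss <- function(seq, template, fields, cfg) {
  stopifnot(inherits(seq, "cine_sequence"), inherits(cfg, "loss_config"))
  registered <- warp_sequence(seq, fields)
  sim <- if (cfg$similarity == "ssd") {
    ssd_loss(registered, cfg$region)
  } else {
    tpl <- template_matrix(template)
    sum(vapply(seq_len(n_frames(registered)), function(n)
      ncc_loss(tpl, registered$frames[, , n], cfg$ncc_window_px),
      numeric(1)))
  }
  reg <- regularization(fields, cfg)
  con <- periodicity_constraint(fields, cfg$lambda_c, cfg$region)
  list(value = sim + reg + con, similarity = sim, regularization = reg,
       constraint = con, registered = registered)
}

# loss value plus analytic gradient with respect to the fields; used both by
# the trainer (chained into the network) and by gradient-check tests
total_loss_grad_fields <- function(seq, template, fields, cfg) {
  registered <- warp_sequence(seq, fields)
  N <- n_frames(seq)
  u <- fields$displacements
  if (cfg$similarity == "ssd") {
    sim <- ssd_loss(registered, cfg$region)
    dreg <- ssd_loss_grad(registered, cfg$region)
  } else {
    tpl <- template_matrix(template)
    sim <- 0
    dreg <- array(0, dim(registered$frames))
    for (n in seq_len(N)) {
      sim <- sim + ncc_loss(tpl, registered$frames[, , n], cfg$ncc_window_px)
      dreg[, , n] <- ncc_loss_grad(tpl, registered$frames[, , n],
                                   cfg$ncc_window_px)
    }
  }
  g <- array(0, dim(u))
  for (n in seq_len(N))
    g[, , , n] <- warp_grad_field(seq$frames[, , n], u[, , , n],
                                  dreg[, , n])
  g <- g + regularization_grad(fields, cfg) +
    periodicity_constraint_grad(fields, cfg$lambda_c, cfg$region)
  reg <- regularization(fields, cfg)
  con <- periodicity_constraint(fields, cfg$lambda_c, cfg$region)
  list(value = sim + reg + con, similarity = sim, regularization = reg,
       constraint = con, grad = g, registered = registered)
}
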