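#' Warp an image with a dense displacement field
#'
#' Backward (pull) warping with bilinear interpolation: the output at pixel
#' `x = (r, c)` is the input sampled at `x + u(x)`. Sample positions outside
#' the image are clamped to the edge, so no artificial dark border is
#' introduced. The operation is differentiable with respect to both the image
#' and the field (see [warp_grad_field()]), which is what makes it usable as
#' the spatial-transformer stage of gradient-based registration training.
#'
#' @param image numeric `H x W` matrix.
#' @param field numeric `H x W x 2` displacement array in pixels
#'   (component 1 along rows, component 2 along columns).
#' @return warped `H x W` matrix.
#' @export
warp_image <- function(image, field) {
  g <- warp_prepare(image, field)
  w11 <- (1 - g$fr) * (1 - g$fc); w21 <- g$fr * (1 - g$fc)
  w12 <- (1 - g$fr) * g$fc;       w22 <- g$fr * g$fc
  out <- w11 * image[g$i11] + w21 * image[g$i21] +
         w12 * image[g$i12] + w22 * image[g$i22]
  matrix(out, nrow(image), ncol(image))
}

# shared geometry for warp forward/backward: clamped sample coordinates,
# integer corners (as linear indices) and interpolation fractions
warp_prepare <- function(image, field) {
  h <- nrow(image); w <- ncol(image)
  if (!is.array(field) || length(dim(field)) != 3L ||
      !all(dim(field) == c(h, w, 2L)))
    stop("`field` must be an H x W x 2 array matching the image")
  r <- rep.int(seq_len(h), w) + as.vector(field[, , 1])
  c_ <- rep(seq_len(w), each = h) + as.vector(field[, , 2])
  r <- pmin.int(pmax.int(r, 1), h)
  c_ <- pmin.int(pmax.int(c_, 1), w)
  r0 <- pmin.int(floor(r), h - 1L); c0 <- pmin.int(floor(c_), w - 1L)
  if (h == 1L) r0 <- rep.int(1, length(r))
  if (w == 1L) c0 <- rep.int(1, length(c_))
  fr <- r - r0; fc <- c_ - c0
  i11 <- r0 + (c0 - 1) * h
  list(fr = fr, fc = fc, i11 = i11, i21 = i11 + (h > 1),
       i12 = i11 + (w > 1) * h, i22 = i11 + (h > 1) + (w > 1) * h,
       clamped_r = (r <= 1 | r >= h), clamped_c = (c_ <= 1 | c_ >= w))
}

#' Gradient of a warped image with respect to the displacement field
#'
#' Given the gradient of a scalar loss with respect to the warp output,
#' returns its gradient with respect to the field, by the chain rule through
#' the bilinear kernel. Where the sample position is clamped at the image
#' edge the derivative is zero (the clamp is locally constant).
#'
#' @param image,field as in [warp_image()].
#' @param upstream `H x W` matrix, dLoss/dOutput.
#' @return `H x W x 2` array dLoss/dField.
#' @export
warp_grad_field <- function(image, field, upstream) {
  g <- warp_prepare(image, field)
  # d out / d r = (1-fc)*(I21-I11) + fc*(I22-I12); analogous for columns
  dr <- (1 - g$fc) * (image[g$i21] - image[g$i11]) +
        g$fc * (image[g$i22] - image[g$i12])
  dc <- (1 - g$fr) * (image[g$i12] - image[g$i11]) +
        g$fr * (image[g$i22] - image[g$i21])
  dr[g$clamped_r] <- 0
  dc[g$clamped_c] <- 0
  u <- as.vector(upstream)
  array(c(u * dr, u * dc), c(nrow(image), ncol(image), 2L))
}

#' Warp every frame of a sequence
#'
#' Frame-wise [warp_image()]: frame `n` is pulled back onto the template grid
#' with its own displacement field, yielding the registered sequence.
#'
#' @param seq a [cine_sequence()].
#' @param fields a [deformation_sequence()] of matching shape.
#' @return registered [cine_sequence()].
#' @export
warp_sequence <- function(seq, fields) {
  stopifnot(inherits(seq, "cine_sequence"),
            inherits(fields, "deformation_sequence"))
  check_seq_fields(seq, fields)
  out <- seq
  for (n in seq_len(n_frames(seq)))
    out$frames[, , n] <- warp_image(seq$frames[, , n],
                                    fields$displacements[, , , n])
  out
}
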