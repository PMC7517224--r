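#' Structural similarity index
#'
#' Standard SSIM with an 11x11 Gaussian weighting window (sigma 1.5),
#' stability constants K1 = 0.01, K2 = 0.03 and dynamic range 1 (images are
#' expected in `[0, 1]`); the local map is averaged over the valid region.
#' Symmetric in its arguments; equals 1 iff the images are identical
#' (including the constant-image case, which the K constants stabilize).
#'
#' @param a,b numeric matrices of equal shape, at least 11 x 11.
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  win <- 11L; sigma <- 1.5
  if (nrow(a) < win || ncol(a) < win)
    stop("images must be at least ", win, " pixels in each dimension")
  g <- exp(-((seq_len(win) - (win + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  filt <- function(x) {
    kh <- valid_band(nrow(x), g); kw <- valid_band(ncol(x), g)
    kh %*% x %*% t(kw)
  }
  C1 <- 0.01^2; C2 <- 0.03^2
  mu1 <- filt(a); mu2 <- filt(b)
  s11 <- filt(a * a) - mu1^2
  s22 <- filt(b * b) - mu2^2
  s12 <- filt(a * b) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}

# banded valid-convolution matrix for a 1D kernel, cached per (n, kernel)
valid_band <- local({
  cache <- new.env(parent = emptyenv())
  function(n, g) {
    key <- paste0(n, ":", length(g))
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- n - length(g) + 1L
    K <- matrix(0, m, n)
    for (i in seq_len(m)) K[i, i:(i + length(g) - 1L)] <- g
    cache[[key]] <- K
    K
  }
})

#' Signal-to-error ratio
#'
#' `SER = 10 * log10(sum(ref^2) / sum((ref - img)^2))` in dB, capped at
#' 300 dB for (numerically) identical inputs. Asymmetric: the first argument
#' is the reference.
#'
#' @param ref reference image.
#' @param img test image of the same shape.
#' @return scalar in dB.
#' @export
ser <- function(ref, img) {
  if (!all(dim(ref) == dim(img))) stop("image shapes differ")
  err <- sum((ref - img)^2)
  if (err == 0) return(300)
  min(10 * log10(sum(ref^2) / err), 300)
}

#' Mutual information between two images
#'
#' Estimated from a joint intensity histogram with `bins` equal-width bins
#' spanning `[0, 1]` (values outside are clamped), in bits. For identical
#' images this equals the marginal (histogram) entropy.
#'
#' @param a,b numeric matrices of equal shape, intensities nominally in
#'   `[0, 1]`.
#' @param bins number of histogram bins per axis (default 64).
#' @return scalar >= 0, in bits.
#' @export
mutual_information <- function(a, b, bins = 64) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  ia <- pmin.int(pmax.int(floor(as.vector(a) * bins) + 1L, 1L), bins)
  ib <- pmin.int(pmax.int(floor(as.vector(b) * bins) + 1L, 1L), bins)
  joint <- tabulate(ia + bins * (ib - 1L), bins * bins) / length(ia)
  pj <- matrix(joint, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log2(pj[nz] / outer(pa, pb)[nz]))
}

#' Global Pearson correlation of two images
#'
#' @param a,b numeric matrices of equal shape.
#' @return correlation in `[-1, 1]`; 0 (with a warning) when either image is
#'   constant.
#' @export
pearson_cc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant image: correlation undefined, returning 0")
    return(0)
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' SSIM sample at two distant frames
#'
#' SSIM of each of two selected registered frames against the final
#' template. The frames are chosen far apart in the motion cycle (for the
#' cardiac application, systole and diastole; for phantoms, the phase of
#' maximum contraction and the rest phase, see [phantom_frame_pair()]), so
#' the per-sequence sample is weakly correlated.
#'
#' @param result a `registration_result` from [register_gw()].
#' @param frame_pair integer vector of two 1-based frame indices.
#' @return numeric vector of two SSIM values.
#' @export
sample_ssim <- function(result, frame_pair) {
  stopifnot(inherits(result, "registration_result"),
            length(frame_pair) == 2)
  N <- n_frames(result$registered)
  if (any(frame_pair < 1 | frame_pair > N))
    stop("frame index out of range")
  tpl <- template_matrix(result$final_template)
  vapply(frame_pair,
         function(n) ssim(result$registered$frames[, , n], tpl),
         numeric(1))
}

#' Paired one-sided tests
#'
#' Paired unilateral t-test (alternative: `a` greater than `b`) and the
#' one-sided sign test (binomial on the sign of the paired differences,
#' ties dropped), the latter robust to non-normality. With all differences
#' tied at zero the t statistic is 0 (p = 0.5) and the sign test is
#' undefined (p = 1 with a warning).
#'
#' @param sample_a,sample_b paired numeric vectors of equal length >= 2.
#' @return list with `t_p_value` and `sign_p_value`.
#' @export
paired_tests <- function(sample_a, sample_b) {
  if (length(sample_a) != length(sample_b) || length(sample_a) < 2)
    stop("samples must be paired and of length >= 2")
  d <- sample_a - sample_b
  t_p <- if (stats::sd(d) == 0) {
    if (mean(d) == 0) 0.5 else if (mean(d) > 0) 0 else 1
  } else {
    stats::t.test(sample_a, sample_b, paired = TRUE,
                  alternative = "greater")$p.value
  }
  npos <- sum(d > 0); nneg <- sum(d < 0)
  sign_p <- if (npos + nneg == 0) {
    warning("all paired differences are ties: sign test undefined")
    1.0
  } else {
    n <- npos + nneg
    if (n <= 60) sum(choose(n, npos:n)) / 2^n   # exact dyadic tail sum
    else stats::pbinom(npos - 1, n, 0.5, lower.tail = FALSE)
  }
  list(t_p_value = t_p, sign_p_value = sign_p)
}

#' Greedy forward selection of regularization weights
#'
#' Stage 0 trains with all weights zero and collects a baseline SSIM sample
#' on validation data. Each subsequent stage tries, for every still-inactive
#' parameter and each of its candidate values (the already-selected
#' parameters held fixed), one training run; the best value per parameter is
#' the one with the highest median paired SSIM difference against the
#' current selection's sample, and the stage's winner is the parameter with
#' the highest such median among those whose paired one-sided t-test is
#' significant. The procedure stops when no addition yields a significant
#' positive difference.
#'
#' @param train_fn function taking a named list/vector of weights (names
#'   from `grid`, absent = 0) and returning a numeric SSIM sample; samples
#'   from different calls must be paired (same validation items in the same
#'   order).
#' @param grid named list of candidate value vectors, e.g.
#'   `list(lambda1 = c(1e-7, 5e-7), ..., lambda_c = c(1e-7, 1e-5))`.
#' @param alpha significance threshold for the paired t-test (default 0.05).
#' @return list with `selected` (named numeric vector, empty if nothing
#'   helped), `stages` (data.frame of every trained cell: stage, parameter,
#'   value, median paired difference, p-values, kept flag) and `n_trained`
#'   (total training runs including Stage 0).
#' @export
forward_select <- function(train_fn, grid, alpha = 0.05) {
  if (!length(grid) || is.null(names(grid)) || any(names(grid) == ""))
    stop("`grid` must be a non-empty named list of candidate values")
  selected <- numeric(0)
  baseline <- train_fn(as.list(selected))
  n_trained <- 1L
  ref_sample <- baseline
  remaining <- names(grid)
  stages <- list()
  stage <- 0L
  while (length(remaining)) {
    stage <- stage + 1L
    best <- list(param = NA_character_, value = NA_real_,
                 median = -Inf, t_p = NA_real_, sample = NULL)
    for (p in remaining) {
      p_best <- list(value = NA_real_, median = -Inf, t_p = NA_real_,
                     sign_p = NA_real_, sample = NULL)
      for (v in grid[[p]]) {
        cand <- c(as.list(selected), stats::setNames(list(v), p))
        smp <- tryCatch(train_fn(cand), error = function(e) {
          warning(sprintf("training failed for %s = %g: %s; cell skipped",
                          p, v, conditionMessage(e)))
          NULL
        })
        n_trained <- n_trained + 1L
        if (is.null(smp)) next
        md <- stats::median(smp - ref_sample)
        pt <- paired_tests(smp, ref_sample)
        stages[[length(stages) + 1L]] <- data.frame(
          stage = stage, parameter = p, value = v, median_diff = md,
          t_p_value = pt$t_p_value, sign_p_value = pt$sign_p_value,
          kept = FALSE)
        if (md > p_best$median)
          p_best <- list(value = v, median = md, t_p = pt$t_p_value,
                         sign_p = pt$sign_p_value, sample = smp)
      }
      if (!is.null(p_best$sample) && p_best$t_p < alpha &&
          p_best$median > best$median)
        best <- list(param = p, value = p_best$value,
                     median = p_best$median, t_p = p_best$t_p,
                     sample = p_best$sample)
    }
    if (is.na(best$param)) break
    selected[best$param] <- best$value
    ref_sample <- best$sample
    remaining <- setdiff(remaining, best$param)
    keep <- vapply(stages, function(s)
      s$stage == stage & s$parameter == best$param &
        s$value == best$value, logical(1))
    stages[keep] <- lapply(stages[keep],
                           function(s) { s$kept <- TRUE; s })
  }
  list(selected = selected, stages = do.call(rbind, stages),
       n_trained = n_trained)
}

#' Pseudocolor overlay of two images
#'
#' Composite highlighting differences: pixels where `a` exceeds `b` tend to
#' pink, pixels where `b` exceeds `a` to green, and agreeing pixels stay
#' gray. Optionally draws the overlay on the current device.
#'
#' @param a,b numeric matrices of equal shape (intensities in `[0, 1]`).
#' @param plot draw the overlay (default `TRUE`).
#' @return the `H x W x 3` RGB array, invisibly.
#' @export
plot_overlay <- function(a, b, plot = TRUE) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  cl <- function(x) pmin(pmax(x, 0), 1)
  rgb_arr <- array(c(cl(a), cl(b), cl(a)), c(dim(a), 3))
  if (plot) {
    op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
    graphics::plot.new()
    graphics::rasterImage(grDevices::as.raster(rgb_arr), 0, 0, 1, 1)
  }
  invisible(rgb_arr)
}
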