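#' Registration network configuration
#'
#' Architecture of the convolutional registration network: a reduced
#' encoder-decoder ("U-net"-like) with skip connections. The input has two
#' channels (the frame to register and the current template, stacked); the
#' output has two channels (the per-pixel displacement components). Channel
#' counts are deliberately small so that training fits commodity hardware;
#' the defaults keep the parameter count in the tens of thousands.
#'
#' @param depth number of resolution levels (>= 2); the image side must be
#'   divisible by `2^(depth - 1)`.
#' @param base_filters channels at the first level; levels double up to the
#'   default cap unless `filters_per_level` is given.
#' @param filters_per_level optional integer vector of length `depth`
#'   overriding the doubling rule.
#' @param activation currently `"leaky_relu"` (slope 0.2).
#' @param use_skip_connections concatenate encoder feature maps into the
#'   decoder (default `TRUE`).
#' @param seed integer seed for weight initialization.
#' @return an object of class `net_config`.
#' @export
net_config <- function(depth = 3, base_filters = 8, filters_per_level = NULL,
                       activation = "leaky_relu",
                       use_skip_connections = TRUE, seed = 1) {
  activation <- match.arg(activation, "leaky_relu")
  if (depth < 2) stop("`depth` must be >= 2")
  if (is.null(filters_per_level))
    filters_per_level <- base_filters * 2^(seq_len(depth) - 1)
  filters_per_level <- as.integer(filters_per_level)
  if (length(filters_per_level) != depth || any(filters_per_level < 1))
    stop("`filters_per_level` must be ", depth, " counts >= 1")
  structure(list(depth = as.integer(depth),
                 filters = filters_per_level, activation = activation,
                 use_skip_connections = isTRUE(use_skip_connections),
                 seed = as.integer(seed)),
            class = "net_config")
}

# ---- primitive layers (arrays are H x W x N x C; N = batch of frames) -----
# 3x3 same convolutions run in compiled code (src/conv.cpp, batched
# im2col + GEMM); W is (9*Cin) x Cout with im2col columns ordered
# offset-major, b length Cout

conv3_fwd <- function(x, W, b) .conv3_fwd_cpp(x, W, b)

conv3_bwd <- function(x, W, dout) {
  r <- .conv3_bwd_cpp(x, W, dout)
  r$db <- as.numeric(r$db)
  r
}

conv1_fwd <- function(x, W, b) .conv1_fwd_cpp(x, W, b)

conv1_bwd <- function(x, W, dout) {
  r <- .conv1_bwd_cpp(x, W, dout)
  r$db <- as.numeric(r$db)
  r
}

lrelu_fwd <- function(x, slope = 0.2) .lrelu_fwd_cpp(x, slope)

lrelu_bwd <- function(dout, fac) dout * fac

# 2x2 max pooling; ties resolved to the first maximal element in
# (top-left, bottom-left, top-right, bottom-right) scan order
pool2_fwd <- function(x) .pool2_fwd_cpp(x)

pool2_bwd <- function(dout, which) .pool2_bwd_cpp(dout, which)

upsample2_fwd <- function(x) .upsample2_fwd_cpp(x)

upsample2_bwd <- function(dout) .upsample2_bwd_cpp(dout)

# ---- network construction -------------------------------------------------

he_init <- function(n_in, n_out) {
  matrix(rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

#' Build a registration network
#'
#' Allocates and seeds the weights. The encoder at level i applies two 3x3
#' convolutions (LeakyReLU) and halves the resolution; the decoder ascends
#' with nearest-neighbour upsampling, concatenation of the encoder feature
#' maps (skip connections, when enabled), a 1x1 channel-fusion convolution
#' and one 3x3 convolution per level. A final 1x1 convolution maps to the
#' two displacement components; its weights are initialized near zero so the
#' untrained network outputs displacements close to the identity transform.
#'
#' @param cfg a [net_config()].
#' @return an object of class `gw_network` with elements `cfg` and `par`
#'   (flat named list of weight matrices / bias vectors).
#' @export
build_network <- function(cfg) {
  stopifnot(inherits(cfg, "net_config"))
  f <- cfg$filters; D <- cfg$depth
  par <- list()
  with_seed(cfg$seed, {
    in_ch <- 2L
    for (i in seq_len(D)) {
      par[[paste0("enc", i, ".W1")]] <- he_init(9L * in_ch, f[i])
      par[[paste0("enc", i, ".b1")]] <- numeric(f[i])
      par[[paste0("enc", i, ".W2")]] <- he_init(9L * f[i], f[i])
      par[[paste0("enc", i, ".b2")]] <- numeric(f[i])
      in_ch <- f[i]
    }
    for (i in rev(seq_len(D - 1))) {
      in_ch <- f[i + 1] + if (cfg$use_skip_connections) f[i] else 0L
      par[[paste0("dec", i, ".Wf")]] <- he_init(in_ch, f[i])
      par[[paste0("dec", i, ".bf")]] <- numeric(f[i])
      par[[paste0("dec", i, ".W1")]] <- he_init(9L * f[i], f[i])
      par[[paste0("dec", i, ".b1")]] <- numeric(f[i])
    }
    par[["final.W"]] <- matrix(rnorm(f[1] * 2L, sd = 1e-5), f[1], 2L)
    par[["final.b"]] <- numeric(2L)
  })
  structure(list(cfg = cfg, par = par), class = "gw_network")
}

#' @export
print.gw_network <- function(x, ...) {
  np <- sum(vapply(x$par, length, numeric(1)))
  cat(sprintf("<gw_network> depth %d, filters (%s), %d parameters\n",
              x$cfg$depth, paste(x$cfg$filters, collapse = ", "), np))
  invisible(x)
}

#' Parameter count of a network
#' @param net a `gw_network`.
#' @return integer total number of trainable scalars.
#' @export
n_parameters <- function(net) {
  sum(vapply(net$par, length, numeric(1)))
}

check_net_size <- function(cfg, h, w) {
  div <- 2^(cfg$depth - 1)
  if (h %% div != 0 || w %% div != 0)
    stop(sprintf(paste0(
      "image size %dx%d is not divisible by 2^(depth-1) = %d; ",
      "pad to %dx%d or reduce depth"), h, w, div,
      ceiling(h / div) * div, ceiling(w / div) * div))
}

# encoder block: two 3x3 convolutions, LeakyReLU after each; caches layer
# inputs and activation factors for the backward pass
enc_block_fwd <- function(x, p, pre, want_cache) {
  c1 <- conv3_fwd(x, p[[paste0(pre, ".W1")]], p[[paste0(pre, ".b1")]])
  a1 <- lrelu_fwd(c1)
  c2 <- conv3_fwd(a1$y, p[[paste0(pre, ".W2")]], p[[paste0(pre, ".b2")]])
  a2 <- lrelu_fwd(c2)
  cache <- if (want_cache)
    list(x1 = x, f1 = a1$fac, x2 = a1$y, f2 = a2$fac)
  list(y = a2$y, cache = cache)
}

enc_block_bwd <- function(dout, p, pre, cc, g) {
  d2 <- lrelu_bwd(dout, cc$f2)
  b2 <- conv3_bwd(cc$x2, p[[paste0(pre, ".W2")]], d2)
  g[[paste0(pre, ".W2")]] <- b2$dW
  g[[paste0(pre, ".b2")]] <- b2$db
  d1 <- lrelu_bwd(b2$dx, cc$f1)
  b1 <- conv3_bwd(cc$x1, p[[paste0(pre, ".W1")]], d1)
  g[[paste0(pre, ".W1")]] <- b1$dW
  g[[paste0(pre, ".b1")]] <- b1$db
  list(dx = b1$dx, g = g)
}

# decoder block: 1x1 channel-fusion convolution of the (upsampled + skip)
# stack followed by one 3x3 convolution, LeakyReLU after each — a reduced
# decoder that keeps full-resolution compute proportional to the level's
# own channel count rather than the concatenation's
dec_block_fwd <- function(x, p, pre, want_cache) {
  cf <- conv1_fwd(x, p[[paste0(pre, ".Wf")]], p[[paste0(pre, ".bf")]])
  af <- lrelu_fwd(cf)
  c1 <- conv3_fwd(af$y, p[[paste0(pre, ".W1")]], p[[paste0(pre, ".b1")]])
  a1 <- lrelu_fwd(c1)
  cache <- if (want_cache)
    list(xf = x, ff = af$fac, x1 = af$y, f1 = a1$fac)
  list(y = a1$y, cache = cache)
}

dec_block_bwd <- function(dout, p, pre, cc, g) {
  d1 <- lrelu_bwd(dout, cc$f1)
  b1 <- conv3_bwd(cc$x1, p[[paste0(pre, ".W1")]], d1)
  g[[paste0(pre, ".W1")]] <- b1$dW
  g[[paste0(pre, ".b1")]] <- b1$db
  df <- lrelu_bwd(b1$dx, cc$ff)
  bf <- conv1_bwd(cc$xf, p[[paste0(pre, ".Wf")]], df)
  g[[paste0(pre, ".Wf")]] <- bf$dW
  g[[paste0(pre, ".bf")]] <- bf$db
  list(dx = bf$dx, g = g)
}

# forward pass for a batch of frames against one template; `frames` is
# H x W x N (or a single H x W matrix); returns fields as H x W x N x 2 and
# (optionally) the cache needed for backprop
net_forward <- function(net, frames, template, want_cache = FALSE) {
  cfg <- net$cfg; p <- net$par; D <- cfg$depth
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  d <- dim(frames)
  h <- d[1]; w <- d[2]; N <- d[3]
  check_net_size(cfg, h, w)
  x <- array(c(frames, rep(template, N)), c(h, w, N, 2L))
  cache <- if (want_cache) list(enc = vector("list", D),
                                dec = vector("list", D - 1)) else NULL
  enc_out <- vector("list", D)
  for (i in seq_len(D)) {
    bl <- enc_block_fwd(x, p, paste0("enc", i), want_cache)
    enc_out[[i]] <- bl$y
    pl <- NULL
    if (i < D) {
      pl <- pool2_fwd(bl$y)
      x <- pl$y
    }
    if (want_cache) cache$enc[[i]] <- c(bl$cache, list(pool = pl))
  }
  x <- enc_out[[D]]
  for (i in rev(seq_len(D - 1))) {
    up <- upsample2_fwd(x)
    xin <- if (cfg$use_skip_connections) {
      du <- dim(up)
      array(c(up, enc_out[[i]]),
            c(du[1:3], du[4] + dim(enc_out[[i]])[4]))
    } else up
    bl <- dec_block_fwd(xin, p, paste0("dec", i), want_cache)
    if (want_cache)
      cache$dec[[i]] <- c(bl$cache, list(up_ch = dim(up)[4]))
    x <- bl$y
  }
  if (want_cache) cache$pre_final <- x
  field <- conv1_fwd(x, p[["final.W"]], p[["final.b"]])
  list(field = field, cache = cache)
}

# backward pass; dfield is H x W x N x 2. Returns flat named gradient list
# (gradients are accumulated over the batch by the convolution GEMMs).
net_backward <- function(net, cache, dfield) {
  cfg <- net$cfg; p <- net$par; D <- cfg$depth
  g <- list()
  fb <- conv1_bwd(cache$pre_final, p[["final.W"]], dfield)
  g[["final.W"]] <- fb$dW; g[["final.b"]] <- fb$db
  dx <- fb$dx
  denc <- vector("list", D)  # gradients flowing into encoder outputs
  for (i in seq_len(D - 1)) {
    cc <- cache$dec[[i]]
    bb <- dec_block_bwd(dx, p, paste0("dec", i), cc, g)
    g <- bb$g
    dxin <- bb$dx
    nu <- cc$up_ch
    if (cfg$use_skip_connections) {
      denc[[i]] <- dxin[, , , (nu + 1):dim(dxin)[4], drop = FALSE]
      dxin <- dxin[, , , seq_len(nu), drop = FALSE]
    }
    dx <- upsample2_bwd(dxin)
  }
  # dx now flows into the bottleneck encoder output
  for (i in rev(seq_len(D))) {
    cc <- cache$enc[[i]]
    dy <- if (i == D) dx else {
      down <- pool2_bwd(dx, cc$pool$which)
      if (!is.null(denc[[i]])) down + denc[[i]] else down
    }
    bb <- enc_block_bwd(dy, p, paste0("enc", i), cc, g)
    g <- bb$g
    dx <- bb$dx
  }
  g
}

#' Predict deformation fields for a whole sequence
#'
#' Runs the network frame by frame with a fixed template, returning one
#' displacement field per frame. Inference is deterministic given fixed
#' weights.
#'
#' @param net a `gw_network` from [build_network()].
#' @param seq a [cine_sequence()].
#' @param template a [template_image()] or plain `H x W` matrix.
#' @return a [deformation_sequence()].
#' @export
predict_fields <- function(net, seq, template) {
  stopifnot(inherits(net, "gw_network"), inherits(seq, "cine_sequence"))
  tpl <- template_matrix(template)
  d <- dim(seq$frames)
  if (!all(dim(tpl) == d[1:2]))
    stop("template shape does not match sequence frames")
  fw <- net_forward(net, seq$frames, tpl)
  deformation_sequence(aperm(fw$field, c(1L, 2L, 4L, 3L)))
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(par) {
  list(t = 0L,
       m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0))
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a network checkpoint
#'
#' A checkpoint is a single RDS file embedding the weights, the
#' [net_config()] and a format version string.
#'
#' @param net a `gw_network`.
#' @param path destination `.rds` path.
#' @return `path` invisibly (`save_checkpoint`); a `gw_network`
#'   (`load_checkpoint`).
#' @export
save_checkpoint <- function(net, path) {
  stopifnot(inherits(net, "gw_network"))
  saveRDS(list(version = "gwcine-checkpoint-1", cfg = net$cfg,
               par = net$par), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$version, "gwcine-checkpoint-1"))
    stop("not a gwcine checkpoint: ", path)
  structure(list(cfg = obj$cfg, par = obj$par), class = "gw_network")
}
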