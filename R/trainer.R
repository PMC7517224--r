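#' Groupwise training / registration configuration
#'
#' @param L number of template updates (default 5), giving `L + 1` passes of
#'   the sequence through the network per epoch and per prediction.
#' @param epochs training epochs (default 10).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param loss a [loss_config()].
#' @param net a [net_config()].
#' @param template a [template_config()] for the initial (l = 0) template
#'   selection.
#' @param shuffle_sequences visit training sequences in a seeded random
#'   order each epoch (default `TRUE`).
#' @param seed integer seed controlling shuffling (weight initialization is
#'   seeded by `net$seed`).
#' @return an object of class `gw_config`.
#' @export
gw_config <- function(L = 5, epochs = 10, learning_rate = 1e-4,
                      loss = loss_config(), net = net_config(),
                      template = template_config(),
                      shuffle_sequences = TRUE, seed = 1) {
  if (L < 0) stop("`L` must be >= 0")
  if (epochs < 1) stop("`epochs` must be >= 1")
  if (learning_rate <= 0) stop("`learning_rate` must be > 0")
  stopifnot(inherits(loss, "loss_config"), inherits(net, "net_config"),
            inherits(template, "template_select_config"))
  structure(list(L = as.integer(L), epochs = as.integer(epochs),
                 learning_rate = learning_rate, loss = loss, net = net,
                 template = template,
                 shuffle_sequences = isTRUE(shuffle_sequences),
                 seed = as.integer(seed)),
            class = "gw_config")
}

as_dataset <- function(dataset) {
  if (inherits(dataset, "cine_sequence")) return(list(dataset))
  if (is.list(dataset) && length(dataset) &&
      all(vapply(dataset, inherits, logical(1), "cine_sequence")))
    return(dataset)
  stop("`dataset` must be a cine_sequence or a list of them")
}

# forward all frames (one batch) with caches, evaluate the loss and
# backpropagate; batch = the N frames of the sequence, so one call yields
# the full parameter gradient of the iteration
gw_step <- function(net, seq, template, cfg) {
  tpl <- template_matrix(template)
  fw <- net_forward(net, seq$frames, tpl, want_cache = TRUE)
  if (!all(is.finite(fw$field)))
    stop(sprintf("non-finite network output for subject '%s'",
                 seq$subject_id))
  fields <- deformation_sequence(aperm(fw$field, c(1L, 2L, 4L, 3L)))
  lg <- total_loss_grad_fields(seq, template, fields, cfg$loss)
  if (!is.finite(lg$value))
    stop(sprintf("non-finite loss (%g) for subject '%s'", lg$value,
                 seq$subject_id))
  grads <- net_backward(net, fw$cache, aperm(lg$grad, c(1L, 2L, 4L, 3L)))
  list(loss = lg$value, similarity = lg$similarity,
       regularization = lg$regularization, constraint = lg$constraint,
       grads = grads, fields = fields, registered = lg$registered)
}

#' Train the groupwise registration network
#'
#' Unsupervised training: each epoch visits the sequences in a seeded random
#' order; for each sequence the initial template is the geodesic-medoid
#' frame, then for `l = 0..L` all N frames are passed through the network
#' against the current template (batch = the sequence's N frames), the total
#' loss is evaluated, one Adam step is taken, and the template is recomputed
#' as the pointwise average of the just-registered frames. The template is
#' treated as a constant: no gradient flows through its history.
#'
#' @param dataset list of [cine_sequence()] objects (a single sequence is
#'   accepted).
#' @param cfg a [gw_config()].
#' @param validation optional list of sequences; per-epoch mean validation
#'   loss (no parameter updates) is recorded in the log.
#' @param verbose print per-epoch progress.
#' @return list with `network` (trained `gw_network`), `log` (data.frame of
#'   per-sequence, per-iteration records) and `epoch_log` (per-epoch means).
#' @export
train_gw <- function(dataset, cfg = gw_config(), validation = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(cfg, "gw_config"))
  dataset <- as_dataset(dataset)
  net <- build_network(cfg$net)
  state <- adam_init(net$par)
  log <- list()
  epoch_log <- list()
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- if (cfg$shuffle_sequences) sample.int(length(dataset))
             else seq_along(dataset)
      ep_losses <- numeric(0)
      for (si in ord) {
        seq <- dataset[[si]]
        template <- select_template(seq, cfg$template)$template
        for (l in 0:cfg$L) {
          st <- gw_step(net, seq, template, cfg)
          upd <- adam_step(net$par, st$grads, state, cfg$learning_rate)
          net$par <- upd$par; state <- upd$state
          template <- update_template(st$registered, iteration = l + 1L)
          log[[length(log) + 1L]] <- data.frame(
            epoch = ep, sequence = si, l = l, loss = st$loss,
            similarity = st$similarity,
            regularization = st$regularization,
            constraint = st$constraint)
          ep_losses <- c(ep_losses, st$loss)
        }
      }
      val_loss <- NA_real_
      if (!is.null(validation)) {
        vl <- vapply(as_dataset(validation), function(vs) {
          res <- register_gw(net, vs, cfg)
          utils::tail(res$loss_trace, 1)
        }, numeric(1))
        val_loss <- mean(vl)
      }
      epoch_log[[ep]] <- data.frame(epoch = ep,
                                    train_loss = mean(ep_losses),
                                    val_loss = val_loss)
      if (verbose)
        message(sprintf("epoch %d/%d  mean loss %.5g%s", ep, cfg$epochs,
                        mean(ep_losses),
                        if (is.na(val_loss)) ""
                        else sprintf("  val %.5g", val_loss)))
    }
  })
  list(network = net, log = do.call(rbind, log),
       epoch_log = do.call(rbind, epoch_log))
}

#' Register a sequence with a trained network
#'
#' Prediction mode: the same `L + 1`-iteration loop as training (template
#' selection at l = 0, pointwise-average updates thereafter) but with no
#' parameter updates. Records the template and the groupwise SSD of the
#' registered sequence at every iteration.
#'
#' @param net a trained `gw_network`.
#' @param seq a preprocessed [cine_sequence()].
#' @param cfg a [gw_config()] (its `L`, `loss$region` and `template` fields
#'   are used).
#' @return an object of class `registration_result`: `registered` (final
#'   registered sequence), `fields` (final [deformation_sequence()]),
#'   `templates` (list of length L + 1), `ssd_trace` (groupwise SSD per
#'   iteration), `loss_trace` (total loss per iteration).
#' @export
register_gw <- function(net, seq, cfg = gw_config()) {
  stopifnot(inherits(net, "gw_network"), inherits(seq, "cine_sequence"),
            inherits(cfg, "gw_config"))
  template <- select_template(seq, cfg$template)$template
  templates <- vector("list", cfg$L + 1L)
  ssd_trace <- numeric(cfg$L + 1L)
  loss_trace <- numeric(cfg$L + 1L)
  fields <- NULL; registered <- NULL
  for (l in 0:cfg$L) {
    templates[[l + 1L]] <- template
    fields <- predict_fields(net, seq, template)
    lt <- total_loss(seq, template, fields, cfg$loss)
    registered <- lt$registered
    ssd_trace[l + 1L] <- ssd_loss(registered, cfg$loss$region)
    loss_trace[l + 1L] <- lt$value
    if (l < cfg$L)
      template <- update_template(registered, iteration = l + 1L)
  }
  structure(list(registered = registered, fields = fields,
                 templates = templates, ssd_trace = ssd_trace,
                 loss_trace = loss_trace,
                 final_template = utils::tail(templates, 1)[[1]]),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf(
    "<registration_result> %d frames, %d iterations, SSD %.4g -> %.4g\n",
    n_frames(x$registered), length(x$ssd_trace), x$ssd_trace[1],
    utils::tail(x$ssd_trace, 1)))
  invisible(x)
}

#' Cyclically roll a sequence
#'
#' Reorders the frames to start at `start`, following the periodic extension
#' of the cycle (frame N is followed by frame 1). Rolling by 0 or by N
#' returns an identical sequence.
#'
#' @param seq a [cine_sequence()].
#' @param start 1-based index of the frame that becomes first, or a
#'   0..N shift via `roll_sequence(seq, start = shift + 1)`.
#' @return reordered [cine_sequence()].
#' @export
roll_sequence <- function(seq, start) {
  stopifnot(inherits(seq, "cine_sequence"))
  N <- n_frames(seq)
  start <- ((as.integer(start) - 1L) %% N) + 1L
  permute_sequence(seq, ((seq_len(N) + start - 2L) %% N) + 1L)
}

#' Permute the frames of a sequence
#'
#' @param seq a [cine_sequence()].
#' @param permutation a permutation of `1:N`.
#' @return reordered [cine_sequence()].
#' @export
permute_sequence <- function(seq, permutation) {
  stopifnot(inherits(seq, "cine_sequence"))
  N <- n_frames(seq)
  permutation <- as.integer(permutation)
  if (length(permutation) != N || !setequal(permutation, seq_len(N)))
    stop("`permutation` must be a permutation of 1:", N)
  seq$frames <- seq$frames[, , permutation, drop = FALSE]
  seq
}
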