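#' Template image
#'
#' The common reference image of the groupwise problem, together with its
#' provenance: either a selected frame (initial iteration) or the pointwise
#' average of registered frames at a given iteration.
#'
#' @param image `H x W` numeric matrix.
#' @param origin `"selected_frame"` or `"average"`.
#' @param index selected frame index (when `origin = "selected_frame"`).
#' @param iteration template-update iteration l (when `origin = "average"`).
#' @return an object of class `template_image`.
#' @export
template_image <- function(image, origin = c("selected_frame", "average"),
                           index = NA_integer_, iteration = NA_integer_) {
  origin <- match.arg(origin)
  if (!is.matrix(image) || !is.numeric(image))
    stop("`image` must be a numeric matrix")
  structure(list(image = image, origin = origin,
                 index = as.integer(index),
                 iteration = as.integer(iteration)),
            class = "template_image")
}

#' @export
print.template_image <- function(x, ...) {
  prov <- if (x$origin == "selected_frame")
    sprintf("selected frame %d", x$index)
  else sprintf("average at iteration %d", x$iteration)
  cat(sprintf("<template_image> %d x %d px, %s\n",
              nrow(x$image), ncol(x$image), prov))
  invisible(x)
}

template_matrix <- function(template) {
  if (inherits(template, "template_image")) template$image
  else if (is.matrix(template)) template
  else stop("`template` must be a template_image or a matrix")
}

#' Template-selection configuration
#'
#' @param k neighbour count of the kNN graph (>= 1); automatically increased
#'   when the graph is disconnected.
#' @param rc_alpha scale parameter of the residual-complexity similarity
#'   (> 0).
#' @param similarity `"residual_complexity"` or `"ssd"` frame dissimilarity.
#' @return an object of class `template_select_config`.
#' @export
template_config <- function(k = 4, rc_alpha = 0.05,
                            similarity = c("residual_complexity", "ssd")) {
  similarity <- match.arg(similarity)
  if (k < 1) stop("`k` must be >= 1")
  if (rc_alpha <= 0) stop("`rc_alpha` must be > 0")
  structure(list(k = as.integer(k), rc_alpha = rc_alpha,
                 similarity = similarity),
            class = "template_select_config")
}

# orthonormal DCT-II matrix, cached per size
dct_matrix <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- seq_len(n) - 1
    i <- seq_len(n) - 1
    D <- sqrt(2 / n) * cos(pi * outer(k, 2 * i + 1) / (2 * n))
    D[1, ] <- sqrt(1 / n)
    cache[[key]] <- D
    D
  }
})

#' Residual complexity between two images
#'
#' Dissimilarity defined on the residual `a - b`: with `c` the orthonormal
#' 2D DCT-II coefficients of the residual, the value is
#' `sum(log(1 + c^2 / alpha))`. It measures how much structured content the
#' residual carries (a residual needing many large DCT coefficients is
#' "complex"); it is symmetric and zero iff the images are identical.
#'
#' @param a,b numeric matrices of equal shape.
#' @param alpha positive scale parameter (default 0.05).
#' @return scalar (>= 0).
#' @export
residual_complexity <- function(a, b, alpha = 0.05) {
  if (!all(dim(a) == dim(b))) stop("image shapes differ")
  if (alpha <= 0) stop("`alpha` must be > 0")
  r <- a - b
  cf <- dct_matrix(nrow(r)) %*% r %*% t(dct_matrix(ncol(r)))
  sum(log1p(cf^2 / alpha))
}

frame_dissimilarity <- function(seq, cfg) {
  fr <- seq$frames
  N <- dim(fr)[3]
  d <- matrix(0, N, N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    d[i, j] <- d[j, i] <- if (cfg$similarity == "residual_complexity")
      residual_complexity(fr[, , i], fr[, , j], cfg$rc_alpha)
    else sum((fr[, , i] - fr[, , j])^2)
  }
  d
}

knn_edges <- function(d, k) {
  N <- nrow(d)
  edges <- NULL
  for (i in seq_len(N)) {
    others <- setdiff(seq_len(N), i)
    # ties in dissimilarity broken by lower frame index
    ord <- others[order(d[i, others], others)]
    nb <- ord[seq_len(min(k, length(ord)))]
    edges <- rbind(edges, cbind(i, nb))
  }
  und <- t(apply(edges, 1, sort))
  und <- unique(und)
  list(edges = und, weights = d[und])
}

#' Build the kNN frame graph
#'
#' Undirected graph over the frames of a sequence: each frame is connected
#' to its k most similar frames (smallest dissimilarity, ties broken by
#' lower index), edges weighted by the dissimilarity. If the union graph is
#' disconnected, k is increased until it is connected.
#'
#' @param seq a [cine_sequence()] with N >= 2 frames.
#' @param cfg a [template_config()].
#' @return an [igraph::graph] with edge attribute `weight` and graph
#'   attributes `k` (the k actually used) and `dissimilarity` (the full
#'   matrix).
#' @export
build_knn_graph <- function(seq, cfg = template_config()) {
  stopifnot(inherits(seq, "cine_sequence"))
  N <- n_frames(seq)
  if (N < 2) stop("need at least 2 frames")
  d <- frame_dissimilarity(seq, cfg)
  k <- min(cfg$k, N - 1)
  repeat {
    ed <- knn_edges(d, k)
    g <- igraph::graph_from_edgelist(ed$edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0, N - igraph::vcount(g)))
    igraph::E(g)$weight <- ed$weights
    if (igraph::is_connected(g) || k >= N - 1) break
    k <- k + 1L
  }
  g <- igraph::set_graph_attr(g, "k", k)
  igraph::set_graph_attr(g, "dissimilarity", d)
}

#' Select the initial template frame
#'
#' Geodesic-medoid selection: on the kNN frame graph, compute single-source
#' shortest-path (geodesic) distances between all frames and return the
#' frame whose summed geodesic distance to all other frames is minimal
#' (ties broken by lower index). Used at iteration l = 0, before any
#' registration output exists.
#'
#' @param seq a [cine_sequence()] with N >= 2 frames.
#' @param cfg a [template_config()].
#' @return list with `template` (a [template_image()]), `index` (selected
#'   frame) and `distance_sums` (per-frame geodesic distance sums).
#' @export
select_template <- function(seq, cfg = template_config()) {
  g <- build_knn_graph(seq, cfg)
  dist <- igraph::distances(g, algorithm = "dijkstra")
  sums <- rowSums(dist)
  idx <- which.min(sums)   # ties: lowest index
  list(template = template_image(seq$frames[, , idx],
                                 origin = "selected_frame", index = idx),
       index = idx, distance_sums = sums)
}

#' Update the template by pointwise averaging
#'
#' The per-pixel arithmetic mean of the registered frames, which is the
#' template minimizing the groupwise SSD criterion for fixed
#' transformations.
#'
#' @param registered a registered [cine_sequence()].
#' @param iteration iteration number recorded as provenance.
#' @return a [template_image()].
#' @export
update_template <- function(registered, iteration = NA_integer_) {
  stopifnot(inherits(registered, "cine_sequence"))
  template_image(rowMeans(registered$frames, dims = 2),
                 origin = "average", iteration = iteration)
}
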