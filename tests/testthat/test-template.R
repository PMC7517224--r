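test_that("residual complexity is zero at equality and symmetric", {
  set.seed(1)
  a <- smooth_image(16); b <- smooth_image(16)
  expect_equal(residual_complexity(a, a), 0)
  expect_equal(residual_complexity(a, b), residual_complexity(b, a))
  expect_gt(residual_complexity(a, b), 0)
  expect_error(residual_complexity(a, matrix(0, 8, 8)), "differ")
  expect_error(residual_complexity(a, b, alpha = 0), "alpha")
})

test_that("residual complexity matches the closed form on one DCT atom", {
  # construct a residual that is exactly v times one orthonormal DCT basis
  # image: the value must be log(1 + v^2 / alpha)
  n <- 8
  D <- gwcine:::dct_matrix(n)
  for (v in c(0.5, 2)) for (k in list(c(1, 1), c(3, 5))) {
    atom <- outer(D[k[1], ], D[k[2], ])   # inverse DCT of a unit coefficient
    a <- v * atom
    b <- matrix(0, n, n)
    expect_equal(residual_complexity(a, b, alpha = 0.05),
                 log(1 + v^2 / 0.05), tolerance = 1e-10)
  }
})

test_that("kNN graph connects frames with tie-breaks and auto-raised k", {
  set.seed(2)
  fr <- array(runif(12 * 12 * 5), c(12, 12, 5))
  seq <- cine_sequence(fr)
  g <- build_knn_graph(seq, template_config(k = 1))
  expect_true(igraph::is_connected(g))
  # k >= N-1 gives the complete graph
  g_full <- build_knn_graph(seq, template_config(k = 10))
  expect_equal(igraph::ecount(g_full), choose(5, 2))
  # identical frames: selection falls back to the index tie-break
  same <- cine_sequence(array(rep(fr[, , 1], 4), c(12, 12, 4)))
  expect_equal(select_template(same)$index, 1L)
})

test_that("geodesic distances satisfy metric basics", {
  set.seed(3)
  seq <- cine_sequence(array(runif(10 * 10 * 6), c(10, 10, 6)))
  g <- build_knn_graph(seq, template_config(k = 2))
  dmat <- igraph::distances(g)
  expect_true(all(diag(dmat) == 0))
  for (i in 1:6) for (j in 1:6) for (m in 1:6)
    expect_lte(dmat[i, j], dmat[i, m] + dmat[m, j] + 1e-12)
})

test_that("a constructed star-center frame is selected as template", {
  # frame 2 (0-based: index 2) lies close to every other frame; the others
  # are mutually distant, so the kNN graph is a star around it and it has
  # the minimal geodesic distance sum
  set.seed(4)
  n <- 16
  hub <- smooth_image(n)
  frames <- array(0, c(n, n, 4))
  frames[, , 2] <- hub
  for (i in c(1, 3, 4)) {
    bump <- matrix(0, n, n)
    bump[(2 + i):(5 + i), (2 + i):(5 + i)] <- 1.5
    frames[, , i] <- hub + bump
  }
  seq <- cine_sequence(frames)
  sel <- select_template(seq, template_config(k = 1))
  d <- gwcine:::frame_dissimilarity(seq, template_config(k = 1))
  expect_equal(sel$index, fw_medoid(d, 1))
  expect_equal(sel$index, 2L)
})

test_that("select_template equals the Floyd-Warshall medoid on random data", {
  set.seed(5)
  for (case in 1:20) {
    N <- sample(3:8, 1)
    k <- sample(1:3, 1)
    seq <- cine_sequence(array(runif(12 * 12 * N), c(12, 12, N)))
    cfg <- template_config(k = k)
    sel <- select_template(seq, cfg)
    d <- gwcine:::frame_dissimilarity(seq, cfg)
    expect_equal(sel$index, fw_medoid(d, min(k, N - 1)))
  }
})

test_that("template updating is the pointwise mean and SSD-optimal", {
  set.seed(6)
  fr <- array(runif(8 * 8 * 4), c(8, 8, 4))
  reg <- cine_sequence(fr)
  tpl <- update_template(reg, iteration = 2)
  expect_equal(tpl$image, rowMeans(fr, dims = 2))
  expect_equal(tpl$origin, "average")
  # identical frames -> that frame
  same <- cine_sequence(array(rep(fr[, , 1], 3), c(8, 8, 3)))
  expect_equal(update_template(same)$image, fr[, , 1])
  # two constant frames 0 and 1 -> constant 0.5
  two <- cine_sequence(array(rep(c(0, 1), each = 64), c(8, 8, 2)))
  expect_true(all(update_template(two)$image == 0.5))
  # quadratic-minimum property: perturbing the mean increases
  # sum_n sum_x (m_n(x) - f(x))^2
  objective <- function(f) sum(sweep(fr, c(1, 2), f)^2)
  base_val <- objective(tpl$image)
  for (i in 1:10) {
    pert <- tpl$image + matrix(rnorm(64, sd = 0.01), 8, 8)
    expect_gt(objective(pert), base_val)
  }
})

test_that("ssd dissimilarity fallback behaves like a distance", {
  set.seed(7)
  seq <- cine_sequence(array(runif(10 * 10 * 4), c(10, 10, 4)))
  cfg <- template_config(similarity = "ssd")
  d <- gwcine:::frame_dissimilarity(seq, cfg)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  sel <- select_template(seq, cfg)
  expect_equal(sel$index, fw_medoid(d, min(cfg$k, 3)))
})
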