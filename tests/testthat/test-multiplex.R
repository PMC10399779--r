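test_that("similarity layers are Euclidean distances between profiles", {
  p <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), NULL))
  d <- similarity_layer(p)
  expect_equal(d["a", "b"], 5)
  expect_equal(diag(d), c(a = 0, b = 0))
  # permutation equivariance
  p3 <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  d3 <- similarity_layer(p3)
  perm <- c(3, 1, 4, 2)
  expect_equal(similarity_layer(p3[perm, ]), d3[perm, perm])
  expect_equal(dim(similarity_layer(p3[1, , drop = FALSE])), c(0, 0))
})

test_that("upper-quartile thresholding uses interpolated percentiles strictly", {
  w <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  w[upper.tri(w)] <- 1:6
  w <- w + t(w)
  # 75th percentile of 1..6 = 4.75; weights 5 and 6 pass
  e <- upper_quartile_edges(w, kind = "interaction")
  expect_equal(nrow(e), 2)
  # distances: 25th percentile = 2.25; distances 1 and 2 pass
  e2 <- upper_quartile_edges(w, kind = "distance")
  expect_equal(nrow(e2), 2)
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_warning(e3 <- upper_quartile_edges(flat, kind = "interaction"),
                 "degenerate")
  expect_equal(nrow(e3), 0)
})

test_that("multiplex assembly couples like workers across adjacent layers", {
  ids <- sprintf("W%d", 1:6)
  mk <- function(seed) {
    set.seed(seed)
    m <- matrix(runif(36), 6, 6, dimnames = list(ids, ids))
    m <- m + t(m); diag(m) <- 0
    m
  }
  layers <- list(social = mk(1), behavior = mk(2), expression = mk(3),
                 microbiota = mk(4), physical = mk(5))
  mx <- build_multiplex(layers)
  expect_equal(mx$layer_names,
               c("social", "behavior", "expression", "microbiota", "physical"))
  expect_equal(mx$n_interlayer_edges, 4 * 6)
  bad <- layers
  rownames(bad$physical) <- colnames(bad$physical) <- sprintf("X%d", 1:6)
  expect_error(build_multiplex(bad), "physical")
})

test_that("layer reduction recovers known principal axes", {
  # rank-1 data: score recovers the generating axis up to sign convention
  set.seed(6)
  t_true <- rnorm(30)
  prof <- outer(t_true, c(1, 2, -1)) +
    matrix(rnorm(90, sd = 1e-3), 30, 3)
  rownames(prof) <- sprintf("W%d", 1:30)
  score <- reduce_layer(prof, 1, orient = setNames(t_true, rownames(prof)))
  expect_gt(cor(score, t_true), 0.999)

  # 2-D toy: compare against closed-form eigenvectors of the covariance
  set.seed(7)
  xy <- cbind(rnorm(200, sd = 3), rnorm(200))
  rot <- matrix(c(cos(0.5), sin(0.5), -sin(0.5), cos(0.5)), 2, 2)
  xy <- xy %*% rot
  rownames(xy) <- sprintf("W%d", 1:200)
  ev <- eigen(cov(xy))
  proj <- scale(xy, scale = FALSE) %*% ev$vectors[, 1]
  score2 <- reduce_layer(xy, 1)
  expect_equal(abs(cor(score2, proj[, 1])), 1, tolerance = 1e-10)
  expect_error(reduce_layer(xy, 5), "rank|pc_index")
})

test_that("expression component choice separates batch from biology", {
  set.seed(8)
  n <- 80
  batch <- rep(1:4, each = 20)
  bio <- rnorm(n)
  # strong batch direction on component 1, biology on component 2
  scores_dominated <- cbind(scale(batch + rnorm(n, sd = 0.1)) * 10,
                            scale(bio + rnorm(n, sd = 0.2)) * 3,
                            matrix(rnorm(3 * n), n, 3))
  sel <- select_expression_pc(scores_dominated, batch, list(bio = bio))
  expect_equal(sel$recommended, 2L)
  # no batch effect: PC1 is biological
  scores_clean <- cbind(scale(bio + rnorm(n, sd = 0.2)) * 10,
                        matrix(rnorm(4 * n), n, 4))
  sel2 <- select_expression_pc(scores_clean, batch, list(bio = bio))
  expect_equal(sel2$recommended, 1L)
  # single batch: batch R^2 treated as 0
  sel3 <- select_expression_pc(scores_clean, rep(1, n), list(bio = bio))
  expect_equal(sel3$recommended, 1L)
})

test_that("interlayer R-squared network averages colony matrices", {
  s <- tibble::tibble(
    worker_id = sprintf("W%d", 1:8),
    colony_id = rep(c("c1", "c2"), each = 4),
    social = c(1, 2, 3, 4, 1, 2, 3, 4),
    behavior = c(3, 5, 7, 9, 2, 4, 6, 8),     # exact affine function
    expression = c(1, 2, 2, 4, 1, 2, 2, 4),
    microbiota = rnorm(8),
    physical = rnorm(8),
    age = c(4, 3, 2, 1, 4, 3, 2, 1)
  )
  cn <- interlayer_r2_network(s)
  expect_equal(cn$average["social", "behavior"], 1)
  expect_equal(cn$average["social", "age"], 1)  # exact decreasing line
  expect_equal(cn$average, t(cn$average))
  expect_true(all(diag(cn$average) == 1))
  # hand-computed Pearson R^2 for x=1:4 vs y=c(1,2,2,4)
  expect_equal(cn$average["social", "expression"], 0.853, tolerance = 1e-3)
  # affine rescaling leaves the network unchanged
  s2 <- dplyr::mutate(s, behavior = -3 * .data$behavior + 11)
  expect_equal(interlayer_r2_network(s2)$average, cn$average)
  # constant variable collapses to zero with a warning per affected pair
  s3 <- dplyr::mutate(s, microbiota = 1)
  w <- testthat::capture_warnings(cn3 <- interlayer_r2_network(s3))
  expect_true(all(grepl("constant", w)))
  expect_equal(cn3$average["microbiota", "social"], 0)
})

test_that("random-intercept fit collapses to OLS with one group", {
  set.seed(9)
  x <- rnorm(40); y <- 2 * x + rnorm(40)
  fit <- random_intercept_fit(x, y, rep("g1", 40))
  ols <- summary(lm(y ~ x))$coefficients
  expect_equal(fit$slope, ols["x", "Estimate"])
  expect_equal(fit$t, ols["x", "t value"])
  expect_error(random_intercept_fit(rep(1, 40), y, rep("g1", 40)), "variance")
})

test_that("random-intercept fit recovers simulated effects", {
  set.seed(10)
  # no group variance: estimated sigma_group collapses
  x <- rnorm(120); g <- rep(1:4, each = 30)
  y0 <- 1 + 0.5 * x + rnorm(120, sd = 0.5)
  fit0 <- random_intercept_fit(x, y0, g)
  expect_lt(fit0$sigma_group, 0.15)
  # slope recovery over replicates at beta = 0.5, 4 groups x 50
  slopes <- vapply(1:200, function(i) {
    x <- rnorm(200); g <- rep(1:4, each = 50)
    u <- rnorm(4, sd = 0.8)[g]
    y <- 1 + 0.5 * x + u + rnorm(200, sd = 0.7)
    random_intercept_fit(x, y, g)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 0.5), 0.05)
})
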