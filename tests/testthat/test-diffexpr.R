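test_that("gene count filter keeps totals at or above the threshold", {
  counts <- matrix(c(33, 33, 33, 25, 25, 50, 40, 30, 31), 3, 3, byrow = TRUE,
                   dimnames = list(c("g1", "g2", "g3"), c("w1", "w2", "w3")))
  # totals 99, 100, 101: the "<100" rule removes only g1
  kept <- filter_low_count_genes(counts)
  expect_equal(rownames(kept), c("g2", "g3"))
  expect_equal(formals(filter_low_count_genes)$min_total, 100)
  expect_error(filter_low_count_genes(matrix(0L, 3, 3)), "filter")
})

test_that("median-of-ratios size factors normalize depth", {
  set.seed(1)
  base <- matrix(rnbinom(500, mu = 50, size = 5) + 1, 100, 5)
  counts <- cbind(base, base[, 1] * 2)
  colnames(counts) <- sprintf("w%d", 1:6)
  rownames(counts) <- sprintf("g%d", 1:100)
  sf <- size_factors(counts)
  expect_equal(sf[["w6"]] / sf[["w1"]], 2, tolerance = 1e-8)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-10)
  # identical columns give unit factors
  same <- base[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(size_factors(same)), rep(1, 3))
})

test_that("dispersion estimates track the generating law", {
  set.seed(2)
  # Poisson data: dispersion collapses toward the floor
  pois <- matrix(rpois(200 * 100, lambda = rep(exp(rnorm(200, 4)), 100)),
                 200, 100, dimnames = list(sprintf("g%d", 1:200), NULL))
  d_pois <- estimate_dispersions(pois)
  expect_lte(median(d_pois), 0.01)
  # NB with dispersion 0.5 at n = 200
  mu <- exp(rnorm(200, 4))
  nb <- matrix(rnbinom(200 * 200, mu = rep(mu, 200), size = 2), 200, 200,
               dimnames = list(sprintf("g%d", 1:200), NULL))
  d_nb <- estimate_dispersions(nb)
  expect_gt(median(d_nb), 0.3)
  expect_lt(median(d_nb), 0.7)
  # constant counts hit the floor
  flat <- matrix(5L, 10, 10, dimnames = list(sprintf("g%d", 1:10), NULL))
  expect_true(all(estimate_dispersions(flat) <= 1e-6))
})

test_that("BH adjustment matches the closed-form step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  set.seed(3)
  for (i in 1:5) {
    p <- runif(50)^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Wald test flags planted effects and rejects bad inputs", {
  set.seed(4)
  n <- 80; g <- 200
  m <- runif(n)
  mu0 <- rlnorm(g, log(60), 0.8)
  beta <- c(rep(1, 20), rep(0, g - 20))
  counts <- matrix(rnbinom(g * n, mu = mu0 * 2^outer(beta, m), size = 5),
                   g, n, dimnames = list(sprintf("g%03d", 1:g),
                                         sprintf("w%02d", 1:n)))
  res <- nb_wald_test(counts, m)
  expect_s3_class(res, "de_result")
  expect_true(all(res$padj >= res$pvalue))
  expect_true(all(res$significant == (res$padj < 0.05)))
  # planted genes dominate the hit list
  hits <- res$gene_id[res$significant]
  expect_gt(mean(hits %in% sprintf("g%03d", 1:20)), 0.8)
  expect_error(nb_wald_test(counts, rep(1, n)), "constant")
  expect_error(nb_wald_test(counts, m, control = m * 2), "collinear")
})

test_that("DESeq2 agrees with the in-package Wald engine on a small fixture", {
  skip_if_not_installed("DESeq2")
  set.seed(5)
  n <- 40; g <- 120
  m <- runif(n)
  mu0 <- rlnorm(g, log(80), 0.6)
  beta <- c(rep(1.2, 15), rep(0, g - 15))
  counts <- matrix(rnbinom(g * n, mu = mu0 * 2^outer(beta, m), size = 4),
                   g, n, dimnames = list(sprintf("g%03d", 1:g),
                                         sprintf("w%02d", 1:n)))
  res <- nb_wald_test(counts, m)
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, S4Vectors::DataFrame(m = m), ~ m)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  dres <- DESeq2::results(dds, name = "m")
  expect_gt(cor(res$log2fc, dres$log2FoldChange, use = "complete.obs"), 0.98)
  # calls agree on the clear-cut genes
  both <- !is.na(dres$padj)
  agree <- mean((res$padj[both] < 0.05) == (dres$padj[both] < 0.05))
  expect_gt(agree, 0.9)
})

test_that("global-null false-positive rate stays controlled", {
  set.seed(6)
  n <- 60; g <- 400
  counts <- matrix(rnbinom(g * n, mu = rep(rlnorm(g, 4, 1), n), size = 1 / 0.3),
                   g, n, dimnames = list(sprintf("g%03d", 1:g), NULL))
  counts <- filter_low_count_genes(counts)
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)
  frac_bh <- vapply(1:5, function(i) {
    covar <- rnorm(n)
    res <- nb_wald_test(counts, covar, sf = sf, dispersions = disp)
    mean(res$significant)
  }, numeric(1))
  expect_lte(mean(frac_bh), 0.05)
})

test_that("controlled accounting reflects the planted causal structure", {
  set.seed(7)
  d <- simulate_colony(colony_config(n_colonies = 2,
                                     n_workers_per_colony = 60,
                                     n_genes = 400, n_de_genes = 60,
                                     seed = 71),
                       trajectories = FALSE)
  counts <- filter_low_count_genes(d$expression)
  m <- d$workers$maturity
  noise <- rnorm(length(m))
  acc <- de_accounting(counts,
                       list(social = m, noise = noise),
                       colony = d$workers$colony_id)
  expect_gt(acc$n_de[["social"]], acc$n_de[["noise"]])
  expect_true(is.na(acc$pct_remaining["social", "social"]))
  td <- tidy(acc)
  expect_equal(nrow(td), 2)
  expect_true(all(td$pct_of_genes <= 100, na.rm = TRUE))
  expect_true(all(acc$pct_remaining >= 0 & acc$pct_remaining <= 100,
                  na.rm = TRUE))
})
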