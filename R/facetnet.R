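#' Soft community decomposition of a weighted interaction network
#'
#' Factorizes the (internally sum-normalized) interaction matrix as
#' `W ~ X Lambda X'`, where the columns of `X` are community profiles summing
#' to one and `Lambda` holds nonnegative community weights summing to one, by
#' minimizing the generalized Kullback-Leibler divergence
#' `D(W || X Lambda X')` with multiplicative updates. The soft membership of
#' worker `i` in community `c` is `M_ic = x_ic * lambda_c / sum_c(...)`, a
#' continuous number in \[0, 1\]. With `k = 2` on an ant colony network the
#' two communities correspond to the nurse and forager communities, and the
#' forager-community membership is the worker's social maturity (see
#' [orient_social_maturity()]).
#'
#' The KL objective is non-increasing at every multiplicative update; the best
#' of `n_restarts` random (Dirichlet) initializations is returned. Workers
#' with zero network strength cannot be placed and get uniform membership
#' `1/k`, flagged in `isolated`.
#'
#' @param W An [interaction_network] or symmetric nonnegative matrix.
#' @param k Number of communities (2 for nurse/forager colonies).
#' @param max_iter Maximum multiplicative updates per restart.
#' @param tol Stop when the objective decrease falls below `tol`.
#' @param n_restarts Number of random initializations.
#' @param seed Integer seed making the decomposition deterministic.
#' @return An object of class `"soft_community"`: `X` (n x k, columns sum to
#'   1), `lambda` (k weights summing to 1), `membership` (n x k, rows sum to
#'   1), `objective` (KL trace of the winning restart), `converged`,
#'   `n_iter`, `isolated`, `worker_ids`, `k`.
#' @export
#' @examples
#' net <- simulate_interaction_network(rbeta(40, 0.5, 0.5), seed = 1)
#' sc <- facetnet_decompose(net, k = 2, seed = 1)
#' head(sc$membership)
facetnet_decompose <- function(W, k = 2, max_iter = 2000, tol = 1e-9,
                               n_restarts = 10, seed = 1L) {
  if (inherits(W, "interaction_network")) {
    ids <- W$worker_ids
    W <- W$w
  } else {
    W <- as.matrix(W)
    ids <- rownames(W) %||% sprintf("W%03d", seq_len(nrow(W)))
  }
  assert_scalar_count(k, "k")
  if (any(W < 0) || any(abs(W - t(W)) > 1e-8)) {
    abort("W must be symmetric and nonnegative")
  }
  if (sum(W) <= 0) abort("W must have at least one positive entry")

  n <- nrow(W)
  strength <- rowSums(W)
  isolated <- strength == 0
  Wn <- W / sum(W)
  eps <- 1e-12

  set.seed(seed)
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    fit <- facetnet_once(Wn, k, max_iter, tol, eps)
    if (is.null(best) || fit$objective[length(fit$objective)] <
        best$objective[length(best$objective)]) {
      best <- fit
    }
  }

  lam <- best$lambda
  Xl <- sweep(best$X, 2, lam, `*`)
  rs <- rowSums(Xl)
  M <- matrix(1 / k, n, k)
  ok <- rs > 0 & !isolated
  M[ok, ] <- Xl[ok, , drop = FALSE] / rs[ok]
  dimnames(M) <- list(ids, sprintf("community_%d", seq_len(k)))
  if (any(isolated)) {
    warn(sprintf("%d isolated worker(s) assigned uniform membership 1/%d",
                 sum(isolated), k))
  }
  structure(
    list(
      X = best$X, lambda = lam, membership = M,
      objective = best$objective,
      converged = best$converged, n_iter = length(best$objective),
      isolated = setNames(isolated, ids),
      worker_ids = ids, k = as.integer(k)
    ),
    class = "soft_community"
  )
}

# one multiplicative-update run on the sum-normalized matrix
facetnet_once <- function(Wn, k, max_iter, tol, eps) {
  n <- nrow(Wn)
  X <- matrix(stats::rexp(n * k), n, k)
  X <- sweep(X, 2, colSums(X), `/`)
  lam <- rep(1 / k, k)
  obj <- numeric(max_iter)
  prev <- Inf
  converged <- FALSE
  it <- 0L
  kl <- function(What) {
    pos <- Wn > 0
    sum(Wn[pos] * log(Wn[pos] / pmax(What[pos], eps))) - sum(Wn) + sum(What)
  }
  for (it in seq_len(max_iter)) {
    What <- X %*% (lam * t(X))
    R <- Wn / pmax(What, eps)
    # X update (the lambda_c factor cancels in the column normalization)
    X <- X * (R %*% X)
    cs <- colSums(X)
    cs[cs == 0] <- 1
    X <- sweep(X, 2, cs, `/`)
    # lambda update with the new X
    What <- X %*% (lam * t(X))
    R <- Wn / pmax(What, eps)
    lam <- lam * colSums(X * (R %*% X))
    lam <- lam / sum(lam)
    obj[it] <- kl(X %*% (lam * t(X)))
    if (is.finite(prev) && prev - obj[it] < tol) {
      converged <- TRUE
      break
    }
    prev <- obj[it]
  }
  list(X = X, lambda = lam, objective = obj[seq_len(it)], converged = converged)
}

#' @export
print.soft_community <- function(x, ...) {
  cat(sprintf("<soft_community> %d workers, k = %d, KL = %.3g (%d iterations%s)\n",
              length(x$worker_ids), x$k, x$objective[x$n_iter], x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @export
tidy.soft_community <- function(x, ...) {
  out <- as_tibble(x$membership)
  out <- dplyr::bind_cols(tibble(worker_id = x$worker_ids), out)
  out$isolated <- unname(x$isolated)
  out
}

#' @export
glance.soft_community <- function(x, ...) {
  tibble(
    k = x$k, n_workers = length(x$worker_ids),
    kl_divergence = x$objective[x$n_iter],
    n_iter = x$n_iter, converged = x$converged,
    n_isolated = sum(x$isolated)
  )
}

#' Orient a two-community decomposition into a social maturity score
#'
#' Labels as the "forager" community the membership column with the larger
#' Pearson correlation with the foraging fraction; social maturity is that
#' column of the membership matrix, so the output is invariant to column
#' permutation of the input. An exact correlation tie is broken toward the
#' column whose top-decile members forage most (and logged).
#'
#' @param community A `"soft_community"` with `k = 2`.
#' @param foraging Tibble `worker_id`, `foraging` (or a named numeric vector)
#'   for at least 3 workers.
#' @return Tibble `worker_id`, `maturity`, plus the two membership columns.
#' @export
orient_social_maturity <- function(community, foraging) {
  stopifnot(inherits(community, "soft_community"))
  if (community$k != 2) abort("orientation requires k = 2")
  if (is.data.frame(foraging)) {
    fvec <- setNames(foraging$foraging, foraging$worker_id)
  } else {
    fvec <- foraging
  }
  common <- intersect(community$worker_ids, names(fvec))
  if (length(common) < 3) abort("need foraging values for >= 3 workers")
  M <- community$membership
  f <- fvec[common]
  corr <- function(col) {
    v <- M[common, col]
    if (sd(v) == 0 || sd(f) == 0) return(0)
    cor(v, f)
  }
  c1 <- corr(1); c2 <- corr(2)
  if (isTRUE(all.equal(c1, c2))) {
    # tie: larger mean foraging among each column's top-decile members
    top_mean <- function(col) {
      v <- M[common, col]
      mean(f[v >= quantile(v, 0.9)])
    }
    forager_col <- if (top_mean(1) >= top_mean(2)) 1L else 2L
    warn("correlation tie between communities; broke tie by top-decile foraging")
  } else {
    forager_col <- if (c1 > c2) 1L else 2L
  }
  tibble(
    worker_id = community$worker_ids,
    maturity = unname(M[, forager_col]),
    community_nurse = unname(M[, 3L - forager_col]),
    community_forager = unname(M[, forager_col])
  )
}

#' Decile histogram and bimodality summary of maturity scores
#'
#' Summarises the distribution of social maturity scores: counts per decile
#' bin and the ratio of mass in the two outer deciles to mass in the two
#' middle deciles. A U-shaped ("socially polarized") colony has ratio > 1; a
#' fully polarized colony with empty middle bins is reported as `Inf`.
#'
#' @param maturity Numeric vector of scores in \[0, 1\] (n >= 20).
#' @return A list with `histogram` (tibble `bin`, `lower`, `upper`, `count`)
#'   and `outer_middle_ratio`.
#' @export
maturity_distribution_diagnostic <- function(maturity) {
  stopifnot(length(maturity) >= 20, all(maturity >= 0 & maturity <= 1))
  breaks <- seq(0, 1, by = 0.1)
  bin <- cut(maturity, breaks = breaks, include.lowest = TRUE,
             labels = FALSE)
  counts <- tabulate(bin, nbins = 10)
  outer <- counts[1] + counts[10]
  middle <- counts[5] + counts[6]
  list(
    histogram = tibble(
      bin = seq_len(10),
      lower = breaks[-11], upper = breaks[-1],
      count = counts
    ),
    outer_middle_ratio = if (middle == 0) Inf else outer / middle
  )
}
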