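#' Remove genes with too few reads overall
#'
#' Keeps genes whose total count across all workers is at least `min_total`
#' (default 100, i.e., genes with fewer than 100 reads across all samples are
#' filtered out before differential expression).
#'
#' @param counts Gene x worker integer matrix.
#' @param min_total Minimum row total to keep a gene.
#' @return The filtered matrix.
#' @export
filter_low_count_genes <- function(counts, min_total = 100) {
  keep <- rowSums(counts) >= min_total
  if (!any(keep)) abort("all genes fall below the count filter")
  counts[keep, , drop = FALSE]
}

#' Median-of-ratios size factors
#'
#' Per-worker sequencing-depth normalization: each worker's factor is the
#' median, over reference genes, of its counts divided by the gene's
#' geometric mean across workers; factors are rescaled to geometric mean 1.
#' Reference genes are those with nonzero counts in every worker, falling
#' back to genes nonzero in at least 90% of workers when none exist.
#'
#' @param counts Gene x worker matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  nz_frac <- rowMeans(counts > 0)
  ref <- nz_frac == 1
  if (!any(ref)) {
    ref <- nz_frac >= 0.9
    if (!any(ref)) abort("no gene is expressed in >= 90% of workers")
  }
  sub <- counts[ref, , drop = FALSE]
  log_geo <- rowMeans(log(sub + (sub == 0)))  # zeros only in fallback mode
  ratios <- log(pmax(sub, 0.5)) - log_geo
  sf <- exp(apply(ratios, 2, median))
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Per-gene negative-binomial dispersion estimates
#'
#' Method-of-moments estimates on size-factor-normalized counts
#' (`alpha = (var - mu * mean(1/sf)) / mu^2`, floored at 1e-8), shrunk on the
#' log scale toward a monotone mean-dispersion trend fitted by isotonic
#' regression (non-increasing in mean expression). This is a deliberately
#' simple, calibration-testable replacement for empirical-Bayes dispersion
#' machinery.
#'
#' @param counts Gene x worker matrix.
#' @param sf Size factors from [size_factors()].
#' @param shrink_weight Weight of the trend in the log-scale shrinkage
#'   (0 = raw method-of-moments, 1 = trend only).
#' @return Named numeric vector of dispersions.
#' @export
estimate_dispersions <- function(counts, sf = size_factors(counts),
                                 shrink_weight = 0.5) {
  if (ncol(counts) < 4) abort("need at least 4 workers")
  floor_disp <- 1e-8
  y <- sweep(counts, 2, sf, `/`)
  mu <- rowMeans(y)
  v <- apply(y, 1, var)
  raw <- pmax((v - mu * mean(1 / sf)) / mu^2, floor_disp)
  raw[!is.finite(raw)] <- floor_disp
  # non-increasing trend in mean expression: isotonic fit on reversed order
  ord <- order(mu)
  ir <- isoreg(seq_along(ord), rev(raw[ord]))
  trend <- numeric(length(raw))
  trend[ord] <- rev(ir$yf)
  trend <- pmax(trend, floor_disp)
  out <- exp(shrink_weight * log(trend) + (1 - shrink_weight) * log(raw))
  setNames(pmax(out, floor_disp), rownames(counts))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: `p_(i) * m / i` with a running
#' minimum from the largest p-value down, capped at 1; ties are preserved.
#'
#' @param pvalues Numeric vector in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvalues)
  if (m == 1) return(pvalues)
  o <- order(pvalues, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * pvalues[o]))[ro]
}

#' Negative-binomial Wald test per gene
#'
#' For each gene fits a log-link negative-binomial regression
#' `log mu = offset(log sf) + colony + (control) + beta * covariate`
#' with the gene's dispersion held fixed (from [estimate_dispersions()]),
#' and tests `beta = 0` with a Wald z-test; Benjamini-Hochberg adjustment is
#' applied across genes. Non-convergent genes are flagged and conservatively
#' assigned p = 1.
#'
#' @param counts Gene x worker matrix (pre-filtered; see
#'   [filter_low_count_genes()]).
#' @param covariate Per-worker numeric variable of interest (nonconstant).
#' @param control Optional second per-worker covariate to control for.
#' @param colony Optional per-worker colony labels entering as indicators.
#' @param sf,dispersions Optional precomputed size factors / dispersions.
#' @param alpha Adjusted-p threshold for the `significant` flag.
#' @return A tibble of class `"de_result"`: `gene_id`, `base_mean`, `log2fc`
#'   (per unit covariate), `se`, `stat`, `pvalue`, `padj`, `significant`,
#'   `converged`. Attribute `n_nonconverged` counts flagged genes.
#' @export
nb_wald_test <- function(counts, covariate, control = NULL, colony = NULL,
                         sf = NULL, dispersions = NULL, alpha = 0.05) {
  n <- ncol(counts)
  if (length(covariate) != n) abort("covariate length must match workers")
  if (!all(is.finite(covariate))) abort("covariate must be finite")
  if (sd(covariate) == 0) abort("covariate is constant: unidentifiable")
  if (!is.null(control)) {
    if (sd(control) == 0) abort("control covariate is constant")
    if (abs(cor(covariate, control)) > 0.999) {
      abort("covariate and control are collinear")
    }
  }
  sf <- sf %||% size_factors(counts)
  dispersions <- dispersions %||% estimate_dispersions(counts, sf)

  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(colony) && length(unique(colony)) > 1) {
    cm <- stats::model.matrix(~ factor(colony))[, -1, drop = FALSE]
    X <- cbind(X, cm)
  }
  if (!is.null(control)) X <- cbind(X, control = control)
  X <- cbind(X, covariate = covariate)
  off <- log(sf)

  g <- nrow(counts)
  beta <- se <- rep(NA_real_, g)
  converged <- logical(g)
  for (i in seq_len(g)) {
    fam <- MASS::negative.binomial(theta = 1 / max(dispersions[i], 1e-8))
    fit <- tryCatch(
      suppressWarnings(
        stats::glm.fit(X, counts[i, ], family = fam, offset = off)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || fit$rank < ncol(X)) next
    p1 <- seq_len(fit$rank)
    covmat <- chol2inv(fit$qr$qr[p1, p1, drop = FALSE])
    piv <- fit$qr$pivot[p1]
    ci <- which(colnames(X)[piv] == "covariate")
    if (length(ci) != 1) next
    beta[i] <- fit$coefficients[piv][ci]
    se[i] <- sqrt(covmat[ci, ci])
    converged[i] <- is.finite(beta[i]) && is.finite(se[i]) && se[i] > 0
  }
  stat <- beta / se
  pvalue <- 2 * pnorm(-abs(stat))
  pvalue[!converged] <- 1
  stat[!converged] <- 0
  padj <- bh_adjust(pvalue)
  out <- tibble(
    gene_id = rownames(counts) %||% sprintf("gene_%04d", seq_len(g)),
    base_mean = rowMeans(sweep(counts, 2, sf, `/`)),
    log2fc = beta / log(2),
    se = se / log(2),
    stat = stat,
    pvalue = pvalue,
    padj = padj,
    significant = padj < alpha,
    converged = converged
  )
  attr(out, "n_nonconverged") <- sum(!converged)
  attr(out, "alpha") <- alpha
  class(out) <- c("de_result", class(out))
  out
}

#' Controlled differential-expression accounting
#'
#' For each of the five per-worker variables, counts the genes differentially
#' expressed by that variable alone (with colony indicators), then the
#' percentage of those genes that remain differentially expressed when
#' controlling for each other variable (significance in the two-covariate
#' model intersected with the uncontrolled set). Also reports the
#' controlled-significant percentage of all tested genes, and the size of the
#' controlled set irrespective of the uncontrolled one.
#'
#' @param counts Gene x worker matrix (pre-filtered).
#' @param variables Named list (or tibble) of per-worker numeric variables;
#'   canonically social, behavior, age, physical, microbiota.
#' @param colony Per-worker colony labels (or `NULL` for one colony).
#' @param alpha Adjusted-p significance threshold.
#' @return An object of class `"de_accounting"`: `n_de` (named uncontrolled
#'   DE counts), `pct_remaining` (variable x control matrix, `NA` diagonal),
#'   `pct_of_all_genes` (same shape, intersection as % of tested genes),
#'   `n_de_controlled` (controlled-set sizes), `n_genes_tested`, `de_sets`
#'   (named list of uncontrolled DE gene ids).
#' @export
de_accounting <- function(counts, variables, colony = NULL, alpha = 0.05) {
  variables <- as.list(variables)
  variables <- variables[!names(variables) %in% c("worker_id", "colony_id")]
  vn <- names(variables)
  if (length(vn) < 2) abort("need at least two variables")
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)
  g <- nrow(counts)

  de_sets <- purrr::map(variables, function(v) {
    res <- nb_wald_test(counts, v, colony = colony, sf = sf,
                        dispersions = disp, alpha = alpha)
    res$gene_id[res$significant]
  })
  n_de <- vapply(de_sets, length, integer(1))

  pct_remaining <- matrix(NA_real_, length(vn), length(vn),
                          dimnames = list(vn, vn))
  pct_all <- n_ctl <- pct_remaining
  for (v in vn) {
    for (ctl in setdiff(vn, v)) {
      res <- tryCatch(
        nb_wald_test(counts, variables[[v]], control = variables[[ctl]],
                     colony = colony, sf = sf, dispersions = disp,
                     alpha = alpha),
        error = function(e) NULL
      )
      if (is.null(res)) next  # collinear pair: left NA
      ctl_set <- res$gene_id[res$significant]
      inter <- length(intersect(de_sets[[v]], ctl_set))
      pct_remaining[v, ctl] <- if (n_de[[v]] == 0) NA_real_ else
        100 * inter / n_de[[v]]
      pct_all[v, ctl] <- 100 * inter / g
      n_ctl[v, ctl] <- length(ctl_set)
    }
  }
  structure(
    list(n_de = n_de, pct_remaining = pct_remaining,
         pct_of_all_genes = pct_all, n_de_controlled = n_ctl,
         n_genes_tested = g, de_sets = de_sets, alpha = alpha),
    class = "de_accounting"
  )
}

#' @export
print.de_accounting <- function(x, ...) {
  cat(sprintf("<de_accounting> %d genes tested, alpha = %g\n",
              x$n_genes_tested, x$alpha))
  tab <- cbind(n_de = x$n_de, round(x$pct_remaining, 1))
  print(tab)
  invisible(x)
}

#' @export
tidy.de_accounting <- function(x, ...) {
  vn <- names(x$n_de)
  out <- as_tibble(x$pct_remaining, rownames = "variable")
  out <- dplyr::bind_cols(
    tibble(variable = vn, n_de = unname(x$n_de),
           pct_of_genes = 100 * unname(x$n_de) / x$n_genes_tested),
    out[, setdiff(names(out), "variable")]
  )
  out
}
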