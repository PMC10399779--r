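#' Select predictor genes by differential expression on the target
#'
#' Runs the negative-binomial Wald test for the variable of interest on all
#' samples with colony indicators (model: colony + variable) and returns the
#' genes with Benjamini-Hochberg adjusted p below `alpha`. These are the
#' features the support-vector regression is trained on.
#'
#' @param counts Pre-filtered gene x worker matrix.
#' @param target Per-worker numeric variable of interest.
#' @param colony Per-worker colony labels.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param sf,dispersions Optional precomputed normalization inputs.
#' @return Character vector of gene ids.
#' @export
select_features_de <- function(counts, target, colony = NULL, alpha = 0.05,
                               sf = NULL, dispersions = NULL) {
  res <- nb_wald_test(counts, target, colony = colony, sf = sf,
                      dispersions = dispersions, alpha = alpha)
  genes <- res$gene_id[res$significant]
  if (length(genes) == 0) {
    abort("no differentially expressed genes at this alpha; relax `alpha`")
  }
  genes
}

#' Iterated half-split support-vector-regression prediction
#'
#' Quantifies how well brain expression predicts a worker-level variable:
#' at each of `n_iterations` seeded iterations, workers are split in half
#' (stratified by colony), a linear epsilon-insensitive support-vector
#' regression is fitted on the training half's expression features
#' (size-factor normalized, log2(x + 1), z-scored per gene on training
#' statistics), and the squared Pearson correlation between predicted and
#' observed values on the held-out half is recorded. The distribution of
#' these scores measures how strongly the variable is reflected in the brain
#' transcriptome.
#'
#' By default features are the genes differentially expressed by the target
#' using *all* samples (the conventional protocol, which leaks the feature
#' selection across the split); `strict_cv = TRUE` re-selects features within
#' each training half for leakage-free estimates.
#'
#' @param counts Pre-filtered gene x worker matrix.
#' @param target Per-worker numeric variable (names or order matching
#'   `colnames(counts)`).
#' @param colony Per-worker colony labels (used for stratified splits and the
#'   feature-selection design).
#' @param features Optional precomputed gene subset; when `NULL`, chosen via
#'   [select_features_de()].
#' @param n_iterations Number of half-split iterations (default 100).
#' @param seed Integer seed; fixes the split sequence.
#' @param alpha Feature-selection threshold.
#' @param cost,epsilon Linear SVR hyperparameters.
#' @param strict_cv Re-select features inside each training half.
#' @return An object of class `"prediction_result"`: `variable`, `r2`
#'   (per-iteration vector), `mean_r2`, `median_r2`, `n_features`,
#'   `features`, `n_iterations`, `seed`.
#' @export
iterate_prediction <- function(counts, target, colony = NULL, features = NULL,
                               n_iterations = 100, seed = 1L, alpha = 0.05,
                               cost = 1, epsilon = 0.1, strict_cv = FALSE,
                               variable = "target") {
  n <- ncol(counts)
  if (length(target) != n) abort("target length must match workers")
  if (n < 20) abort("need at least 20 workers")
  sf <- size_factors(counts)
  disp <- estimate_dispersions(counts, sf)
  logexpr <- t(log2(sweep(counts, 2, sf, `/`) + 1))  # workers x genes

  if (is.null(features) && !strict_cv) {
    features <- select_features_de(counts, target, colony = colony,
                                   alpha = alpha, sf = sf, dispersions = disp)
  }
  if (!strict_cv && length(features) == 0) abort("empty feature set")
  colony <- colony %||% rep("colony_1", n)

  set.seed(seed)
  r2 <- numeric(n_iterations)
  n_constant <- 0L
  for (it in seq_len(n_iterations)) {
    train <- unlist(lapply(split(seq_len(n), colony), function(idx) {
      sample(idx, floor(length(idx) / 2))
    }), use.names = FALSE)
    test <- setdiff(seq_len(n), train)
    feats <- features
    if (strict_cv) {
      feats <- tryCatch(
        select_features_de(counts[, train, drop = FALSE], target[train],
                           colony = colony[train], alpha = alpha),
        error = function(e) character(0)
      )
      if (length(feats) == 0) { r2[it] <- 0; next }
    }
    Xtr <- logexpr[train, feats, drop = FALSE]
    Xte <- logexpr[test, feats, drop = FALSE]
    mu <- colMeans(Xtr)
    sdv <- apply(Xtr, 2, sd)
    sdv[sdv == 0] <- 1
    Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, `/`)
    Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, `/`)
    fit <- e1071::svm(Xtr, target[train], type = "eps-regression",
                      kernel = "linear", cost = cost, epsilon = epsilon,
                      scale = FALSE)
    pred <- as.numeric(stats::predict(fit, Xte))
    if (sd(pred) == 0 || sd(target[test]) == 0) {
      n_constant <- n_constant + 1L
      r2[it] <- 0
    } else {
      r2[it] <- cor(pred, target[test])^2
    }
  }
  if (n_constant > 0) {
    warn(sprintf("%d iteration(s) produced constant predictions (R^2 = 0)",
                 n_constant))
  }
  structure(
    list(
      variable = variable, r2 = r2,
      mean_r2 = mean(r2), median_r2 = median(r2),
      n_features = if (strict_cv) NA_integer_ else length(features),
      features = if (strict_cv) NULL else features,
      n_iterations = n_iterations, seed = seed, strict_cv = strict_cv
    ),
    class = "prediction_result"
  )
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("<prediction_result> %s: mean R^2 = %.3f (median %.3f) over %d iterations",
              x$variable, x$mean_r2, x$median_r2, x$n_iterations))
  if (!is.na(x$n_features)) cat(sprintf(", %d feature genes", x$n_features))
  cat("\n")
  invisible(x)
}

#' @export
tidy.prediction_result <- function(x, ...) {
  tibble(variable = x$variable, iteration = seq_len(x$n_iterations),
         r_squared = x$r2)
}

#' @export
glance.prediction_result <- function(x, ...) {
  tibble(
    variable = x$variable, mean_r2 = x$mean_r2, median_r2 = x$median_r2,
    sd_r2 = sd(x$r2), n_features = x$n_features,
    n_iterations = x$n_iterations
  )
}

#' Compare two prediction-accuracy distributions
#'
#' Welch two-sample t-test between the per-iteration R-squared distributions
#' of two [iterate_prediction()] results.
#'
#' @param a,b `"prediction_result"` objects (>= 2 iterations each).
#' @return Tibble `variable_a`, `variable_b`, `mean_diff`, `t`, `df`,
#'   `p_value` (`NA` with a warning if both distributions are constant).
#' @export
compare_r2_distributions <- function(a, b) {
  stopifnot(inherits(a, "prediction_result"), inherits(b, "prediction_result"),
            a$n_iterations >= 2, b$n_iterations >= 2)
  tt <- tryCatch(stats::t.test(a$r2, b$r2), error = function(e) NULL)
  if (is.null(tt)) {
    warn("zero variance in both R^2 distributions; p undefined")
    return(tibble(variable_a = a$variable, variable_b = b$variable,
                  mean_diff = a$mean_r2 - b$mean_r2,
                  t = NA_real_, df = NA_real_, p_value = NA_real_))
  }
  tibble(
    variable_a = a$variable, variable_b = b$variable,
    mean_diff = a$mean_r2 - b$mean_r2,
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
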