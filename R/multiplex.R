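#' Pairwise Euclidean distances between worker profiles
#'
#' The non-social layers of the multiplex network (behavior, brain expression,
#' microbiota, physical environment) connect workers by profile similarity,
#' measured as Euclidean distance.
#'
#' @param profiles Worker x feature numeric matrix (rownames = worker ids) or
#'   a data frame with a `worker_id` column.
#' @return Symmetric distance matrix with zero diagonal (empty for < 2
#'   workers).
#' @export
similarity_layer <- function(profiles) {
  if (is.data.frame(profiles)) {
    ids <- profiles$worker_id
    profiles <- as.matrix(profiles[, setdiff(names(profiles),
                                             c("worker_id", "colony_id"))])
    rownames(profiles) <- ids
  }
  if (anyNA(profiles)) abort("profiles contain missing values; impute upstream")
  if (nrow(profiles) < 2) return(matrix(numeric(0), 0, 0))
  as.matrix(stats::dist(profiles))
}

#' Threshold a pairwise weight matrix at the upper quartile
#'
#' Intralayer edges of the multiplex network are unweighted and connect pairs
#' whose interaction strength strictly exceeds the upper quartile of the
#' off-diagonal edge-weight distribution. For distance (dissimilarity) layers
#' the equivalent rule keeps pairs strictly below the lower quartile of
#' distances. Percentiles use linear interpolation of order statistics.
#'
#' @param weights Symmetric matrix (interaction counts or distances).
#' @param kind `"interaction"` (keep large weights) or `"distance"` (keep
#'   small distances).
#' @return Tibble `worker_i`, `worker_j` (upper-triangle pairs).
#' @export
upper_quartile_edges <- function(weights, kind = c("interaction", "distance")) {
  kind <- match.arg(kind)
  n <- nrow(weights)
  if (is.null(rownames(weights))) {
    rownames(weights) <- colnames(weights) <- sprintf("W%03d", seq_len(n))
  }
  ut <- upper.tri(weights)
  vals <- weights[ut]
  if (length(vals) < 4) abort("need at least 4 worker pairs")
  if (kind == "interaction") {
    thr <- quantile(vals, 0.75, type = 7, names = FALSE)
    keep <- ut & weights > thr
  } else {
    thr <- quantile(vals, 0.25, type = 7, names = FALSE)
    keep <- ut & weights < thr
  }
  if (!any(keep)) warn("degenerate edge-weight distribution: no edges pass")
  idx <- which(keep, arr.ind = TRUE)
  tibble(
    worker_i = rownames(weights)[idx[, 1]],
    worker_j = colnames(weights)[idx[, 2]]
  )
}

#' Assemble the 5-layer multiplex network
#'
#' Takes one pairwise weight matrix per layer (interaction counts for the
#' social layer, profile distances for the others), thresholds each at the
#' upper quartile, and couples each worker with itself across adjacent layers
#' (identity interlayer edges). Layer order is social, behavior, expression,
#' microbiota, physical.
#'
#' @param layers Named list of symmetric matrices sharing identical worker
#'   sets; names from
#'   `c("social", "behavior", "expression", "microbiota", "physical")`.
#' @return An object of class `"multiplex_network"`: `workers`, `layer_names`,
#'   `edges` (named list of edge tibbles), `n_interlayer_edges`.
#' @export
build_multiplex <- function(layers) {
  order_ref <- c("social", "behavior", "expression", "microbiota", "physical")
  if (is.null(names(layers)) || !all(names(layers) %in% order_ref)) {
    abort("layers must be named from: social, behavior, expression, microbiota, physical")
  }
  layers <- layers[intersect(order_ref, names(layers))]
  worker_sets <- lapply(layers, rownames)
  ref <- worker_sets[[1]]
  bad <- names(layers)[!vapply(worker_sets, function(s) identical(sort(s), sort(ref)),
                               logical(1))]
  if (length(bad)) {
    abort(paste0("worker sets differ across layers: ", paste(bad, collapse = ", ")))
  }
  edges <- purrr::imap(layers, function(w, nm) {
    upper_quartile_edges(w, kind = if (nm == "social") "interaction" else "distance")
  })
  structure(
    list(
      workers = ref,
      layer_names = names(layers),
      edges = edges,
      n_interlayer_edges = (length(layers) - 1L) * length(ref)
    ),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  cat(sprintf("<multiplex_network> %d workers, %d layers (%s)\n",
              length(x$workers), length(x$layer_names),
              paste(x$layer_names, collapse = ", ")))
  for (nm in x$layer_names) {
    cat(sprintf("  %-10s %d intralayer edges\n", nm, nrow(x$edges[[nm]])))
  }
  cat(sprintf("  %d interlayer identity couplings\n", x$n_interlayer_edges))
  invisible(x)
}

#' Reduce a layer's profiles to a single principal-component score
#'
#' Centered (uncentered-variance-free) PCA of the worker x feature profile
#' matrix; returns the coordinates on the requested component, with the sign
#' fixed so the score correlates nonnegatively with the orientation variable
#' (conventionally the foraging fraction), making scores comparable across
#' colonies and runs.
#'
#' @param profiles Worker x feature matrix (rownames = worker ids) or data
#'   frame with `worker_id`.
#' @param pc_index Which principal component (1-based).
#' @param orient Named numeric vector used to fix the sign; `NULL` leaves the
#'   arbitrary PCA sign.
#' @return Named numeric vector of scores.
#' @export
reduce_layer <- function(profiles, pc_index = 1, orient = NULL) {
  if (is.data.frame(profiles)) {
    ids <- profiles$worker_id
    profiles <- as.matrix(profiles[, setdiff(names(profiles),
                                             c("worker_id", "colony_id"))])
    rownames(profiles) <- ids
  }
  assert_scalar_count(pc_index, "pc_index")
  p <- prcomp(profiles, center = TRUE, scale. = FALSE)
  if (pc_index > ncol(p$x)) {
    abort(sprintf("pc_index %d exceeds the rank (%d components available)",
                  pc_index, ncol(p$x)))
  }
  score <- p$x[, pc_index]
  if (!is.null(orient)) {
    common <- intersect(names(score), names(orient))
    if (length(common) >= 3 && sd(score[common]) > 0 &&
        sd(orient[common]) > 0 &&
        cor(score[common], orient[common]) < 0) {
      score <- -score
    }
  }
  score
}

#' Choose which expression PC carries the biological signal
#'
#' The leading PC of brain expression is often dominated by technical
#' extraction-batch effects. For each of the first `n_components` components
#' this reports the R-squared against batch (one-way group fit) and the best
#' R-squared against the supplied biological variables, and recommends the
#' smallest-index component whose biological R-squared exceeds its batch
#' R-squared (falling back to PC1 with a warning if none does). With a single
#' batch the batch R-squared is undefined and treated as 0.
#'
#' @param pc_scores Worker x component score matrix (e.g., `prcomp()$x`).
#' @param batch Per-worker batch labels.
#' @param biological Named list (or data frame) of per-worker numeric
#'   variables.
#' @param n_components How many leading components to inspect.
#' @return A list: `recommended` (component index) and `diagnostics` (tibble
#'   `component`, `batch_r2`, `biological_r2`, `best_variable`).
#' @export
select_expression_pc <- function(pc_scores, batch, biological,
                                 n_components = 5) {
  biological <- as.list(biological)
  biological <- biological[!names(biological) %in% c("worker_id", "colony_id")]
  C <- min(n_components, ncol(pc_scores))
  batch <- as.factor(batch)
  rows <- purrr::map(seq_len(C), function(j) {
    s <- pc_scores[, j]
    b_r2 <- if (nlevels(batch) < 2) 0 else summary(lm(s ~ batch))$r.squared
    bio <- vapply(biological, function(v) r_squared(s, v), numeric(1))
    tibble(
      component = j, batch_r2 = b_r2,
      biological_r2 = max(bio),
      best_variable = names(bio)[which.max(bio)]
    )
  })
  diagnostics <- dplyr::bind_rows(rows)
  passing <- diagnostics$component[diagnostics$biological_r2 > diagnostics$batch_r2]
  if (length(passing) == 0) {
    warn("no component's biological R^2 exceeds its batch R^2; using PC1")
    rec <- 1L
  } else {
    rec <- min(passing)
  }
  list(recommended = rec, diagnostics = diagnostics)
}

#' Interlayer R-squared correlation network
#'
#' Reduces the analysis to one scalar per worker per layer (social maturity,
#' PCs, age), then computes, within each colony, the squared Pearson
#' correlation for every unordered pair of the 6 variables, and averages the
#' colony matrices. Each variable's strength (sum of its incident edge
#' weights) identifies the network's hub.
#'
#' @param scores Tibble with `worker_id`, `colony_id` and the score columns.
#' @param variables Which columns form the network (default the 6 canonical
#'   variables).
#' @return An object of class `"correlation_network"`: `average` (symmetric
#'   matrix, unit diagonal), `per_colony` (named list), `strength` (tibble),
#'   `hub` (variable name).
#' @export
interlayer_r2_network <- function(scores,
                                  variables = c("social", "behavior",
                                                "expression", "microbiota",
                                                "physical", "age")) {
  missing_vars <- setdiff(variables, names(scores))
  if (length(missing_vars)) {
    abort(paste0("scores lack columns: ", paste(missing_vars, collapse = ", ")))
  }
  colonies <- unique(scores$colony_id)
  per_colony <- lapply(colonies, function(cid) {
    sub <- scores[scores$colony_id == cid, variables, drop = FALSE]
    if (nrow(sub) < 3) abort(sprintf("colony %s has fewer than 3 workers", cid))
    mat <- diag(1, length(variables))
    dimnames(mat) <- list(variables, variables)
    for (i in seq_along(variables)) {
      for (j in seq_along(variables)) {
        if (i < j) {
          x <- sub[[variables[i]]]; y <- sub[[variables[j]]]
          if (sd(x) == 0 || sd(y) == 0) {
            warn(sprintf("constant variable in colony %s; R^2 set to 0", cid))
            mat[i, j] <- mat[j, i] <- 0
          } else {
            mat[i, j] <- mat[j, i] <- cor(x, y)^2
          }
        }
      }
    }
    mat
  })
  names(per_colony) <- colonies
  avg <- Reduce(`+`, per_colony) / length(per_colony)
  strength <- tibble(
    variable = variables,
    strength = rowSums(avg) - diag(avg)
  ) %>% arrange(dplyr::desc(.data$strength))
  structure(
    list(average = avg, per_colony = per_colony, strength = strength,
         hub = strength$variable[1]),
    class = "correlation_network"
  )
}

#' @export
print.correlation_network <- function(x, ...) {
  cat(sprintf("<correlation_network> %d variables, %d colonies; hub: %s\n",
              nrow(x$average), length(x$per_colony), x$hub))
  print(round(x$average, 3))
  invisible(x)
}

#' @export
tidy.correlation_network <- function(x, ...) {
  vars <- rownames(x$average)
  idx <- which(upper.tri(x$average), arr.ind = TRUE)
  tibble(
    variable_1 = vars[idx[, 1]],
    variable_2 = vars[idx[, 2]],
    r_squared = x$average[idx]
  ) %>% arrange(dplyr::desc(.data$r_squared))
}

#' Random-intercept regression of one score on another
#'
#' Fits `y = b0 + b1 x + u_g + e` with a Gaussian random intercept per group
#' (colony) by maximum likelihood, the standard way to relate worker-level
#' scores while absorbing colony baselines. With a single group the model
#' collapses to ordinary least squares. The reported R-squared is the squared
#' Pearson correlation between the fixed-effect fitted values `b0 + b1 x` and
#' `y` (marginal-style).
#'
#' @param x,y Numeric vectors.
#' @param groups Grouping labels (colony identity).
#' @return Tibble `slope`, `se`, `t`, `r_squared`, `sigma_group`, `n`,
#'   `n_groups`.
#' @export
random_intercept_fit <- function(x, y, groups) {
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("inputs must be finite")
  if (sd(x) == 0) abort("x has zero variance")
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) {
    fit <- lm(y ~ x)
    co <- summary(fit)$coefficients
    fitted_fixed <- fitted(fit)
    return(tibble(
      slope = co["x", "Estimate"], se = co["x", "Std. Error"],
      t = co["x", "t value"],
      r_squared = r_squared(fitted_fixed, y),
      sigma_group = 0, n = length(y), n_groups = 1L
    ))
  }
  df <- data.frame(x = x, y = y, g = groups)
  fit <- lme4::lmer(y ~ x + (1 | g), data = df, REML = FALSE)
  co <- summary(fit)$coefficients
  beta <- lme4::fixef(fit)
  fitted_fixed <- beta[1] + beta[2] * x
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble(
    slope = co["x", "Estimate"], se = co["x", "Std. Error"],
    t = co["x", "t value"],
    r_squared = r_squared(fitted_fixed, y),
    sigma_group = vc$sdcor[vc$grp == "g"],
    n = length(y), n_groups = nlevels(groups)
  )
}
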