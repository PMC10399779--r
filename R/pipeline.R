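#' Per-worker layer scores for a colony dataset
#'
#' Runs the tracking-to-scores chain: zone assignment and detection filtering,
#' per-colony interaction networks and soft two-community maturity, behavior
#' normalization and PCA, expression PCA with batch-aware component choice,
#' microbiota PCA after endosymbiont exclusion, physical (hexagonal
#' occupancy) PCA, and age. All PCs are computed per colony and sign-oriented
#' toward the foraging fraction.
#'
#' @param dataset A `"colony_dataset"` with detections.
#' @param facetnet_seed Seed for the community decompositions.
#' @param n_restarts Restarts per decomposition.
#' @param expression_pc Fixed expression component index, or `NULL` to use
#'   the batch-vs-biology recommendation of [select_expression_pc()].
#' @return A list: `scores` (tibble with `worker_id`, `colony_id`, `social`,
#'   `behavior`, `expression`, `microbiota`, `physical`, `age`), `kept`
#'   (detection-filter table), `networks`, `communities`, `maturity`,
#'   `foraging`, `expression_pc` (per-colony tibble), `profiles` (per-layer
#'   per-colony matrices for multiplex construction).
#' @export
layer_scores <- function(dataset, facetnet_seed = 1L, n_restarts = 10,
                         expression_pc = NULL) {
  stopifnot(inherits(dataset, "colony_dataset"))
  if (is.null(dataset$detections)) abort("dataset has no detections")
  frames <- assign_zone(dataset$detections, dataset$geometry)
  kept <- filter_low_detection(frames, dataset$workers)
  keep_ids <- kept$worker_id[kept$kept]

  workers <- dataset$workers %>% filter(.data$worker_id %in% keep_ids)
  frames <- frames %>% filter(.data$worker_id %in% keep_ids)
  forag <- foraging_fraction(frames)

  behav_norm <- normalize_behaviors(
    dataset$behavior %>% filter(.data$worker_id %in% keep_ids)
  )

  micro <- exclude_endosymbiont(dataset$microbiota, dataset$taxonomy)
  micro_props <- relative_abundance(micro$counts)$proportions

  sf <- size_factors(dataset$expression)
  expr_log <- t(log2(sweep(dataset$expression, 2, sf, `/`) + 1))
  expr_log <- sweep(expr_log, 2, colMeans(expr_log))  # gene-centered

  colonies <- unique(workers$colony_id)
  networks <- communities <- list()
  score_rows <- vector("list", length(colonies))
  expr_pc_rows <- vector("list", length(colonies))
  profiles <- list()

  for (ci in seq_along(colonies)) {
    cid <- colonies[ci]
    wk <- workers %>% filter(.data$colony_id == cid)
    fr <- frames %>% filter(.data$worker_id %in% wk$worker_id)
    fvec <- setNames(forag$foraging, forag$worker_id)[wk$worker_id]

    net <- detect_interactions(fr, body_geometry())
    sc <- facetnet_decompose(net, k = 2, n_restarts = n_restarts,
                             seed = derive_seed(facetnet_seed, ci))
    mat <- orient_social_maturity(
      sc, tibble(worker_id = names(fvec), foraging = unname(fvec))
    )
    social <- setNames(mat$maturity, mat$worker_id)[wk$worker_id]

    bm <- behav_norm %>% filter(.data$worker_id %in% wk$worker_id)
    behavior_score <- reduce_layer(bm, pc_index = 1, orient = fvec)

    sp <- spatial_fidelity(fr, cell_diameter = body_geometry()$mean_body_length)
    phys_prof <- sp$counts / rowSums(sp$counts)
    physical_score <- reduce_layer(phys_prof, pc_index = 1, orient = fvec)

    mic_prof <- t(micro_props[, wk$worker_id, drop = FALSE])
    micro_score <- reduce_layer(mic_prof, pc_index = 1, orient = fvec)

    ex_prof <- expr_log[wk$worker_id, , drop = FALSE]
    pfit <- prcomp(ex_prof, center = TRUE)
    age_vec <- setNames(as.numeric(wk$age_weeks), wk$worker_id)
    if (is.null(expression_pc)) {
      sel <- select_expression_pc(
        pfit$x,
        batch = wk$batch_id,
        biological = list(social = social, age = age_vec, foraging = fvec)
      )
      pc_idx <- sel$recommended
    } else {
      sel <- NULL
      pc_idx <- expression_pc
    }
    expr_score <- pfit$x[, pc_idx]
    if (sd(expr_score) > 0 && cor(expr_score, fvec) < 0) {
      expr_score <- -expr_score
    }

    networks[[cid]] <- net
    communities[[cid]] <- sc
    profiles[[cid]] <- list(
      social = net$w[wk$worker_id, wk$worker_id],
      behavior = similarity_layer(bm),
      expression = similarity_layer(ex_prof),
      microbiota = similarity_layer(mic_prof),
      physical = similarity_layer(phys_prof)
    )
    expr_pc_rows[[ci]] <- tibble(colony_id = cid, expression_pc = pc_idx)
    score_rows[[ci]] <- tibble(
      worker_id = wk$worker_id,
      colony_id = cid,
      social = unname(social),
      behavior = unname(behavior_score[wk$worker_id]),
      expression = unname(expr_score[wk$worker_id]),
      microbiota = unname(micro_score[wk$worker_id]),
      physical = unname(physical_score[wk$worker_id]),
      age = unname(age_vec)
    )
  }

  list(
    scores = dplyr::bind_rows(score_rows),
    kept = kept,
    networks = networks,
    communities = communities,
    foraging = forag,
    expression_pc = dplyr::bind_rows(expr_pc_rows),
    profiles = profiles
  )
}

#' Run the full analysis on a (synthetic or supplied) colony dataset
#'
#' End-to-end composition: simulate (or accept) a dataset, derive layer
#' scores, build the per-colony multiplex networks, compute the interlayer
#' R-squared correlation network and its hub, the random-intercept
#' regressions of maturity on age and foraging, optionally the controlled
#' differential-expression accounting and the iterated SVR prediction, and
#' write all artifacts plus a manifest when `out_dir` is given. Fully
#' deterministic given `master_seed`.
#'
#' @param config A [colony_config()] (ignored when `dataset` is supplied).
#' @param dataset Optional pre-built `"colony_dataset"`.
#' @param master_seed Master seed fanned out to per-stage seeds.
#' @param de Run the 5-variable DE accounting (the slowest stage).
#' @param prediction Run iterated SVR prediction.
#' @param prediction_targets Which variables to predict from expression.
#' @param n_prediction_iterations Half-split iterations per target.
#' @param out_dir Optional output directory for CSV artifacts and manifest.
#' @return An object of class `"colony_analysis"`.
#' @export
run_full_analysis <- function(config = colony_config(),
                              dataset = NULL,
                              master_seed = config$seed,
                              de = TRUE,
                              prediction = TRUE,
                              prediction_targets = c("social", "behavior",
                                                     "age", "foraging"),
                              n_prediction_iterations = 100,
                              out_dir = NULL) {
  if (is.null(dataset)) {
    cfg <- config
    cfg$seed <- as.integer(master_seed)
    dataset <- simulate_colony(cfg)
  }
  ls_out <- layer_scores(dataset, facetnet_seed = derive_seed(master_seed, 101L))
  scores <- ls_out$scores
  corrnet <- interlayer_r2_network(scores)

  multiplex <- purrr::map(ls_out$profiles, build_multiplex)

  lmer_age <- random_intercept_fit(scores$age, scores$social, scores$colony_id)
  forag_vec <- setNames(ls_out$foraging$foraging, ls_out$foraging$worker_id)
  lmer_forag <- random_intercept_fit(forag_vec[scores$worker_id],
                                     scores$social, scores$colony_id)

  de_result <- NULL
  counts <- filter_low_count_genes(dataset$expression[, scores$worker_id,
                                                      drop = FALSE])
  if (de) {
    de_result <- de_accounting(
      counts,
      variables = list(
        social = scores$social, behavior = scores$behavior,
        age = scores$age, physical = scores$physical,
        microbiota = scores$microbiota
      ),
      colony = scores$colony_id
    )
  }

  pred_results <- NULL
  comparisons <- NULL
  if (prediction) {
    target_values <- list(
      social = scores$social, behavior = scores$behavior,
      age = scores$age, foraging = unname(forag_vec[scores$worker_id])
    )
    target_values <- target_values[prediction_targets]
    pred_results <- purrr::imap(target_values, function(v, nm) {
      iterate_prediction(counts, v, colony = scores$colony_id,
                         n_iterations = n_prediction_iterations,
                         seed = derive_seed(master_seed, 201L + match(nm, prediction_targets)),
                         variable = nm)
    })
    if (length(pred_results) > 1) {
      pairs <- utils::combn(names(pred_results), 2, simplify = FALSE)
      comparisons <- dplyr::bind_rows(purrr::map(pairs, function(p) {
        compare_r2_distributions(pred_results[[p[1]]], pred_results[[p[2]]])
      }))
    }
  }

  analysis <- structure(
    list(
      dataset = dataset, scores = scores, kept = ls_out$kept,
      networks = ls_out$networks, communities = ls_out$communities,
      foraging = ls_out$foraging, expression_pc = ls_out$expression_pc,
      multiplex = multiplex, corrnet = corrnet,
      lmer_age = lmer_age, lmer_foraging = lmer_forag,
      de = de_result, prediction = pred_results, comparisons = comparisons,
      master_seed = master_seed
    ),
    class = "colony_analysis"
  )
  if (!is.null(out_dir)) write_analysis(analysis, out_dir)
  analysis
}

#' @export
print.colony_analysis <- function(x, ...) {
  cat("<colony_analysis>\n")
  cat(sprintf("  %d workers kept in %d colonies (master seed %d)\n",
              nrow(x$scores), length(x$networks), x$master_seed))
  cat(sprintf("  correlation-network hub: %s\n", x$corrnet$hub))
  cat(sprintf("  maturity ~ age: R^2 = %.3f (t = %.2f); maturity ~ foraging: R^2 = %.3f (t = %.2f)\n",
              x$lmer_age$r_squared, x$lmer_age$t,
              x$lmer_foraging$r_squared, x$lmer_foraging$t))
  if (!is.null(x$prediction)) {
    ranks <- sort(vapply(x$prediction, `[[`, numeric(1), "mean_r2"),
                  decreasing = TRUE)
    cat("  prediction mean R^2: ",
        paste(sprintf("%s = %.2f", names(ranks), ranks), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

# plain-text run report: hub variable and prediction ranking
analysis_report <- function(x) {
  lines <- c(
    sprintf("Workers analysed: %d in %d colonies", nrow(x$scores),
            length(x$networks)),
    sprintf("Interlayer R^2 network hub: %s", x$corrnet$hub),
    sprintf("Strengths: %s",
            paste(sprintf("%s = %.3f", x$corrnet$strength$variable,
                          x$corrnet$strength$strength), collapse = ", ")),
    sprintf("Social maturity vs age: R^2 = %.3f, t = %.2f",
            x$lmer_age$r_squared, x$lmer_age$t),
    sprintf("Social maturity vs foraging: R^2 = %.3f, t = %.2f",
            x$lmer_foraging$r_squared, x$lmer_foraging$t)
  )
  if (!is.null(x$prediction)) {
    ranks <- sort(vapply(x$prediction, `[[`, numeric(1), "mean_r2"),
                  decreasing = TRUE)
    lines <- c(lines, sprintf(
      "Prediction ranking (mean R^2): %s",
      paste(sprintf("%s = %.3f", names(ranks), ranks), collapse = " > ")
    ))
  }
  lines
}

write_analysis <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(x$scores, file.path(out_dir, "layer_scores.csv"))
  readr::write_csv(x$kept, file.path(out_dir, "detection_filter.csv"))
  avg <- as_tibble(x$corrnet$average, rownames = "variable")
  readr::write_csv(avg, file.path(out_dir, "correlation_network.csv"))
  for (cid in names(x$corrnet$per_colony)) {
    readr::write_csv(
      as_tibble(x$corrnet$per_colony[[cid]], rownames = "variable"),
      file.path(out_dir, sprintf("correlation_network_%s.csv", cid))
    )
  }
  for (cid in names(x$networks)) {
    readr::write_csv(as_tibble(x$networks[[cid]]),
                     file.path(out_dir, sprintf("interactions_%s.csv", cid)))
    for (lyr in x$multiplex[[cid]]$layer_names) {
      readr::write_csv(
        x$multiplex[[cid]]$edges[[lyr]],
        file.path(out_dir, sprintf("multiplex_%s_%s.csv", cid, lyr))
      )
    }
  }
  if (!is.null(x$de)) {
    readr::write_csv(tidy(x$de), file.path(out_dir, "de_accounting.csv"))
  }
  if (!is.null(x$prediction)) {
    readr::write_csv(
      dplyr::bind_rows(purrr::map(x$prediction, tidy)),
      file.path(out_dir, "prediction_r2.csv")
    )
    if (!is.null(x$comparisons)) {
      readr::write_csv(x$comparisons, file.path(out_dir, "prediction_comparisons.csv"))
    }
  }
  writeLines(analysis_report(x), file.path(out_dir, "report.txt"))
  manifest <- list(
    package = "colonynet",
    version = as.character(utils::packageVersion("colonynet")),
    master_seed = x$master_seed,
    config = unclass(x$dataset$config),
    hub = x$corrnet$hub,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
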