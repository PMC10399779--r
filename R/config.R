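#' Configuration for a synthetic colony
#'
#' Bundles every parameter of the synthetic-colony generator. Defaults emulate
#' the study design the package targets: 4 queenright colonies of ~100
#' known-age workers tracked in a two-chamber setup (nest box connected by a
#' tube to a foraging arena), a U-shaped latent social maturity, brain
#' expression counts with maturity-driven effects plus extraction-batch
#' effects, and an endosymbiont-dominated gut microbiota.
#'
#' @param n_colonies Number of colonies.
#' @param n_workers_per_colony Workers per colony.
#' @param n_frames Tracked frames per colony (desk-scale default; real
#'   deployments record days of video).
#' @param frame_rate Frames per second (metadata only).
#' @param nest_width,nest_height Nest box dimensions, mm.
#' @param arena_width,arena_height Foraging arena dimensions, mm.
#' @param tube_length,tube_width Connecting tube dimensions, mm.
#' @param maturity_alpha,maturity_beta Beta-law parameters of the latent
#'   social maturity; the default Beta(0.5, 0.5) is bimodal ("U-shaped").
#' @param age_maturity_correlation Target Pearson correlation between age and
#'   latent maturity, in \[0, 1\].
#' @param max_age_weeks Oldest worker age, weeks.
#' @param n_behavior_frames Number of scan-sampled frames for the 5 manually
#'   annotated behaviors (each count is bounded by this).
#' @param n_genes Number of genes in the expression matrix.
#' @param n_de_genes Number of genes whose log-mean responds to maturity.
#' @param de_effect_size log2 fold change per unit maturity for those genes.
#' @param dispersion Negative-binomial dispersion of expression counts.
#' @param n_batches Number of RNA extraction batches.
#' @param batch_effect_sd Log2-scale standard deviation of batch effects.
#' @param n_asvs Number of amplicon sequence variants (ASVs).
#' @param endosymbiont_fraction Mean relative abundance of the dominant
#'   obligate endosymbiont taxon.
#' @param n_maturity_asvs Number of minor taxa whose abundance rises with
#'   maturity.
#' @param microbiota_depth Mean sequencing depth per worker.
#' @param detection_miss_rate Per-frame probability that a present worker's
#'   tag is not decoded.
#' @param seed Integer seed; identical seeds give identical datasets.
#'
#' @return A list of class `"colony_config"`.
#' @export
#' @examples
#' cfg <- colony_config(n_colonies = 1, n_workers_per_colony = 20,
#'                      n_frames = 50, seed = 1)
colony_config <- function(n_colonies = 4,
                          n_workers_per_colony = 100,
                          n_frames = 1000,
                          frame_rate = 6,
                          nest_width = 170, nest_height = 123,
                          arena_width = 170, arena_height = 123,
                          tube_length = 50, tube_width = 19,
                          maturity_alpha = 0.5, maturity_beta = 0.5,
                          age_maturity_correlation = 0.7,
                          max_age_weeks = 52,
                          n_behavior_frames = 80,
                          n_genes = 2000,
                          n_de_genes = 200,
                          de_effect_size = 1,
                          dispersion = 0.3,
                          n_batches = 4,
                          batch_effect_sd = 0.3,
                          n_asvs = 79,
                          endosymbiont_fraction = 0.8,
                          n_maturity_asvs = 8,
                          microbiota_depth = 20000,
                          detection_miss_rate = 0.1,
                          seed = 1L) {
  assert_scalar_count(n_colonies, "n_colonies")
  assert_scalar_count(n_workers_per_colony, "n_workers_per_colony", min = 2L)
  assert_scalar_count(n_frames, "n_frames")
  assert_scalar_count(n_genes, "n_genes")
  assert_scalar_count(n_de_genes, "n_de_genes", min = 0L)
  assert_scalar_count(n_batches, "n_batches")
  assert_scalar_count(n_asvs, "n_asvs", min = 2L)
  assert_scalar_count(n_maturity_asvs, "n_maturity_asvs", min = 0L)
  assert_fraction(endosymbiont_fraction, "endosymbiont_fraction")
  assert_fraction(detection_miss_rate, "detection_miss_rate")
  assert_fraction(age_maturity_correlation, "age_maturity_correlation")
  if (n_de_genes > n_genes) {
    abort("`n_de_genes` cannot exceed `n_genes`")
  }
  if (maturity_alpha <= 0 || maturity_beta <= 0) {
    abort("Beta parameters of the maturity law must be > 0")
  }
  if (n_maturity_asvs > n_asvs - 1) {
    abort("`n_maturity_asvs` must leave room for the endosymbiont taxon")
  }
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  for (d in c(nest_width, nest_height, arena_width, arena_height,
              tube_length, tube_width)) {
    if (!is.numeric(d) || d <= 0) abort("all geometry dimensions must be > 0")
  }
  structure(
    list(
      n_colonies = as.integer(n_colonies),
      n_workers_per_colony = as.integer(n_workers_per_colony),
      n_frames = as.integer(n_frames),
      frame_rate = frame_rate,
      nest_width = nest_width, nest_height = nest_height,
      arena_width = arena_width, arena_height = arena_height,
      tube_length = tube_length, tube_width = tube_width,
      maturity_alpha = maturity_alpha, maturity_beta = maturity_beta,
      age_maturity_correlation = age_maturity_correlation,
      max_age_weeks = max_age_weeks,
      n_behavior_frames = as.integer(n_behavior_frames),
      n_genes = as.integer(n_genes),
      n_de_genes = as.integer(n_de_genes),
      de_effect_size = de_effect_size,
      dispersion = dispersion,
      n_batches = as.integer(n_batches),
      batch_effect_sd = batch_effect_sd,
      n_asvs = as.integer(n_asvs),
      endosymbiont_fraction = endosymbiont_fraction,
      n_maturity_asvs = as.integer(n_maturity_asvs),
      microbiota_depth = microbiota_depth,
      detection_miss_rate = detection_miss_rate,
      seed = as.integer(seed)
    ),
    class = "colony_config"
  )
}

#' @export
print.colony_config <- function(x, ...) {
  cat("<colony_config>\n")
  cat(sprintf("  %d colonies x %d workers, %d frames @ %g fps\n",
              x$n_colonies, x$n_workers_per_colony, x$n_frames, x$frame_rate))
  cat(sprintf("  maturity ~ Beta(%g, %g); r(age, m) target %g\n",
              x$maturity_alpha, x$maturity_beta, x$age_maturity_correlation))
  cat(sprintf("  expression: %d genes (%d maturity-responsive, LFC %g), NB dispersion %g\n",
              x$n_genes, x$n_de_genes, x$de_effect_size, x$dispersion))
  cat(sprintf("  microbiota: %d ASVs, endosymbiont fraction %g\n",
              x$n_asvs, x$endosymbiont_fraction))
  invisible(x)
}

#' Body geometry used for interaction inference
#'
#' Head and body regions are modelled as disks positioned from the tag pose:
#' the head disk sits `head_offset` mm ahead of the tag centre along the body
#' axis. Defaults scale from the mean body length (head offset 0.4 L, head
#' radius 0.2 L, body radius 0.35 L).
#'
#' @param mean_body_length Mean worker body length, mm.
#' @param head_offset Distance from tag centre to head-disk centre, mm.
#' @param head_radius Head disk radius, mm.
#' @param body_radius Body disk radius, mm.
#' @return A list of class `"body_geometry"`.
#' @export
body_geometry <- function(mean_body_length = 10,
                          head_offset = 0.4 * mean_body_length,
                          head_radius = 0.2 * mean_body_length,
                          body_radius = 0.35 * mean_body_length) {
  stopifnot(mean_body_length > 0, head_offset > 0, head_radius > 0,
            body_radius > 0, head_radius < mean_body_length)
  structure(
    list(mean_body_length = mean_body_length, head_offset = head_offset,
         head_radius = head_radius, body_radius = body_radius),
    class = "body_geometry"
  )
}

#' Two-chamber setup geometry
#'
#' Nest box at the origin, tube to its right, foraging arena beyond. Used to
#' label detections with a zone (`nest`, `tube`, `arena`); boundaries are
#' half-open toward increasing x.
#'
#' @param config A [colony_config()].
#' @return A list with the three rectangles (xmin/xmax/ymin/ymax each).
#' @export
setup_geometry <- function(config = colony_config()) {
  nest <- list(xmin = 0, xmax = config$nest_width,
               ymin = 0, ymax = config$nest_height)
  tube_y0 <- (config$nest_height - config$tube_width) / 2
  tube <- list(xmin = nest$xmax, xmax = nest$xmax + config$tube_length,
               ymin = tube_y0, ymax = tube_y0 + config$tube_width)
  arena <- list(xmin = tube$xmax, xmax = tube$xmax + config$arena_width,
                ymin = 0, ymax = config$arena_height)
  structure(list(nest = nest, tube = tube, arena = arena),
            class = "setup_geometry")
}
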