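#' Simulate a synthetic multi-colony dataset
#'
#' Generates colonies with the statistical structure the downstream analysis
#' assumes: a latent per-worker social maturity `m` drawn from a (by default
#' U-shaped) Beta law; age as a rank-preserving noisy transform of `m` hitting
#' a target correlation; six task behaviors (an automatic foraging fraction
#' plus five scan-sampled counts) whose rates are noisy functions of `m`;
#' negative-binomial brain expression counts in which a known subset of genes
#' responds to `m` and extraction batches load on many genes; and a
#' Dirichlet-multinomial gut microbiota dominated by an obligate endosymbiont
#' with minor taxa enriched in high-maturity workers. Ground truth (latent
#' maturities, responsive genes) is exported for recovery tests.
#'
#' @param config A [colony_config()].
#' @param trajectories If `TRUE` (default) also simulate frame-level tag
#'   detections via [simulate_trajectories()].
#' @return A list of class `"colony_dataset"` with elements `config`,
#'   `geometry`, `workers`, `behavior`, `detections`, `expression` (gene x
#'   worker integer matrix), `gene_truth`, `microbiota` (ASV x worker integer
#'   matrix) and `taxonomy`.
#' @export
#' @examples
#' d <- simulate_colony(colony_config(n_colonies = 1,
#'                                    n_workers_per_colony = 20,
#'                                    n_frames = 50, n_genes = 100,
#'                                    n_de_genes = 10, seed = 42))
#' d$workers
simulate_colony <- function(config = colony_config(), trajectories = TRUE) {
  stopifnot(inherits(config, "colony_config"))
  set.seed(config$seed)

  n_col <- config$n_colonies
  n_w <- config$n_workers_per_colony
  n <- n_col * n_w

  workers <- tibble(
    worker_id = sprintf("C%d_W%03d", rep(seq_len(n_col), each = n_w),
                        rep(seq_len(n_w), n_col)),
    colony_id = sprintf("colony_%d", rep(seq_len(n_col), each = n_w)),
    batch_id = sprintf("batch_%d", sample.int(config$n_batches, n, replace = TRUE)),
    maturity = rbeta(n, config$maturity_alpha, config$maturity_beta)
  )
  m <- workers$maturity

  # age: linear (hence rank-preserving) in a noisy copy of m whose noise sd is
  # set so that cor(m, latent) equals the configured target
  r <- config$age_maturity_correlation
  latent <- if (r > 0) {
    sigma <- sqrt(1 / r^2 - 1)
    as.numeric(scale(m)) + sigma * rnorm(n)
  } else {
    rnorm(n)
  }
  workers$age_weeks <- as.integer(round(
    1 + (config$max_age_weeks - 1) *
      (latent - min(latent)) / (max(latent) - min(latent))
  ))

  workers <- workers[, c("worker_id", "colony_id", "age_weeks", "batch_id",
                         "maturity")]

  behavior <- simulate_behavior(workers, config)
  workers$foraging_target <- behavior$foraging

  expr <- simulate_expression(workers, config)
  micro <- simulate_microbiota(workers, config)

  dataset <- structure(
    list(
      config = config,
      geometry = setup_geometry(config),
      workers = workers,
      behavior = behavior,
      detections = NULL,
      expression = expr$counts,
      gene_truth = expr$truth,
      microbiota = micro$counts,
      taxonomy = micro$taxonomy
    ),
    class = "colony_dataset"
  )
  if (trajectories) {
    dataset$detections <- simulate_trajectories(dataset, config)
  }
  dataset
}

# six behaviors: foraging is a fraction in [0,1]; the other five are counts
# out of config$n_behavior_frames scan samples. Rates are logistic in m with a
# shared per-worker behavioral deviation u (a "personality" that does not
# average out across behaviors) plus behavior-specific noise, so the behavior
# profile is an informative but genuinely imperfect readout of m. The
# foraging noise level is calibrated so that cor(foraging, m) is ~0.75,
# matching the moderate maturity-foraging coupling seen in real colonies.
simulate_behavior <- function(workers, config) {
  n <- nrow(workers)
  m <- workers$maturity
  ns <- config$n_behavior_frames
  u <- rnorm(n)  # shared behavioral deviation
  p_logis <- function(a, b, load_u, noise_sd) {
    stats::plogis(a + b * m + load_u * u + rnorm(n, sd = noise_sd))
  }
  tibble(
    worker_id = workers$worker_id,
    colony_id = workers$colony_id,
    foraging = p_logis(-2.6, 5.2, 0.8, 1.2),
    queen_tending = rbinom(n, ns, p_logis(-0.5, -3.0, -0.8, 0.4)),
    guarding = rbinom(n, ns, p_logis(-2.5, 0.4, 0.3, 0.4)),
    nursing = rbinom(n, ns, p_logis(1.0, -3.5, -0.8, 0.4)),
    cleaning = rbinom(n, ns, p_logis(-2.3, 0.2, 0.3, 0.4)),
    trophallaxis = rbinom(n, ns, p_logis(-2.0, 0.3, 0.3, 0.4))
  )
}

# counts_gw ~ NB(mean = s_w * q_g * 2^(beta_g * m_w + B[g, batch_w]), disp).
# Batch effects are gene-specific log2 shifts: a purely sample-level shift
# would be absorbed by size-factor normalization, whereas extraction batches
# are expected to dominate the leading expression PC.
simulate_expression <- function(workers, config) {
  n <- nrow(workers)
  g <- config$n_genes
  m <- workers$maturity
  q_g <- stats::rlnorm(g, meanlog = log(20), sdlog = 1.5)
  s_w <- stats::rlnorm(n, meanlog = 0, sdlog = 0.2)
  # individual variation: genes respond to a noisy copy of m, not m itself
  m <- m + rnorm(n, sd = 0.2)
  beta <- numeric(g)
  de_idx <- if (config$n_de_genes > 0) sample.int(g, config$n_de_genes) else integer()
  # balanced up/down regulation so depth normalization stays unconfounded
  beta[de_idx] <- config$de_effect_size *
    rep_len(c(1, -1), length(de_idx))
  batch_levels <- sort(unique(workers$batch_id))
  # rank-1 batch structure: one dominant technical direction (gene loadings
  # times batch offsets), the way extraction batches show up in practice
  b_g <- rnorm(g, sd = config$batch_effect_sd)
  delta <- rnorm(length(batch_levels))
  delta <- delta - mean(delta)
  B <- outer(b_g, delta)
  batch_j <- match(workers$batch_id, batch_levels)
  log2mu <- outer(beta, m) + B[, batch_j, drop = FALSE]
  mu <- q_g * 2^log2mu
  mu <- sweep(mu, 2, s_w, `*`)
  counts <- if (config$dispersion > 0) {
    matrix(rnbinom(g * n, mu = mu, size = 1 / config$dispersion), nrow = g)
  } else {
    matrix(stats::rpois(g * n, lambda = mu), nrow = g)
  }
  gene_ids <- sprintf("gene_%04d", seq_len(g))
  dimnames(counts) <- list(gene_ids, workers$worker_id)
  list(
    counts = counts,
    truth = tibble(gene_id = gene_ids, beta = beta,
                   is_de = seq_len(g) %in% de_idx)
  )
}

# Dirichlet-multinomial with one dominant endosymbiont whose expected share is
# exactly endosymbiont_fraction; minor-taxon weights for n_maturity_asvs taxa
# scale as exp(2.5 * (m - 0.5)), emulating taxa present in foragers but rare
# in nurses.
simulate_microbiota <- function(workers, config) {
  n <- nrow(workers)
  k <- config$n_asvs
  f <- config$endosymbiont_fraction
  m <- workers$maturity
  base <- stats::rlnorm(k - 1, meanlog = 0, sdlog = 1)
  mat_idx <- if (config$n_maturity_asvs > 0) {
    order(base, decreasing = TRUE)[seq_len(config$n_maturity_asvs)]
  } else {
    integer()
  }
  # gut community tracks maturity loosely (diet/host state), not exactly
  m <- m + rnorm(n, sd = 0.35)
  conc <- 50
  counts <- matrix(0L, nrow = k, ncol = n)
  depth <- rnbinom(n, mu = config$microbiota_depth, size = 10) + 100L
  for (w in seq_len(n)) {
    minor <- base
    minor[mat_idx] <- minor[mat_idx] * exp(2.5 * (m[w] - 0.5))
    wts <- c(f, (1 - f) * minor / sum(minor))
    p <- rgamma(k, shape = conc * wts)
    p <- p / sum(p)
    counts[, w] <- as.integer(rmultinom(1, depth[w], p))
  }
  asv_ids <- sprintf("ASV_%03d", seq_len(k))
  dimnames(counts) <- list(asv_ids, workers$worker_id)
  label <- c("Blochmannia", sprintf("Taxon_%03d", seq_len(k - 1)))
  label[1 + mat_idx] <- sprintf("Acetobacteraceae_%d", seq_along(mat_idx))
  list(
    counts = counts,
    taxonomy = tibble(asv_id = asv_ids, label = label,
                      endosymbiont = c(TRUE, rep(FALSE, k - 1)))
  )
}

#' Simulate frame-level tag detections
#'
#' Biased random walks in the two-chamber geometry. Each worker occupies the
#' foraging arena with long-run probability equal to its foraging tendency
#' (increasing in latent maturity), and within a chamber performs an
#' Ornstein-Uhlenbeck walk around an anchor point interpolated between a
#' nurse-side and a forager-side anchor by its maturity, so workers of the
#' same community are near each other more often and head-overlap interactions
#' are assortative. A per-frame miss rate leaves the `present` flag `FALSE`.
#'
#' @param dataset A `"colony_dataset"` (needs `workers` with `maturity` and
#'   `foraging_target`).
#' @param config A [colony_config()]; defaults to the dataset's own.
#' @return A tibble with columns `frame` (0-based), `worker_id`, `x_mm`,
#'   `y_mm`, `theta_rad`, `present`.
#' @export
simulate_trajectories <- function(dataset, config = dataset$config) {
  workers <- dataset$workers
  geom <- setup_geometry(config)
  set.seed(derive_seed(config$seed, 11L))

  out <- vector("list", length(unique(workers$colony_id)))
  for (ci in seq_along(unique(workers$colony_id))) {
    cid <- unique(workers$colony_id)[ci]
    wk <- workers[workers$colony_id == cid, ]
    out[[ci]] <- simulate_colony_walk(wk, geom, config)
  }
  dplyr::bind_rows(out)
}

simulate_colony_walk <- function(wk, geom, config) {
  n <- nrow(wk)
  nf <- config$n_frames
  m <- wk$maturity
  pi_arena <- wk$foraging_target

  # Two aggregation sites inside the nest (brood pile / pre-foraging area)
  # whose separation axis rotates slowly around the nest centre, plus one
  # drifting focus in the arena (food). A worker's nest anchor interpolates
  # between the two sites by maturity, so same-community workers track the
  # same moving point and stay close to each other (assortative contacts);
  # because the axis rotates, each worker's time-averaged occupancy map is
  # nearly centred and carries far less maturity information than the
  # instantaneous co-location structure does.
  mid_y <- (geom$nest$ymin + geom$nest$ymax) / 2
  nest_center <- c((geom$nest$xmin + geom$nest$xmax) / 2, mid_y)
  site_radius <- 45      # half the nurse-forager site separation, mm
  axis_angle <- runif(1, -pi, pi)
  site_arena_mu <- c((geom$arena$xmin + geom$arena$xmax) / 2, mid_y)
  rho_site <- 0.99       # slow arena-site drift
  site_sd <- 25          # stationary arena-site wander, mm
  site_step <- site_sd * sqrt(1 - rho_site^2)
  Ra <- site_arena_mu
  sites <- function() {
    v <- site_radius * c(cos(axis_angle), sin(axis_angle))
    list(Rn = nest_center - v, Rf = nest_center + v)
  }
  s0 <- sites(); Rn <- s0$Rn; Rf <- s0$Rf

  jitter <- matrix(rnorm(2 * n, sd = 6), ncol = 2)  # worker-level site bias

  phi <- 0.8            # OU persistence of the worker walk
  sigma_stat <- 12      # stationary positional sd around the anchor, mm
  sigma_step <- sigma_stat * sqrt(1 - phi^2)
  k_switch <- 0.08      # zone-switch rate scale

  in_arena <- runif(n) < pi_arena
  anchors <- function() {
    a <- cbind((1 - m) * Rn[1] + m * Rf[1], (1 - m) * Rn[2] + m * Rf[2])
    a[in_arena, 1] <- Ra[1]
    a[in_arena, 2] <- Ra[2]
    a + jitter
  }
  pos <- anchors() + matrix(rnorm(2 * n, sd = sigma_stat), ncol = 2)
  theta <- runif(n, -pi, pi)

  frames <- vector("list", nf)
  for (t in seq_len(nf)) {
    axis_angle <- axis_angle + rnorm(1, sd = 0.15)
    st <- sites(); Rn <- st$Rn; Rf <- st$Rf
    Ra <- site_arena_mu + rho_site * (Ra - site_arena_mu) + rnorm(2, sd = site_step)
    # zone Markov chain with stationary arena probability pi_arena
    p_leave <- ifelse(in_arena, k_switch * (1 - pi_arena), k_switch * pi_arena)
    switching <- runif(n) < p_leave
    in_arena <- xor(in_arena, switching)
    a <- anchors()
    # walkers that changed chamber restart near their new anchor
    if (any(switching)) {
      pos[switching, ] <- a[switching, , drop = FALSE] +
        matrix(rnorm(2 * sum(switching), sd = sigma_stat), ncol = 2)
    }
    pos <- a + phi * (pos - a) + matrix(rnorm(2 * n, sd = sigma_step), ncol = 2)
    # clamp into the current chamber rectangle
    xlo <- ifelse(in_arena, geom$arena$xmin, geom$nest$xmin)
    xhi <- ifelse(in_arena, geom$arena$xmax, geom$nest$xmax)
    pos[, 1] <- pmin(pmax(pos[, 1], xlo + 1), xhi - 1)
    ylo <- ifelse(in_arena, geom$arena$ymin, geom$nest$ymin)
    yhi <- ifelse(in_arena, geom$arena$ymax, geom$nest$ymax)
    pos[, 2] <- pmin(pmax(pos[, 2], ylo + 1), yhi - 1)
    theta <- (theta + rnorm(n, sd = 0.5) + pi) %% (2 * pi) - pi
    frames[[t]] <- list(x = pos[, 1], y = pos[, 2], th = theta)
  }

  present <- matrix(runif(n * nf) >= config$detection_miss_rate, nrow = n)
  tibble(
    frame = rep(0:(nf - 1), each = n),
    worker_id = rep(wk$worker_id, nf),
    x_mm = unlist(lapply(frames, `[[`, "x"), use.names = FALSE),
    y_mm = unlist(lapply(frames, `[[`, "y"), use.names = FALSE),
    theta_rad = unlist(lapply(frames, `[[`, "th"), use.names = FALSE),
    present = as.vector(present)
  )
}

#' Direct two-community weighted network generator
#'
#' Fast path that skips trajectories: pairwise interaction counts are drawn
#' as `w_ij ~ Poisson(lambda * (m_i m_j + (1 - m_i)(1 - m_j) + epsilon))`,
#' the weighted overlapping two-block model implied by a nurse community and
#' a forager community with soft membership `m`.
#'
#' @param maturity Numeric vector of latent maturities in \[0, 1\].
#' @param mean_degree Target mean weighted degree; sets `lambda` unless given.
#' @param lambda Optional rate multiplier overriding `mean_degree`.
#' @param epsilon Baseline rate added to every pair.
#' @param worker_ids Optional node names.
#' @param seed Optional integer seed.
#' @return An [interaction_network] object.
#' @export
simulate_interaction_network <- function(maturity, mean_degree = 20,
                                         lambda = NULL, epsilon = 0.05,
                                         worker_ids = NULL, seed = NULL) {
  stopifnot(all(maturity >= 0 & maturity <= 1))
  if (!is.null(seed)) set.seed(seed)
  n <- length(maturity)
  m <- maturity
  block <- outer(m, m) + outer(1 - m, 1 - m) + epsilon
  diag(block) <- 0
  if (is.null(lambda)) {
    lambda <- mean_degree / ((n - 1) * mean(block[upper.tri(block)]))
  }
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- stats::rpois(sum(ut), lambda * block[ut])
  w <- w + t(w)
  ids <- worker_ids %||% sprintf("W%03d", seq_len(n))
  interaction_network(w, worker_ids = ids)
}

#' @export
print.colony_dataset <- function(x, ...) {
  cat("<colony_dataset>\n")
  cat(sprintf("  %d workers in %d colonies\n", nrow(x$workers),
              length(unique(x$workers$colony_id))))
  cat(sprintf("  expression: %d genes (%d maturity-responsive)\n",
              nrow(x$expression), sum(x$gene_truth$is_de)))
  cat(sprintf("  microbiota: %d ASVs (1 endosymbiont)\n", nrow(x$microbiota)))
  if (!is.null(x$detections)) {
    cat(sprintf("  detections: %d frames x %d workers\n",
                x$config$n_frames, nrow(x$workers)))
  }
  invisible(x)
}

#' Write a colony dataset to delimited text files
#'
#' Emits the worker table, detections, behavior counts, gene counts, ASV
#' counts, taxonomy, and the ground-truth tables as headed CSVs (coordinates
#' in mm, angles in radians, frames 0-based).
#'
#' @param dataset A `"colony_dataset"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_colony_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dataset$workers, file.path(dir, "workers.csv"))
  readr::write_csv(dataset$behavior, file.path(dir, "behavior.csv"))
  if (!is.null(dataset$detections)) {
    readr::write_csv(dataset$detections, file.path(dir, "detections.csv"))
  }
  write_count_matrix(dataset$expression, "gene_id",
                     file.path(dir, "gene_counts.csv"))
  write_count_matrix(dataset$microbiota, "asv_id",
                     file.path(dir, "asv_counts.csv"))
  readr::write_csv(dataset$taxonomy, file.path(dir, "taxonomy.csv"))
  readr::write_csv(dataset$gene_truth, file.path(dir, "truth_genes.csv"))
  readr::write_csv(dataset$workers[, c("worker_id", "maturity")],
                   file.path(dir, "truth_maturity.csv"))
  invisible(dir)
}

write_count_matrix <- function(mat, id_col, path) {
  df <- as_tibble(mat, rownames = id_col)
  readr::write_csv(df, path)
}

#' Read a gene or ASV count matrix written by [write_colony_dataset()]
#'
#' @param path CSV with an id column followed by one column per worker.
#' @return Integer matrix with row and column names.
#' @export
read_count_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mat <- as.matrix(df[, -1])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  mat
}
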