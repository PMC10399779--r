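#' Weighted interaction network
#'
#' Container for a symmetric worker-by-worker matrix of pairwise interaction
#' counts (zero diagonal).
#'
#' @param w Symmetric nonnegative matrix.
#' @param worker_ids Node names; defaults to `rownames(w)`.
#' @return An object of class `"interaction_network"`.
#' @export
interaction_network <- function(w, worker_ids = rownames(w)) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) abort("interaction matrix must be square")
  if (any(w < 0)) abort("interaction counts must be nonnegative")
  if (any(abs(w - t(w)) > 1e-8)) abort("interaction matrix must be symmetric")
  diag(w) <- 0
  ids <- worker_ids %||% sprintf("W%03d", seq_len(nrow(w)))
  dimnames(w) <- list(ids, ids)
  structure(list(w = w, worker_ids = ids), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d workers, %g total interactions\n",
              length(x$worker_ids), sum(x$w) / 2))
  invisible(x)
}

#' Edge-list view of an interaction network
#'
#' @param x An [interaction_network].
#' @param ... Unused.
#' @return Tibble with `worker_i`, `worker_j`, `weight` (upper triangle,
#'   nonzero pairs only).
#' @export
as_tibble.interaction_network <- function(x, ...) {
  idx <- which(upper.tri(x$w) & x$w > 0, arr.ind = TRUE)
  tibble(
    worker_i = x$worker_ids[idx[, 1]],
    worker_j = x$worker_ids[idx[, 2]],
    weight = x$w[idx]
  )
}

#' Label detections with the chamber they fall in
#'
#' Point-in-rectangle tests against the nest, tube and arena rectangles;
#' boundaries are half-open toward increasing coordinates (a point exactly on
#' the nest/tube boundary belongs to the tube).
#'
#' @param frames Detections tibble with `x_mm`, `y_mm`.
#' @param geometry A [setup_geometry()].
#' @return `frames` with a `zone` column (`"nest"`, `"tube"`, `"arena"`, or
#'   `NA` for out-of-bounds points).
#' @export
assign_zone <- function(frames, geometry) {
  in_rect <- function(r) {
    frames$x_mm >= r$xmin & frames$x_mm < r$xmax &
      frames$y_mm >= r$ymin & frames$y_mm < r$ymax
  }
  zone <- rep(NA_character_, nrow(frames))
  zone[in_rect(geometry$nest)] <- "nest"
  zone[in_rect(geometry$tube)] <- "tube"
  zone[in_rect(geometry$arena)] <- "arena"
  frames$zone <- zone
  frames
}

#' Infer pairwise interactions from tag detections
#'
#' A pair is in contact in a frame when both workers are present and their
#' head disks (centre at tag position plus `head_offset` along the body axis,
#' radius `head_radius`) intersect; in mode `"head_or_body"` contact
#' additionally occurs when either worker's head disk intersects the other's
#' body disk (centred on the tag). The interaction count `w_ij` is the number
#' of maximal contact runs after merging runs separated by at most
#' `gap_bridge` non-contact frames.
#'
#' @param frames Detections tibble (`frame`, `worker_id`, `x_mm`, `y_mm`,
#'   `theta_rad`, optionally `present`).
#' @param geometry A [body_geometry()].
#' @param gap_bridge Number of non-contact frames across which two contact
#'   runs are merged into one interaction (default 0: no bridging).
#' @param mode `"head_head"` (default) or `"head_or_body"`.
#' @param weighting `"bouts"` (default) counts maximal contact runs;
#'   `"frames"` counts contact frames. Note that widening the contact
#'   definition can merge two bouts into one, so only frame weighting is
#'   guaranteed to be entrywise monotone in the contact definition.
#' @return An [interaction_network] over all workers appearing in `frames`.
#' @export
detect_interactions <- function(frames, geometry = body_geometry(),
                                gap_bridge = 0,
                                mode = c("head_head", "head_or_body"),
                                weighting = c("bouts", "frames")) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  stopifnot(inherits(geometry, "body_geometry"), gap_bridge >= 0)
  ids <- sort(unique(frames$worker_id))
  n <- length(ids)
  if (nrow(frames) == 0 || n < 2) {
    return(interaction_network(matrix(0, n, n), worker_ids = ids))
  }
  if ("present" %in% names(frames)) frames <- frames[frames$present, ]

  hx <- frames$x_mm + geometry$head_offset * cos(frames$theta_rad)
  hy <- frames$y_mm + geometry$head_offset * sin(frames$theta_rad)
  thr_hh <- 2 * geometry$head_radius
  thr_hb <- geometry$head_radius + geometry$body_radius

  ord <- order(frames$frame)
  fr <- frames$frame[ord]
  widx <- match(frames$worker_id, ids)[ord]
  hx <- hx[ord]; hy <- hy[ord]
  bx <- frames$x_mm[ord]; by <- frames$y_mm[ord]

  # per frame, find contact pairs; collect (pair key, frame) records
  starts <- c(1L, which(diff(fr) > 0) + 1L)
  ends <- c(starts[-1L] - 1L, length(fr))
  keys <- integer(0)
  kframes <- integer(0)
  acc_k <- vector("list", length(starts))
  acc_f <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    sel <- starts[b]:ends[b]
    if (length(sel) < 2) next
    w <- widx[sel]
    dh <- as.matrix(stats::dist(cbind(hx[sel], hy[sel])))
    contact <- dh <= thr_hh
    if (mode == "head_or_body") {
      # head of row worker vs body of column worker, both directions
      dhb <- sqrt(outer(hx[sel], bx[sel], `-`)^2 +
                    outer(hy[sel], by[sel], `-`)^2)
      contact <- contact | dhb <= thr_hb | t(dhb <= thr_hb)
    }
    contact[lower.tri(contact, diag = TRUE)] <- FALSE
    hit <- which(contact, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    i <- pmin(w[hit[, 1]], w[hit[, 2]])
    j <- pmax(w[hit[, 1]], w[hit[, 2]])
    acc_k[[b]] <- (i - 1L) * n + j
    acc_f[[b]] <- rep.int(fr[sel[1]], nrow(hit))
  }
  keys <- unlist(acc_k, use.names = FALSE)
  kframes <- unlist(acc_f, use.names = FALSE)

  w <- matrix(0, n, n)
  if (length(keys)) {
    o <- order(keys, kframes)
    keys <- keys[o]; kframes <- kframes[o]
    if (weighting == "frames") {
      bouts <- tapply(rep(1L, length(keys)), keys, sum)
    } else {
      new_pair <- c(TRUE, diff(keys) != 0)
      new_bout <- new_pair | c(TRUE, diff(kframes) > gap_bridge + 1)
      bouts <- tapply(new_bout, keys, sum)
    }
    pk <- as.integer(names(bouts))
    i <- (pk - 1L) %/% n + 1L
    j <- pk - (i - 1L) * n
    w[cbind(i, j)] <- as.numeric(bouts)
    w <- w + t(w)
  }
  interaction_network(w, worker_ids = ids)
}

## --- hexagonal spatial binning -------------------------------------------
## flat-top hexagons; `cell_diameter` is the internal (across-flats) diameter,
## following the convention of using the mean ant body length as cell size.

hex_axial_from_xy <- function(x, y, cell_diameter) {
  s <- cell_diameter / sqrt(3)       # circumradius
  qf <- (2 / 3) * x / s
  rf <- (-x / 3 + sqrt(3) / 3 * y) / s
  hex_cube_round(qf, rf)
}

# cube rounding with the standard largest-residual correction
hex_cube_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_y <- !fix_x & dy > dz
  fix_z <- !fix_x & !fix_y
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  ry[fix_y] <- -rx[fix_y] - rz[fix_y]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

hex_center <- function(q, r, cell_diameter) {
  s <- cell_diameter / sqrt(3)
  list(x = s * 1.5 * q, y = s * sqrt(3) * (r + q / 2))
}

#' Spatial fidelity: hexagonal occupancy profiles
#'
#' Discretises space into an equilateral grid of flat-top hexagonal cells
#' (internal diameter `cell_diameter`, conventionally the mean ant body
#' length, grid anchored at the origin) and counts, per worker, the number of
#' frames detected in each cell.
#'
#' @param frames Detections tibble; rows with `present == FALSE` are dropped.
#' @param cell_diameter Internal (across-flats) hexagon diameter, mm.
#' @return A list of class `"spatial_profile"`: `counts` (worker x cell
#'   matrix) and `cells` (tibble of axial coordinates `q`, `r` per column).
#' @export
spatial_fidelity <- function(frames, cell_diameter = 10) {
  stopifnot(cell_diameter > 0)
  if ("present" %in% names(frames)) frames <- frames[frames$present, ]
  ids <- sort(unique(frames$worker_id))
  ax <- hex_axial_from_xy(frames$x_mm, frames$y_mm, cell_diameter)
  cell_key <- paste(ax$q, ax$r, sep = ",")
  cells <- sort(unique(cell_key))
  counts <- matrix(0L, nrow = length(ids), ncol = length(cells),
                   dimnames = list(ids, cells))
  tab <- table(factor(frames$worker_id, levels = ids),
               factor(cell_key, levels = cells))
  counts[] <- as.integer(tab)
  qr <- do.call(rbind, strsplit(cells, ","))
  structure(
    list(
      counts = counts,
      cells = tibble(cell = cells, q = as.integer(qr[, 1]),
                     r = as.integer(qr[, 2])),
      cell_diameter = cell_diameter
    ),
    class = "spatial_profile"
  )
}

#' Exclude workers with abnormally few detections
#'
#' Within each colony, keeps workers detected in at least
#' `mean - k_sd * sd` frames (sample standard deviation). Mirrors the
#' tracking-quality rule of dropping workers more than 2 SD below the colony
#' mean detection count.
#'
#' @param frames Detections tibble; only rows with `present == TRUE` count.
#' @param workers Worker table with `worker_id` and `colony_id`; if `NULL`,
#'   all workers form one colony.
#' @param k_sd Number of standard deviations below the mean (default 2).
#' @return Tibble `worker_id`, `colony_id`, `n_detected`, `kept`.
#' @export
filter_low_detection <- function(frames, workers = NULL, k_sd = 2) {
  if ("present" %in% names(frames)) frames <- frames[frames$present, ]
  det <- frames %>%
    dplyr::count(.data$worker_id, name = "n_detected")
  if (is.null(workers)) {
    workers <- tibble(worker_id = det$worker_id, colony_id = "colony_1")
  }
  workers %>%
    dplyr::select("worker_id", "colony_id") %>%
    left_join(det, by = "worker_id") %>%
    mutate(n_detected = dplyr::coalesce(.data$n_detected, 0L)) %>%
    group_by(.data$colony_id) %>%
    mutate(
      kept = dplyr::n() == 1L | is.na(sd(.data$n_detected)) |
        sd(.data$n_detected) == 0 |
        .data$n_detected >= mean(.data$n_detected) - k_sd * sd(.data$n_detected)
    ) %>%
    ungroup()
}

#' Fraction of detected frames spent in the foraging arena
#'
#' @param frames Detections tibble with a `zone` column (see [assign_zone()]);
#'   only `present` rows count.
#' @return Tibble `worker_id`, `n_detected`, `foraging` = arena frames /
#'   detected frames. Workers never detected are absent from the result.
#' @export
foraging_fraction <- function(frames) {
  if (!"zone" %in% names(frames)) {
    abort("`frames` must carry a `zone` column; see assign_zone()")
  }
  if ("present" %in% names(frames)) frames <- frames[frames$present, ]
  frames %>%
    group_by(.data$worker_id) %>%
    summarise(
      n_detected = dplyr::n(),
      foraging = mean(.data$zone == "arena", na.rm = TRUE),
      .groups = "drop"
    )
}

#' Min-max normalize behaviors within colonies
#'
#' Rescales each behavior column to \[0, 1\] within each colony
#' (`x' = (x - min) / (max - min)`); constant columns map to 0 so downstream
#' PCA input stays finite.
#'
#' @param behavior Tibble with `worker_id`, `colony_id` and behavior columns.
#' @param cols Character vector of columns to normalize; defaults to every
#'   numeric column except identifiers.
#' @return The tibble with normalized behavior columns.
#' @export
normalize_behaviors <- function(behavior, cols = NULL) {
  if (is.null(cols)) {
    cols <- setdiff(names(behavior)[vapply(behavior, is.numeric, logical(1))],
                    c("worker_id", "colony_id"))
  }
  behavior %>%
    group_by(.data$colony_id) %>%
    mutate(dplyr::across(dplyr::all_of(cols), minmax01)) %>%
    ungroup()
}

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1]) / diff(rng)
}
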