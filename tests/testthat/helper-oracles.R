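# Independent brute-force oracles used to check the vectorized implementations.

# frame-by-frame disk-intersection interaction oracle: plain loops, no shared
# code with detect_interactions()
oracle_interactions <- function(frames, geometry, gap_bridge = 0,
                                mode = "head_head", weighting = "bouts") {
  if ("present" %in% names(frames)) frames <- frames[frames$present, ]
  ids <- sort(unique(frames$worker_id))
  n <- length(ids)
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(w)
  all_frames <- sort(unique(frames$frame))
  # contact indicator per pair per frame
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      contact_frames <- integer(0)
      for (f in all_frames) {
        ra <- frames[frames$frame == f & frames$worker_id == ids[a], ]
        rb <- frames[frames$frame == f & frames$worker_id == ids[b], ]
        if (nrow(ra) != 1 || nrow(rb) != 1) next
        ha <- c(ra$x_mm + geometry$head_offset * cos(ra$theta_rad),
                ra$y_mm + geometry$head_offset * sin(ra$theta_rad))
        hb <- c(rb$x_mm + geometry$head_offset * cos(rb$theta_rad),
                rb$y_mm + geometry$head_offset * sin(rb$theta_rad))
        hit <- sqrt(sum((ha - hb)^2)) <= 2 * geometry$head_radius
        if (!hit && mode == "head_or_body") {
          ba <- c(ra$x_mm, ra$y_mm)
          bb <- c(rb$x_mm, rb$y_mm)
          thr <- geometry$head_radius + geometry$body_radius
          hit <- sqrt(sum((ha - bb)^2)) <= thr || sqrt(sum((hb - ba)^2)) <= thr
        }
        if (hit) contact_frames <- c(contact_frames, f)
      }
      if (length(contact_frames)) {
        if (weighting == "frames") {
          bouts <- length(contact_frames)
        } else {
          bouts <- 1
          if (length(contact_frames) > 1) {
            gaps <- diff(contact_frames)
            bouts <- 1 + sum(gaps > gap_bridge + 1)
          }
        }
        w[a, b] <- w[b, a] <- bouts
      }
    }
  }
  w
}

# exhaustive nearest-hexagon-center search over a generous candidate patch;
# returns, per point, the best label, the best squared distance and whether
# the optimum is an exact tie between cells (point on a cell edge)
oracle_hex_assign <- function(x, y, cell_diameter) {
  s <- cell_diameter / sqrt(3)
  qs <- seq(floor(min(x) / s / 1.5) - 3, ceiling(max(x) / s / 1.5) + 3)
  rs <- seq(floor(min(y) / s) - 6, ceiling(max(y) / s) + 6)
  grid <- expand.grid(q = qs, r = rs)
  cx <- s * 1.5 * grid$q
  cy <- s * sqrt(3) * (grid$r + grid$q / 2)
  out <- lapply(seq_along(x), function(i) {
    d2 <- (cx - x[i])^2 + (cy - y[i])^2
    j <- which.min(d2)
    list(label = paste(grid$q[j], grid$r[j], sep = ","),
         best = d2[j],
         tie = sum(abs(d2 - d2[j]) < 1e-9) > 1)
  })
  list(label = vapply(out, `[[`, character(1), "label"),
       best = vapply(out, `[[`, numeric(1), "best"),
       tie = vapply(out, `[[`, logical(1), "tie"))
}

# distance from each point to the centre of its assigned hexagon
hex_assigned_dist2 <- function(x, y, q, r, cell_diameter) {
  s <- cell_diameter / sqrt(3)
  (s * 1.5 * q - x)^2 + (s * sqrt(3) * (r + q / 2) - y)^2
}

# direct step-up BH formula (independent of bh_adjust)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# small detections tibble builder
make_frames <- function(frame, worker_id, x, y, theta = 0, present = TRUE) {
  tibble::tibble(frame = frame, worker_id = worker_id, x_mm = x, y_mm = y,
                 theta_rad = theta, present = present)
}

# random-walk fixture with several workers in a small box
random_walk_frames <- function(n_workers, n_frames, box = 60, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(seq_len(n_workers), function(w) {
    x <- cumsum(rnorm(n_frames, sd = 4)) %% box
    y <- cumsum(rnorm(n_frames, sd = 4)) %% box
    make_frames(0:(n_frames - 1), sprintf("W%02d", w), x, y,
                theta = runif(n_frames, -pi, pi),
                present = runif(n_frames) > 0.05)
  }))
}

small_colony <- function(seed = 42, ...) {
  simulate_colony(colony_config(n_colonies = 1, n_workers_per_colony = 30,
                                n_frames = 200, n_genes = 300, n_de_genes = 30,
                                n_asvs = 20, n_maturity_asvs = 4,
                                seed = seed, ...))
}
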