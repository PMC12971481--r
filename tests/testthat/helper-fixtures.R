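# Small deterministic fixtures shared across test files.

# A tiny world: 40 x 40 fine cells (4 x 4 coarse), 3 species.
tiny_world <- function(seed = 11L, n_species = 3L) {
  make_world(n_species = n_species, n_rows = 40L, n_cols = 40L, seed = seed)
}

# A minimal valid recording tibble with given species columns.
toy_records <- function(n = 20L, species = "sp01", seed = 7L) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      recording_id = sprintf("r%03d", seq_len(n)),
      year = 2024L,
      day_of_year = sample(100:200, n, replace = TRUE),
      minute_of_day = sample(0:1439, n, replace = TRUE),
      row = sample(0:39, n, replace = TRUE),
      col = sample(0:39, n, replace = TRUE),
      latitude_deg = runif(n, 60, 62),
      rec_type = sample(c("direct", "interval", "point"), n, replace = TRUE),
      duration_min = runif(n, 0.2, 5)
    )
    out$log_duration <- log(out$duration_min)
    for (sp in species) out[[sp]] <- rbinom(n, 1, 0.3)
    out
  })
}

# Per-record table for the spatial updater on a given coarse grid.
toy_spatial_records <- function(n = 60L, n_rows = 4L, n_cols = 4L, seed = 9L) {
  withr::with_seed(seed, tibble::tibble(
    row = sample(0:(n_rows - 1L), n, replace = TRUE),
    col = sample(0:(n_cols - 1L), n, replace = TRUE),
    y = rbinom(n, 1, 0.4),
    m = runif(n, 0.5, 1),
    d = runif(n, 0.2, 0.9)
  ))
}

# Independent brute-force oracle for the kernel-weighted log likelihood.
brute_local_loglik <- function(s, focal_row, focal_col, records, grid,
                               tau, trunc_km) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    d_km <- grid$cell_size_km *
      sqrt((records$row[i] - focal_row)^2 + (records$col[i] - focal_col)^2)
    w <- if (tau == 0) 1 else if (d_km <= trunc_km) exp(-tau * d_km^2 / 2) else 0
    p <- min(max(records$m[i] * s * records$d[i], 1e-12), 1 - 1e-12)
    total <- total + w * (records$y[i] * log(p) + (1 - records$y[i]) * log(1 - p))
  }
  total
}

# O(n^2) pair-counting oracle for the AUC.
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}
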