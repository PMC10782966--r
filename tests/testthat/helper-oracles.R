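# Independent oracles used to cross-check the package's implementations.
# Each is deliberately written from first principles, not by calling the
# code path it checks.

# Two-sided Student's t p-value by numeric integration of the t density.
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# ROC AUC by exhaustive positive/negative pair counting, ties = 1/2.
oracle_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Brute-force Ward.D2 agglomeration: Lance-Williams recurrence on squared
# Euclidean distances, merge heights reported on the unsquared scale.
oracle_ward_heights <- function(x) {
  d2 <- as.matrix(stats::dist(x))^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_val <- Inf
    for (i in seq_along(active)) {
      for (j in seq_along(active)) {
        if (i < j) {
          v <- d2[active[i], active[j]]
          if (v < best_val) {
            best_val <- v
            best <- c(active[i], active[j])
          }
        }
      }
    }
    i <- best[1]
    j <- best[2]
    heights[step] <- sqrt(best_val)
    ni <- sizes[i]
    nj <- sizes[j]
    for (k in active) {
      if (k != i && k != j) {
        nk <- sizes[k]
        d2[i, k] <- d2[k, i] <-
          ((ni + nk) * d2[i, k] + (nj + nk) * d2[j, k] - nk * d2[i, j]) /
          (ni + nj + nk)
      }
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Small two-condition simulation used across tests: `n_signal` planted
# lipids shifted by `delta` in condition B.
make_two_group_sim <- function(n_lipids = 194, n_signal = 0, delta = 0,
                               sigma = 0.5, n_rep = 3, seed = 1) {
  catalog <- default_lipid_catalog(n_lipids, seed = seed)
  design <- study_design(salinities = c(13, 20), hrts = 24,
                         biofilm = FALSE, n_rep = n_rep)
  effects <- if (n_signal > 0) {
    list(list(lipids = catalog[seq_len(n_signal)],
              selector = list(salinity = 20), delta = delta))
  } else {
    list()
  }
  simulate_lipidome(catalog = catalog, design = design, sigma = sigma,
                    effects = effects, seed = seed)
}

# Minimal handmade raw matrix: 4 lipids (2 per mode), 2 samples.
make_tiny_matrix <- function() {
  values <- matrix(
    c(2, 3,
      8, 5,
      4, 16,
      16, 4),
    nrow = 4, byrow = TRUE,
    dimnames = list(
      c("PG(16:0/18:1)", "PE(16:0/16:0)", "PC(16:0/18:1)", "TG(16:0/18:1/18:1)"),
      c("s1", "s2")
    )
  )
  meta <- tibble::tibble(
    sample_id = c("s1", "s2"),
    salinity = c(13, 20),
    growth_mode = "planktonic",
    hrt = 24,
    replicate = 1:2
  )
  intensity_matrix(values, sample_meta = meta)
}
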