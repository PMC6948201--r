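# Shared fixtures and independent oracles, all built in code.

make_cohort <- function(n, seed, ...) {
  cfg <- simulation_config(n, seed = seed, ...)
  simulate_cohort(cfg, events = FALSE)$cohort
}

# Set-based reimplementation of the two-of-three ascertainment rule, used as
# an independent oracle: count the distinct record types as a set.
ascertain_oracle <- function(events) {
  type_set <- unique(as.character(events$event_type))
  is_case <- length(type_set) >= 2L
  list(is_case = is_case,
       diagnosis_date = if (is_case) min(as.Date(events$event_date)) else as.Date(NA))
}

# Calibration equations at a given offset vector (shared by the oracles).
calib_counts <- function(delta, beta_mat, X, n_obs, ref_idx = 1L) {
  K <- length(delta)
  eta <- matrix(0, nrow(X), K)
  eta[, -ref_idx] <- X %*% t(beta_mat)
  eta <- eta + matrix(delta, nrow(X), K, byrow = TRUE)
  eta <- eta - apply(eta, 1L, max)
  P <- exp(eta); P <- P / rowSums(P)
  n_obs + colSums(P)
}

# 1-D grid-search oracle for the two-category calibration offset.
grid_delta_2cat <- function(beta_mat, X, n_obs, pi, lo = -20, hi = 20) {
  N <- sum(n_obs) + nrow(X)
  obj <- function(d) {
    cnt <- calib_counts(c(0, d), beta_mat, X, n_obs)
    abs(cnt[2L] / N - pi[2L])
  }
  for (r in 1:8) {
    grid <- seq(lo, hi, length.out = 201L)
    vals <- vapply(grid, obj, numeric(1))
    best <- which.min(vals)
    lo <- grid[max(1L, best - 1L)]; hi <- grid[min(201L, best + 1L)]
  }
  grid[best]
}

# Coordinate-wise bisection oracle for K >= 3: each calibration equation is
# monotone in its own offset, so cycle uniroot over the free coordinates.
# Independent of the joint Newton path used by calibrate_delta().
bisect_delta_oracle <- function(beta_mat, X, n_obs, pi, ref_idx = 1L,
                                cycles = 200L, tol = 1e-10) {
  K <- length(pi)
  N <- sum(n_obs) + nrow(X)
  delta <- rep(0, K)
  free <- setdiff(seq_len(K), ref_idx)
  for (cy in seq_len(cycles)) {
    for (k in free) {
      g <- function(d) {
        dd <- delta; dd[k] <- d
        calib_counts(dd, beta_mat, X, n_obs, ref_idx)[k] / N - pi[k]
      }
      delta[k] <- stats::uniroot(g, c(-40, 40), tol = 1e-13)$root
    }
    resid <- max(abs(calib_counts(delta, beta_mat, X, n_obs, ref_idx) / N - pi))
    if (resid < tol) break
  }
  delta
}

# A tiny hand-built cohort with every analysis column populated.
toy_cohort <- function(n = 200, seed = 99) {
  set.seed(seed)
  data.frame(
    id = seq_len(n),
    sex = factor(sample(c("Men", "Women"), n, TRUE), levels = c("Men", "Women")),
    age_group = factor(sample(c("40-49", "50-59"), n, TRUE),
                       levels = c("40-49", "50-59")),
    deprivation = factor(sample(c("Q1", "Q2"), n, TRUE), levels = c("Q1", "Q2")),
    ethnicity = factor(sample(c("White", "Asian"), n, TRUE),
                       levels = c("White", "Asian")),
    t2d = rbinom(n, 1, 0.3),
    registration_start = as.Date("2010-01-01"),
    registration_end = as.Date(NA)
  )
}
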