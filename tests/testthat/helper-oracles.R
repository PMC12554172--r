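# Independent oracles and hand-built fixtures used across the suite.

# Brute-force contact frequency: triple loop over pairs, trials, frames.
brute_force_contacts <- function(ensemble, pose, cutoff = 0.8, burn_in = 0) {
  sub <- ensemble[ensemble$pose == pose, ]
  rec_res <- sort(unique(sub$resno[sub$chain == "receptor"]))
  pep_res <- sort(unique(sub$resno[sub$chain == "peptide"]))
  trials <- sort(unique(sub$trial))
  out <- expand.grid(receptor_resno = rec_res, peptide_resno = pep_res)
  out$frequency <- NA_real_
  for (r in seq_len(nrow(out))) {
    per_trial <- numeric(length(trials))
    for (ti in seq_along(trials)) {
      d <- sub[sub$trial == trials[ti], ]
      frames <- sort(unique(d$frame))
      keep <- frames[(burn_in + 1):length(frames)]
      hits <- 0
      for (fr in keep) {
        a <- d[d$frame == fr & d$chain == "receptor" &
          d$resno == out$receptor_resno[r], c("x", "y", "z")]
        b <- d[d$frame == fr & d$chain == "peptide" &
          d$resno == out$peptide_resno[r], c("x", "y", "z")]
        dist <- sqrt(sum((as.numeric(a) - as.numeric(b))^2))
        if (dist < cutoff) hits <- hits + 1
      }
      per_trial[ti] <- hits / length(keep)
    }
    out$frequency[r] <- mean(per_trial)
  }
  out[order(out$receptor_resno, out$peptide_resno), ]
}

# Numeric-minimization RMSD oracle: search rotations (Euler angles) and
# translations directly, multi-start, and return the smallest RMSD found.
brute_force_rmsd <- function(mobile, reference, n_starts = 12) {
  rot_mat <- function(a, b, c) {
    rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
      byrow = TRUE
    )
    ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
      byrow = TRUE
    )
    rx <- matrix(c(1, 0, 0, 0, cos(c), -sin(c), 0, sin(c), cos(c)), 3,
      byrow = TRUE
    )
    rz %*% ry %*% rx
  }
  obj <- function(par) {
    r <- rot_mat(par[1], par[2], par[3])
    moved <- mobile %*% t(r)
    moved <- sweep(moved, 2, par[4:6], `+`)
    sqrt(mean(rowSums((moved - reference)^2)))
  }
  best <- Inf
  for (s in seq_len(n_starts)) {
    start <- c(runif(3, -pi, pi), colMeans(reference) - colMeans(mobile))
    fit <- optim(start, obj, method = "BFGS", control = list(maxit = 500, reltol = 1e-14))
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
      control = list(maxit = 2000, reltol = 1e-14))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Minimal two-chain ensemble where one receptor/peptide pair sits at a
# prescribed distance in each frame (one trial unless distances is a list).
make_pair_ensemble <- function(distances, pose = 1) {
  if (!is.list(distances)) distances <- list(distances)
  rows <- list()
  for (tr in seq_along(distances)) {
    d <- distances[[tr]]
    for (fr in seq_along(d)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        pose = pose, trial = tr, frame = fr,
        chain = c("receptor", "peptide"),
        resno = c(100L, 5L),
        x = c(0, d[fr]), y = 0, z = 0
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  structure(out,
    frame_spacing_ps = 10,
    class = c("trajectory_ensemble", class(out))
  )
}

# Random non-degenerate point cloud.
random_cloud <- function(n, scale = 1) matrix(rnorm(n * 3, sd = scale), n, 3)

default_noise_config <- function(seed, n_replicates = 9, noise_scale = 0.15) {
  generator_config(
    seed = seed, noise_model = "multiplicative-lognormal",
    noise_scale = noise_scale, n_replicates = n_replicates
  )
}
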