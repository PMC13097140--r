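# Independent oracles used across the suite. Deliberately plain,
# loop-based implementations that share no code with the package internals.

# Brute-force Gamma*: scalar double loop over solvent sites and solute
# atoms, explicit minimum-image arithmetic, no vectorized shortcuts.
oracle_gamma <- function(frame, r, width = 0.1) {
  nwl <- 0; ncl <- 0; nwt <- 0; nct <- 0
  for (i in seq_len(nrow(frame$solvent))) {
    dmin <- Inf
    for (j in seq_len(nrow(frame$solute))) {
      d2 <- 0
      for (k in 1:3) {
        dk <- frame$solvent[i, k] - frame$solute[j, k]
        dk <- dk - frame$box[k] * round(dk / frame$box[k])
        d2 <- d2 + dk^2
      }
      dmin <- min(dmin, sqrt(d2))
    }
    w <- frame$species[i] == "waterO"
    if (w) nwt <- nwt + 1 else nct <- nct + 1
    if (dmin >= r - width / 2 && dmin < r + width / 2) {
      if (w) nwl <- nwl + 1 else ncl <- ncl + 1
    }
  }
  if (nwl + ncl == 0) return(NA_real_)
  nwl * (nwt + nct) / (nwt * (nwl + ncl))
}

# Optimal 1-D two-cluster partition by exhaustive contiguous split
# (the global optimum of 2-means in one dimension).
oracle_two_clusters <- function(x) {
  x <- sort(x)
  n <- length(x)
  best <- Inf; best_split <- 1
  for (s in 1:(n - 1)) {
    a <- x[1:s]; b <- x[(s + 1):n]
    sse <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (sse < best) { best <- sse; best_split <- s }
  }
  list(cluster1 = x[1:best_split], cluster2 = x[(best_split + 1):n])
}

# A small random frame for oracle comparisons.
random_small_frame <- function(seed, max_sites = 500) {
  set.seed(seed)
  box <- runif(3, 2, 4)
  n_solute <- sample(2:6, 1)
  n_solvent <- sample(20:max_sites, 1)
  traj_frame(
    solute = matrix(runif(n_solute * 3, 0, max(box)), ncol = 3),
    solvent = matrix(runif(n_solvent * 3, 0, max(box)), ncol = 3),
    species = sample(c("waterO", "acnC"), n_solvent, replace = TRUE),
    box = box)
}

default_test_calibration <- function() synthetic_calibration()
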