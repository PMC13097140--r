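test_that("distance histogram bins half-open with an overflow bucket", {
  h <- histogram_distances(rep(0.275, 50))
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$counts[28], 50)   # [0.27, 0.28)

  set.seed(3)
  h2 <- histogram_distances(runif(1000))
  expect_equal(sum(h2$counts) + h2$overflow, 1000)

  h3 <- histogram_distances(c(0.005, 0.015, 0.015))
  expect_equal(h3$counts[1:2], c(1, 2))

  h4 <- histogram_distances(c(0.2, 1.0, 1.7))
  expect_equal(h4$overflow, 2)
  expect_error(histogram_distances(numeric(0)), "empty")
})

test_that("Gaussian KDE with Silverman bandwidth tracks the true density", {
  set.seed(5)
  x <- rnorm(1e4, 0.3, 0.02)
  d <- smooth_density(x)
  expect_lte(abs(d$grid[which.max(d$density)] - 0.3), 0.01)
  # sup error against the analytic normal density on the bulk of the support
  idx <- d$grid > 0.24 & d$grid < 0.36
  rel <- abs(d$density[idx] - dnorm(d$grid[idx], 0.3, 0.02)) /
    max(dnorm(0.3, 0.3, 0.02))
  expect_lt(max(rel), 0.10)

  # trapezoidal normalization holds for assorted inputs
  for (smp in list(rnorm(500, 0.5, 0.1), runif(200),
                   c(rnorm(300, 0.28, 0.02), rnorm(700, 0.8, 0.05)))) {
    dd <- smooth_density(smp)
    integral <- sum((dd$density[-1] + dd$density[-length(dd$density)]) / 2) *
      diff(dd$grid[1:2])
    expect_equal(integral, 1, tolerance = 1e-3)
  }
  expect_error(smooth_density(rep(0.3, 100)), "degenerate")
})

test_that("mode detection uses order-3 strict extrema with boundary support", {
  set.seed(6)
  uni <- smooth_density(rnorm(5000, 0.5, 0.05))
  expect_length(detect_modes(uni), 1)

  mix <- smooth_density(c(rnorm(3000, 0.28, 0.02), rnorm(7000, 0.75, 0.06)))
  m <- detect_modes(mix)
  expect_length(m, 2)
  expect_lte(abs(m[1] - 0.28), 0.03)
  expect_lte(abs(m[2] - 0.75), 0.03)

  # monotone decreasing density: only the left boundary is a mode
  fake <- structure(list(grid = seq(0, 1, 0.01),
                         density = exp(-5 * seq(0, 1, 0.01))),
                    class = "smoothed_density")
  expect_equal(detect_modes(fake), 0)
})

test_that("two-cluster mode resolution matches the stated rule and oracle", {
  grid <- seq(0, 1, 0.01)
  dens <- function(vals) structure(list(grid = grid, density = vals),
                                   class = "smoothed_density")
  # density ranks 0.28 above 0.30; open candidate stands alone
  y <- dnorm(grid, 0.28, 0.02) + 0.05 * dnorm(grid, 0.30, 0.01) +
    dnorm(grid, 0.75, 0.05)
  mm <- resolve_two_modes(c(0.28, 0.30, 0.75), dens(y))
  expect_equal(unname(mm), c(0.28, 0.75))

  # exactly two candidates come back ordered
  mm2 <- resolve_two_modes(c(0.8, 0.3), dens(dnorm(grid, 0.5, 0.2)))
  expect_equal(unname(mm2), c(0.3, 0.8))

  # four candidates: clusters {0.2, 0.21} and {0.79, 0.8}
  y4 <- dnorm(grid, 0.21, 0.02) + dnorm(grid, 0.79, 0.02)
  mm4 <- resolve_two_modes(c(0.2, 0.21, 0.79, 0.8), dens(y4))
  expect_equal(unname(mm4), c(0.21, 0.79))

  expect_error(resolve_two_modes(c(0.3, 0.3), dens(y4)), "degenerate")

  # agreement with the exhaustive-partition optimum on random candidate sets
  set.seed(8)
  for (i in 1:25) {
    cand <- sort(c(runif(sample(1:5, 1), 0.1, 0.4),
                   runif(sample(1:5, 1), 0.6, 0.9)))
    if (length(cand) < 2 || diff(range(cand)) == 0) next
    yr <- dnorm(grid, 0.25, 0.05) + dnorm(grid, 0.75, 0.05)
    mm <- resolve_two_modes(cand, dens(yr))
    oc <- oracle_two_clusters(cand)
    expect_true(mm[1] %in% oc$cluster1)
    expect_true(mm[2] %in% oc$cluster2)
  }
})

test_that("split and closed-state probability recover generative weights", {
  d <- gen_bimodal_distances(weights = c(0.3, 0.7), means = c(0.28, 0.80),
                             sds = c(0.02, 0.05), n = 1e5, seed = 13)
  dec <- decompose_states(d)
  expect_true(dec$is_bimodal)
  expect_gt(dec$split_distance, dec$mode_positions[1])
  expect_lt(dec$split_distance, dec$mode_positions[2])
  expect_equal(dec$p_closed, 0.30, tolerance = 0.01 / 0.30)
  # generative-label cross-check: p_closed matches the true label fraction
  truth <- mean(attr(d, "labels") == 1)
  expect_lt(abs(dec$p_closed - truth), 0.005)
  expect_equal(dec$mean_closed_distance, 0.28, tolerance = 0.01)

  # symmetric equal mixture splits at one half
  ds <- gen_bimodal_distances(c(0.5, 0.5), c(0.3, 0.7), c(0.03, 0.03),
                              2e4, seed = 14)
  decs <- decompose_states(ds)
  expect_equal(decs$p_closed, 0.5, tolerance = 0.02)

  # everything below the split
  dens <- smooth_density(c(rnorm(5000, 0.2, 0.02), rnorm(5000, 0.4, 0.02)))
  allbelow <- split_and_probability(dens, rnorm(1000, 0.2, 0.01), 0.2, 0.4)
  expect_equal(allbelow$p_closed, 1)
})

test_that("unimodal series classify by the 0.5 nm cutoff", {
  open <- gen_bimodal_distances(1, 0.8, 0.05, 5000, seed = 21)
  dec <- decompose_states(open)
  expect_false(dec$is_bimodal)
  expect_identical(dec$p_closed, 0)
  expect_true(is.na(dec$mean_closed_distance))

  closed <- gen_bimodal_distances(1, 0.3, 0.03, 5000, seed = 22)
  expect_warning(decc <- decompose_states(closed), "closed-like")
  expect_identical(decc$p_closed, 1)

  # boundary convention: a mode exactly at the cutoff is open
  fake <- structure(list(grid = seq(0, 1, 0.01),
                         density = dnorm(seq(0, 1, 0.01), 0.5, 0.05)),
                    class = "smoothed_density")
  b <- classify_unimodal(fake, rnorm(500, 0.5, 0.05), cutoff = 0.5)
  expect_identical(b$p_closed, 0)
})

test_that("replicate summaries follow the bimodal-only distance rule", {
  mk <- function(p, bim, d = 0.28) structure(
    list(mode_positions = 0.3, split_distance = 0.5, p_closed = p,
         mean_closed_distance = if (bim) d else NA_real_, is_bimodal = bim),
    class = "state_decomposition")

  s1 <- summarize_replicates(list(mk(0.3, TRUE), mk(0.3, TRUE),
                                  mk(0.3, TRUE)))
  expect_equal(s1$mean_p_closed, 0.3)
  expect_equal(s1$se_p_closed, 0)

  s2 <- summarize_replicates(list(mk(0.2, TRUE), mk(0.4, TRUE)))
  expect_equal(s2$mean_p_closed, 0.3)
  expect_equal(s2$se_p_closed, 0.1)

  # six replicates, two unimodal: p averaged over all six, distance over four
  decs <- c(lapply(c(0.25, 0.30, 0.35, 0.40), mk, bim = TRUE),
            list(mk(0, FALSE), mk(0, FALSE)))
  s3 <- summarize_replicates(decs)
  expect_equal(s3$n_bimodal, 4)
  expect_equal(s3$mean_p_closed, mean(c(0.25, 0.30, 0.35, 0.40, 0, 0)))
  expect_equal(s3$mean_closed_distance, 0.28)
})

test_that("decomposition is invariant to sample order and bounded", {
  d <- gen_bimodal_distances(c(0.4, 0.6), c(0.3, 0.75), c(0.03, 0.05),
                             2e4, seed = 31)
  dec1 <- decompose_states(d$samples)
  set.seed(99)
  dec2 <- decompose_states(sample(d$samples))
  expect_equal(dec1$p_closed, dec2$p_closed)
  expect_equal(dec1$split_distance, dec2$split_distance)

  # parameter-recovery property across mixture settings
  cases <- list(c(w = 0.2, m1 = 0.25, m2 = 0.80),
                c(w = 0.5, m1 = 0.30, m2 = 0.75),
                c(w = 0.7, m1 = 0.28, m2 = 0.70))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    d <- gen_bimodal_distances(c(cs["w"], 1 - cs["w"]),
                               c(cs["m1"], cs["m2"]), c(0.02, 0.04),
                               1e4, seed = 40 + i)
    dec <- decompose_states(d)
    expect_gte(dec$p_closed, 0); expect_lte(dec$p_closed, 1)
    expect_lt(abs(dec$p_closed - cs[["w"]]), 0.02)
  }
})
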