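test_that("minimum-image distances handle wrapping in orthorhombic boxes", {
  box <- c(5, 5, 5)
  sol <- matrix(c(0.1, 0, 0), ncol = 3)
  expect_equal(minimal_distance(c(0.1, 0, 0), sol, box), 0)
  expect_equal(minimal_distance(c(0.2, 0, 0), sol, box), 0.1)
  # wrap: site near the far face is 0.2 nm away through the boundary
  expect_equal(minimal_distance(c(5 - 0.1, 0, 0), sol, box), 0.2)
  # minimum over several solute atoms
  sol2 <- rbind(c(1, 1, 1), c(4, 4, 4))
  expect_equal(minimal_distance(c(4, 4, 4.3), sol2, box), 0.3)
  expect_error(minimal_distance(c(1, 1, 1), sol2[0, , drop = FALSE], box),
               "empty")
})

test_that("shell counts respect the centered half-open convention", {
  box <- c(6, 6, 6)
  sol <- matrix(c(3, 3, 3), ncol = 3)
  # 10 waters at exactly 0.40 nm, 5 acn at 0.90 nm
  dirs <- function(n, r) {
    set.seed(n)
    v <- matrix(rnorm(n * 3), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    sweep(v * r, 2, c(3, 3, 3), `+`)
  }
  fr <- traj_frame(sol, rbind(dirs(10, 0.40), dirs(5, 0.90)),
                   c(rep("waterO", 10), rep("acnC", 5)), box)
  sc <- shell_counts(fr, r = 0.4)
  expect_equal(unname(sc), c(10, 0, 10, 5))
  # no sites in shell
  expect_equal(unname(shell_counts(fr, r = 0.7))[1:2], c(0, 0))
  # shell spanning everything
  all_in <- shell_counts(fr, r = 2.6, width = 5.2)
  expect_equal(unname(all_in), c(10, 5, 10, 5))
  expect_error(shell_counts(fr, r = 0.04), "below zero")
})

test_that("shell counts are invariant under translation and rotation", {
  fr <- random_small_frame(77, max_sites = 300)
  ref <- shell_counts(fr, r = 0.5)
  # translate everything and re-wrap
  shift <- c(1.3, -0.7, 2.9)
  fr_t <- traj_frame(sweep(fr$solute, 2, shift, `+`),
                     sweep(fr$solvent, 2, shift, `+`),
                     fr$species, fr$box)
  expect_equal(shell_counts(fr_t, r = 0.5), ref)
  # whole-system rotation by 90 degrees about z in a cubic box
  frc <- random_small_frame(78, max_sites = 300)
  frc$box <- rep(max(frc$box), 3)
  rot <- function(m, L) cbind(m[, 2], L - m[, 1], m[, 3])
  ref2 <- shell_counts(traj_frame(frc$solute, frc$solvent, frc$species,
                                  frc$box), r = 0.5)
  fr_r <- traj_frame(rot(frc$solute, frc$box[1]),
                     rot(frc$solvent, frc$box[1]), frc$species, frc$box)
  expect_equal(shell_counts(fr_r, r = 0.5), ref2)
})

test_that("preferential hydration follows its defining ratio", {
  expect_equal(preferential_hydration(c(10, 0, 100, 100)), 2.0)
  # local composition equal to bulk composition
  expect_equal(preferential_hydration(c(30, 10, 300, 100)), 1.0)
  expect_equal(preferential_hydration(c(0, 5, 100, 100)), 0)
  expect_true(is.na(preferential_hydration(c(0, 0, 100, 100))))
  expect_error(preferential_hydration(c(1, 1, 0, 50)), "no water")
  # enriching water in the shell strictly increases Gamma*
  g <- vapply(1:20, function(nw)
    preferential_hydration(c(nw, 10, 200, 100)), numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("Gamma* agrees exactly with the brute-force oracle", {
  for (seed in 1:30) {
    fr <- random_small_frame(seed, max_sites = 200)
    for (r in c(0.3, 0.5)) {
      sc <- shell_counts(fr, r = r)
      got <- if (sc[1] + sc[2] == 0) NA_real_ else preferential_hydration(sc)
      expect_equal(got, oracle_gamma(fr, r), tolerance = 1e-12)
    }
  }
})

test_that("gamma profile aggregates replicates and flags exclusions", {
  # single replicate: se = 0 by convention
  fr <- gen_solvent_box(box = c(3.5, 3.5, 3.5), seed = 5)
  p1 <- gamma_profile(list(list(fr)), c(0.4, 0.5))
  expect_equal(p1$se, c(0, 0))
  expect_equal(p1$n_replicates, c(1, 1))

  # hard water exclusion in [0.35, 0.45): Gamma*(0.4) = 0
  frd <- gen_solvent_box(box = c(4, 4, 4),
                         bias = list(c(0.35, 0.45, 0)), seed = 6)
  pd <- gamma_profile(list(list(frd)), c(0.4))
  expect_equal(pd$gamma_star, 0)

  # uniform null at modest scale: mean within 3 se of 1
  reps <- lapply(1:8, function(s)
    lapply(1:3, function(j) gen_solvent_box(box = c(4, 4, 4),
                                            seed = s * 50 + j)))
  pn <- gamma_profile(reps, c(0.4, 0.5))
  expect_true(all(abs(pn$gamma_star - 1) <= 3 * pn$se))

  # per-frame mode excludes empty shells but stays near the null
  pf <- gamma_profile(reps, c(0.5), mode = "per_frame")
  expect_lt(abs(pf$gamma_star - 1), 0.2)
})

test_that("local count tables report raw frame-averaged populations", {
  box <- c(6, 6, 6)
  sol <- matrix(c(3, 3, 3), ncol = 3)
  site <- function(r) c(3 + r, 3, 3)
  fr1 <- traj_frame(sol, rbind(site(0.3), site(0.3), site(0.5)),
                    c("waterO", "waterO", "acnC"), box)
  fr2 <- traj_frame(sol, rbind(site(0.3), site(0.5), site(0.5)),
                    c("waterO", "acnC", "acnC"), box)
  tab <- local_counts_table(list(fr1, fr2), c(0.3, 0.5))
  expect_equal(tab$n_water, c(1.5, 0))
  expect_equal(tab$n_acn, c(0, 1.5))
  # empty solvent
  fr0 <- traj_frame(sol, matrix(numeric(0), 0, 3), character(0), box)
  tab0 <- local_counts_table(fr0, 0.3)
  expect_equal(unlist(tab0[, 2:3], use.names = FALSE), c(0, 0))
})
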