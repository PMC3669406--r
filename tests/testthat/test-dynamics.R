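test_that("the rate law has the mass-action form on free sites", {
  sys <- rand_panel(11)
  N0 <- attr(sys, "N0")
  # empty surface: pure association onto n*N0 sites
  expect_equal(corona_rhs(rep(0, 3), sys), sys$ka * sys$c0 * sys$n * N0)
  # full coverage with kd = 0: both terms vanish
  assoc <- assoc_panel(11)
  x_full <- metastable_composition(assoc)$x
  expect_equal(corona_rhs(x_full, assoc), rep(0, 3), tolerance = 1e-20)
  # the exact equilibrium is a fixed point
  eq <- stable_composition_exact(sys)
  scale <- sys$ka * sys$c0 * sys$n * N0
  expect_lt(max(abs(corona_rhs(eq$x, sys)) / scale), 1e-9)
})

test_that("no protein means no binding", {
  sys <- make_panel(ka = c(1e5, 2e5), kd = c(0, 0), n = c(10, 20),
                    c0 = c(0, 0))
  traj <- simulate_corona(sys, times = c(0, 1, 10, 100))
  expect_equal(tibble::as_tibble(traj)$x, rep(0, 8))
})

test_that("single species without dissociation follows the exponential
           coverage law under protein excess", {
  N0 <- 1e-9; n <- 150; ka <- 2e5
  sys <- make_panel(ka = ka, kd = 0, n = n, c0 = 1000 * n * N0)
  rate <- ka * sys$c0
  times <- seq(0, 8 / rate, length.out = 200)
  traj <- simulate_corona(sys, times = times)
  f <- f_matrix(traj, sys)[, 1]
  expect_lt(max(abs(f - (1 - exp(-rate * times)))), 1e-3)
})

test_that("trajectories conserve molecules and respect coverage bounds", {
  for (seed in 1:8) {
    sys <- rand_panel(seed)
    tab <- tibble::as_tibble(simulate_corona(sys))
    c0 <- sys$c0[match(tab$species, sys$name)]
    expect_true(all(tab$x >= -1e-9 * pmax(c0, 1e-300)))
    expect_true(all(tab$x <= c0 * (1 + 1e-9) + 1e-30))
    cover <- 1 - tab$theta
    expect_true(all(cover <= 1 + 1e-9))
    expect_true(all(tab$theta >= -1e-9))
  }
})

test_that("fast-phase composition approaches the metastable closed form", {
  for (seed in 1:3) {
    sys <- assoc_panel(seed)
    tf <- time_scales(sys)$tau_fast
    traj <- simulate_corona(sys, times = c(0, exp(seq(log(tf / 100),
                                                      log(30 * tf),
                                                      length.out = 120))))
    tab <- tidyr::pivot_wider(tibble::as_tibble(traj), id_cols = c("time", "theta"),
                              names_from = "species", values_from = "f")
    k <- which(tab$theta <= 1e-4)[1]
    expect_false(is.na(k))
    expect_lt(max(abs(as.matrix(tab[k, sys$name]) -
                        metastable_composition(sys)$f)), 0.02)
  }
})

test_that("two-phase summary finds 99% coverage and both compositions", {
  sys <- demo_panel()
  traj <- simulate_corona(sys)
  tp <- two_phase_summary(traj, sys)
  expect_true(tp$fast_phase_complete)
  # exponential-coverage estimate: t99 ~ ln(100) * tau_fast
  t_pred <- log(100) * time_scales(sys)$tau_fast
  expect_gt(tp$t99, t_pred / 10)
  expect_lt(tp$t99, t_pred * 10)
  # empirical metastable close to the closed form for this well-separated panel
  expect_lt(max(abs(tp$metastable$f - metastable_composition(sys)$f)), 0.02)
  # final state is the equilibrium
  expect_lt(max(abs(tp$final$f - stable_composition_exact(sys)$f)), 1e-6)
})

test_that("without dissociation the corona composition freezes after the
           fast phase", {
  sys <- assoc_panel(4)
  tf <- time_scales(sys)$tau_fast
  traj <- simulate_corona(sys, times = c(0, exp(seq(log(tf / 100),
                                                    log(1e4 * tf),
                                                    length.out = 150))))
  tp <- two_phase_summary(traj, sys)
  expect_true(tp$fast_phase_complete)
  # between 99% and full coverage the shares cannot rearrange without
  # dissociation; the raw fractions still scale with the residual free area
  shares <- function(comp) comp$f / sum(comp$f)
  expect_lt(max(abs(shares(tp$final) - shares(tp$metastable))), 1e-4)
})

test_that("a symmetric panel stays symmetric", {
  sys <- make_panel(ka = c(2e5, 2e5), kd = c(1e-4, 1e-4), n = c(50, 50),
                    c0 = c(1e-5, 1e-5))
  traj <- simulate_corona(sys)
  tp <- two_phase_summary(traj, sys)
  expect_equal(unname(tp$metastable$f[1]), unname(tp$metastable$f[2]),
               tolerance = 1e-6)
  expect_equal(unname(tp$final$f[1]), unname(tp$final$f[2]),
               tolerance = 1e-6)
})

test_that("insufficient protein leaves the fast phase incomplete, reported
           without error", {
  N0 <- 1e-9
  sys <- suppressWarnings(make_panel(ka = c(1e6, 1e6), kd = c(0, 0),
                                     n = c(100, 100),
                                     c0 = c(0.3 * 100 * N0, 0.3 * 100 * N0)))
  traj <- simulate_corona(sys, times = c(0, exp(seq(log(1e-4), log(1e4),
                                                    length.out = 80))))
  tp <- two_phase_summary(traj, sys)
  expect_false(tp$fast_phase_complete)
  expect_true(is.na(tp$t99))
  # everything bound: coverage plateaus at 0.6
  expect_equal(1 - attr(tp$final, "theta"), 0.6, tolerance = 1e-6)
})

test_that("the long-time limit of the full model is the exact equilibrium", {
  for (seed in c(2, 5, 9)) {
    sys <- rand_panel(seed)
    t_end <- 100 / min(sys$kd)
    tf <- time_scales(sys)$tau_fast
    traj <- simulate_corona(sys, times = c(0, exp(seq(log(tf / 10), log(t_end),
                                                      length.out = 80))))
    f_end <- f_matrix(traj, sys)[81, ]
    expect_lt(max(abs(f_end - stable_composition_exact(sys)$f)), 1e-6)
  }
})

test_that("scaling all association rates speeds the fast phase but leaves
           slow relaxation untouched", {
  sys <- demo_panel()
  sp <- tibble::as_tibble(sys)
  sp$ka <- sp$ka * 10
  fast10 <- corona_system(sp, attr(sys, "N0"))

  t99 <- function(s) {
    tf <- time_scales(s)$tau_fast
    traj <- simulate_corona(s, times = c(0, exp(seq(log(tf / 100), log(50 * tf),
                                                    length.out = 120))))
    two_phase_summary(traj, s)$t99
  }
  r <- t99(fast10) / t99(sys)
  expect_gt(r, 0.05)
  expect_lt(r, 0.2)

  # late-phase relaxation rate from the decay of the deviation from each
  # run's own equilibrium, measured over a late window
  slow_rate <- function(s) {
    eq <- stable_composition_exact(s)$f
    tt <- c(0, 1e4, 3e4)
    fm <- f_matrix(simulate_corona(s, times = tt), s)
    d <- rowSums(abs(sweep(fm, 2, eq)))
    log(d[2] / d[3]) / (tt[3] - tt[2])
  }
  expect_equal(slow_rate(fast10), slow_rate(sys), tolerance = 0.05)
})
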