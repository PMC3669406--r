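test_that("metastable fractions are association-rate shares", {
  # single competitor takes the whole surface
  one <- make_panel(ka = 1e5, kd = 1e-4, n = 100, c0 = 1e-5)
  expect_equal(metastable_composition(one)$f, 1)
  expect_equal(attr(metastable_composition(one), "theta"), 0)
  # symmetry
  sym <- make_panel(ka = c(2e5, 2e5), kd = c(1e-4, 1e-4), n = c(10, 999),
                    c0 = c(1e-5, 1e-5))
  expect_equal(metastable_composition(sym)$f, c(0.5, 0.5))
  # forced arithmetic: ka = (3, 1), equal c0
  two <- make_panel(ka = c(3e5, 1e5), kd = c(1e-4, 1e-4), n = c(10, 10),
                    c0 = c(1e-5, 1e-5))
  expect_equal(metastable_composition(two)$f, c(0.75, 0.25))
  # all rates zero: undefined
  zero <- make_panel(ka = c(1e5, 1e5), kd = c(0, 0), n = c(10, 10),
                     c0 = c(0, 0))
  expect_error(metastable_composition(zero), "undefined")
})

test_that("stable fractions follow the competitive Langmuir isotherm", {
  # K*c0 = 1 splits the surface evenly with the free area
  one <- make_panel(ka = 1e4, kd = 1e-2, n = 100, c0 = 1e-6) # K c0 = 1
  s <- stable_composition(one)
  expect_equal(s$f, 0.5)
  expect_equal(attr(s, "theta"), 0.5)
  # K1 c1 = 2, K2 c2 = 1
  two <- make_panel(ka = c(2e6, 1e6), kd = c(1e-3, 1e-3), n = c(10, 10),
                    c0 = c(1e-9, 1e-9))
  s <- stable_composition(two)
  expect_equal(s$f, c(0.5, 0.25))
  expect_equal(attr(s, "theta"), 0.25)
  # saturation: K c0 = 1e6 leaves a 1e-6-scale free area
  sat <- make_panel(ka = 1e7, kd = 1e-5, n = 100, c0 = 1e-6) # K c0 = 1e6
  s <- stable_composition(sat)
  expect_equal(s$f, 1, tolerance = 1e-5)
  expect_equal(attr(s, "theta"), 1e-6, tolerance = 1e-5)
  # kd = 0 species rejected by name
  bad <- make_panel(ka = c(1e5, 1e5), kd = c(1e-3, 0), n = c(10, 10),
                    c0 = c(1e-6, 1e-6), names = c("ok", "sticky"))
  expect_error(stable_composition(bad), "sticky")
  expect_error(stable_composition_exact(bad), "sticky")
})

test_that("exact equilibrium matches an independent scalar oracle (m = 1)", {
  # single species balance: ka (c0 - x)(b - x) = kd x with b = n N0,
  # the smaller root of the quadratic ka x^2 - (ka c0 + ka b + kd) x + ka c0 b
  ka <- 3e5; kd <- 2e-4; n <- 120; N0 <- 1e-9; c0 <- 5e-7
  b <- n * N0
  disc <- sqrt((ka * c0 + ka * b + kd)^2 - 4 * ka * ka * c0 * b)
  x_oracle <- ((ka * c0 + ka * b + kd) - disc) / (2 * ka)
  sys <- make_panel(ka = ka, kd = kd, n = n, c0 = c0, N0 = N0)
  expect_equal(stable_composition_exact(sys)$x, x_oracle, tolerance = 1e-12)
})

test_that("exact equilibrium is a fixed point of the dynamics and converges
           to the Langmuir form under protein excess", {
  for (seed in 1:5) {
    sys <- rand_panel(seed)
    eq <- stable_composition_exact(sys)
    scale <- sys$ka * sys$c0 * sys$n * attr(sys, "N0")
    expect_lt(max(abs(corona_rhs(eq$x, sys)) / scale), 1e-9)
    expect_equal(sum(eq$f) + attr(eq, "theta"), 1, tolerance = 1e-12)
  }
  # extreme excess: approximation becomes exact
  sp <- tibble::as_tibble(rand_panel(6))
  sp$c0 <- pmax(sp$c0, 1e4 * sp$n * 1e-9)
  sys <- corona_system(sp, 1e-9)
  expect_equal(stable_composition_exact(sys)$f, stable_composition(sys)$f,
               tolerance = 1e-3)
})

test_that("the Langmuir approximation error shrinks monotonically as protein
           excess grows", {
  base <- rand_panel(12)
  sp <- tibble::as_tibble(base)
  gaps <- vapply(0:4, function(k) {
    # shrink N0 tenfold per rung: same approximate composition, less depletion
    sys <- corona_system(sp, attr(base, "N0") / 10^k)
    max(abs(stable_composition_exact(sys)$f - stable_composition(sys)$f))
  }, numeric(1))
  expect_true(all(diff(gaps) < 0))
})

test_that("compositions are independent of coverage numbers and N0", {
  sys <- rand_panel(3)
  sp <- tibble::as_tibble(sys)
  sp$n <- sp$n * c(3, 0.5, 7)
  mod <- corona_system(sp, attr(sys, "N0") * 42)
  expect_identical(metastable_composition(mod)$f, metastable_composition(sys)$f)
  expect_identical(stable_composition(mod)$f, stable_composition(sys)$f)
})

test_that("composition rankings follow the rate and affinity products", {
  for (seed in 1:10) {
    sys <- rand_panel(seed)
    meta <- metastable_composition(sys)
    expect_identical(order(meta$f), order(sys$ka * sys$c0))
    stab <- stable_composition(sys)
    expect_identical(order(stab$f), order((sys$ka / sys$kd) * sys$c0))
    # normalization
    expect_equal(sum(meta$f), 1, tolerance = 1e-15)
    expect_equal(sum(stab$f) + attr(stab, "theta"), 1, tolerance = 1e-12)
  }
})

test_that("time scales are the stated rate aggregates", {
  # tau_fast = 1 / sum(ka c0): products (1e-2, 3e-2) -> 25 s
  sys <- make_panel(ka = c(1e4, 3e4), kd = c(1e-5, 1e-3), n = c(10, 10),
                    c0 = c(1e-6, 1e-6))
  ts <- time_scales(sys)
  expect_equal(ts$tau_fast, 25)
  expect_equal(ts$tau_slow_lower_bound, 1e5)
  # homogeneity: ka x10 -> tau_fast /10, slow bound unchanged
  sp <- tibble::as_tibble(sys); sp$ka <- sp$ka * 10
  ts10 <- time_scales(corona_system(sp, 1e-9))
  expect_equal(ts10$tau_fast, ts$tau_fast / 10)
  expect_equal(ts10$tau_slow_lower_bound, ts$tau_slow_lower_bound)
  # no dissociation: slow bound infinite
  assoc <- make_panel(ka = 1e5, kd = 0, n = 10, c0 = 1e-6)
  expect_identical(time_scales(assoc)$tau_slow_lower_bound, Inf)
})
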