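test_that("quadrature results satisfy the measure identities exactly", {
  tst <- ztest()
  for (pri in scenario_priors()) {
    for (n in c(50, 100, 500)) {
      r <- pos(tst, pri, n)
      p0 <- r$p0; p1 <- r$p1
      u1 <- r$u1
      u0 <- if (p0 > 0) r$u0 else 0   # p0 * u0 term vanishes when p0 = 0
      expect_equal(r$e_a, p1 * u1, tolerance = 1e-8)
      expect_equal(r$e_b, u1, tolerance = 1e-12)
      expect_equal(r$e_c, p0 * (1 - u0) + p1 * u1, tolerance = 1e-8)
      expect_equal(r$u, p0 * u0 + p1 * u1, tolerance = 1e-8)
      # algebraic gap between u-PoS and assurance
      expect_equal(r$u - r$e_c, p0 * (2 * u0 - 1), tolerance = 1e-8)
      expect_true(all(coef(r) >= 0 & coef(r) <= 1, na.rm = TRUE))
    }
  }
})

test_that("a point-mass prior reduces every measure to the power function", {
  tst <- ztest()
  for (n in c(100, 500)) {
    eta <- test_power(tst, 0.372, n)
    rq <- pos(tst, point_prior(0.372), n)
    rm <- pos(tst, point_prior(0.372), n, method = "mc", M = 10, seed = 1)
    expect_equal(unname(coef(rq)), rep(eta, 4))
    expect_equal(unname(coef(rm)), rep(eta, 4))
    expect_equal(unname(rm$se), rep(0, 4))
  }
  # point mass inside the null: the trial succeeds by accepting H0
  r0 <- pos(tst, point_prior(-0.2), 100)
  expect_equal(r0$u, 1 - test_power(tst, -0.2, 100))
  expect_equal(r0$e_c, test_power(tst, -0.2, 100))
  expect_equal(r0$e_a, 0)
  expect_true(is.na(r0$e_b))
})

test_that("closed-form assurance agrees with quadrature and its limits", {
  tst <- ztest()
  for (thd in c(0.198, 0.372, 0.545))
    for (nd in c(15, 46, 165))
      for (n in c(100, 500)) {
        pri <- normal_prior(thd, nd)
        expect_equal(enc_closed_form(tst, pri, n), pos(tst, pri, n)$e_c,
                     tolerance = 1e-8)
      }
  # infinitely concentrated prior: assurance collapses to frequentist power
  expect_equal(enc_closed_form(tst, normal_prior(0.372, 1e12), 500),
               test_power(tst, 0.372, 500), tolerance = 1e-6)
  expect_error(enc_closed_form(tst, skew_normal_prior(0.2, 46, 1), 100),
               "normal priors only")
})

test_that("Monte Carlo estimates agree with quadrature within 3 SEs", {
  tst <- ztest()
  sel <- c("normal_0.198_46", "normal_0.545_15", "skew_46", "trunc_165",
           "mix_0.5")
  for (nm in sel) {
    pri <- scenario_priors()[[nm]]
    for (n in c(100, 500)) {
      rq <- pos(tst, pri, n)
      rm <- pos(tst, pri, n, method = "mc", M = 1e5, seed = 42)
      for (k in c("u", "e_a", "e_b", "e_c")) {
        if (is.na(rq[[k]])) next
        tol <- max(3 * rm$se[[k]], 1e-12)
        expect_lt(abs(rm[[k]] - rq[[k]]), tol)
      }
    }
  }
})

test_that("MC uses common draws, flags an empty alternative, reports SEs", {
  tst <- ztest()
  pri <- normal_prior(0.198, 46)
  r1 <- pos(tst, pri, 100, method = "mc", M = 1e4, seed = 3)
  r2 <- pos(tst, pri, 100, method = "mc", M = 1e4, seed = 3)
  expect_identical(coef(r1), coef(r2))      # seeded reproducibility
  expect_named(r1$se, c("u", "e_a", "e_b", "e_c"))
  expect_true(all(r1$se > 0))
  # a prior with essentially no alternative mass: e_b undefined, with warning
  # (p1 = 1 - pnorm(8) ~ 6e-16 is positive but unreachable at M = 100)
  far <- normal_prior(-0.8, 400)
  expect_warning(rf <- pos(tst, far, 100, method = "mc", M = 100, seed = 1),
                 "undefined")
  expect_true(is.na(rf$e_b))
  expect_error(pos(tst, pri, 100, method = "mc", M = 1), "at least 2")
})

test_that("MC estimator of u-PoS is unbiased for the quadrature value", {
  tst <- ztest()
  pri <- normal_prior(0.198, 46)
  uq <- pos(tst, pri, 100)$u
  reps <- vapply(1:200, function(s)
    pos(tst, pri, 100, method = "mc", M = 1000, seed = s)$u, numeric(1))
  expect_lt(abs(mean(reps) - uq), 3 * sd(reps) / sqrt(200))
})

test_that("the ordering relations among the measures hold when 0 < p0 < 1", {
  tst <- ztest()
  with_mass <- Filter(function(p) {
    p0 <- prob_null(p); p0 > 0 && p0 < 1
  }, scenario_priors())
  expect_gte(length(with_mass), 10)
  for (pri in with_mass)
    for (n in c(50, 200, 1000)) {
      r <- pos(tst, pri, n)
      expect_gt(r$u, r$e_a)
      expect_lt(r$e_a, r$e_b)
      expect_lt(r$e_a, r$e_c)
      expect_identical(r$u > r$e_c, r$u0 > 0.5)
    }
})

test_that("with no null mass all four measures coincide", {
  tst <- ztest()
  for (nd in c(15, 46, 165)) {
    pri <- trunc_normal_prior(0.198, nd, lower = 0)
    v <- coef(pos(tst, pri, 500))
    expect_lt(max(v) - min(v), 1e-8)
    rm <- pos(tst, pri, 500, method = "mc", M = 1e5, seed = 8)
    vm <- coef(rm)
    expect_lt(max(vm) - min(vm), 3 * max(rm$se))
  }
})

test_that("large-sample limits are attained at the O(1/sqrt(n)) rate", {
  tst <- ztest()
  for (pri in scenario_priors()) {
    lim <- pos_limits(tst, pri)
    expect_equal(lim$e_a, 1 - prob_null(pri))
    expect_equal(lim$u, 1)
    # convergence to the limit is O(1/sqrt(n)) with constant
    # pi(theta0) * sigma * C, so 1e-3 closeness needs n >~ 1e8 (more for
    # priors that pile mass right at the boundary)
    r <- pos(tst, pri, 1e9)
    expect_lt(abs(r$u - 1), 1e-3)
    expect_lt(abs(r$e_b - 1), 1e-3)
    expect_lt(abs(r$e_a - lim$e_a), 1e-3)
    expect_lt(abs(r$e_c - lim$e_c), 1e-3)
  }
  # the rate itself: quadrupling n halves the distance to the limit
  for (nm in c("normal_0.198_15", "trunc_46")) {
    pri <- scenario_priors()[[nm]]
    err <- vapply(c(1e6, 4e6), function(n) 1 - pos(tst, pri, n)$u, numeric(1))
    expect_equal(err[1] / err[2], 2, tolerance = 0.05)
  }
  expect_equal(pos_limits(tst, normal_prior(0.198, 15))$e_a, 0.65,
               tolerance = 0.002)
  lp <- pos_limits(tst, point_prior(0.372))
  expect_equal(unlist(lp[c("u", "e_a", "e_b", "e_c")]),
               c(u = 1, e_a = 1, e_b = 1, e_c = 1))
})

test_that("u-PoS converges monotonically in n under quadrature", {
  tst <- ztest()
  grid <- c(seq(10, 200, by = 10), seq(250, 1000, by = 50),
            seq(2000, 10000, by = 2000))
  for (nm in c("normal_0.198_15", "skew_46", "trunc_46", "mix_0.75")) {
    pri <- scenario_priors()[[nm]]
    u <- vapply(grid, function(n) pos(tst, pri, n)$u, numeric(1))
    expect_true(all(diff(u) > -1e-6))
  }
})

test_that("an inverse-gamma variance prior reproduces the unknown-variance table", {
  tst <- ztest()
  pri <- normal_prior(0.198, 46)
  vp <- inv_gamma_prior(16, 60)
  r <- pos(tst, pri, 100, method = "mc", M = 1e6, seed = 10,
           variance_prior = vp)
  # unknown-variance values sit next to the known-variance ones
  expect_lt(abs(r$u - 0.602), max(3 * r$se[["u"]], 0.01))
  expect_lt(abs(r$e_b - 0.472), max(3 * r$se[["e_b"]], 0.01))
  expect_equal(round(r$p0, 2), 0.25)
  # degenerate variance prior recovers the known-variance MC result exactly
  rf <- pos(tst, pri, 100, method = "mc", M = 1e5, seed = 11,
            variance_prior = fixed_variance(4))
  rk <- pos(tst, pri, 100, method = "mc", M = 1e5, seed = 11)
  expect_equal(coef(rf), coef(rk))
  # only the mean of the variance prior matters: halving its SD moves u < 0.01
  vp_half <- inv_gamma_prior(58, 4 * 57)   # mean 4, SD ~ 0.53
  r2 <- pos(tst, pri, 100, method = "mc", M = 1e6, seed = 10,
            variance_prior = vp_half)
  expect_lt(abs(r2$u - r$u), 0.01)
  expect_error(pos(tst, pri, 100, variance_prior = vp), "method")
})
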