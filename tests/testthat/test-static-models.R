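# the worked nonhomogeneous example: x1 generated by
# alpha=0.5, beta=1, gamma=2 from x1(1)=1, i.e. x0 = 2 + 0.5^(t-1)
worked_series <- function(len = 5) {
  grey_series(c(1, 2 + 0.5^(seq_len(len - 1))))
}

test_that("DNGM recovers an exact recursion and its whitening form", {
  f <- fit_dngm(worked_series())
  expect_equal(f$params$alpha, 0.5, tolerance = 1e-9)
  expect_equal(f$params$beta, 1, tolerance = 1e-9)
  expect_equal(f$params$gamma, 2, tolerance = 1e-9)
  expect_equal(f$whitening$A, log(2), tolerance = 1e-9)
  expect_equal(f$whitening$B, 2 * log(2), tolerance = 1e-9)
  expect_equal(f$whitening$C, 2, tolerance = 1e-9)
  expect_lt(f$in_sample_mape, 1e-6)
  # forward mapping reproduces the recursion parameters
  rec <- whitening_to_recursion(f$whitening$A, f$whitening$B, f$whitening$C)
  expect_equal(rec$alpha, 0.5, tolerance = 1e-9)
  expect_equal(rec$beta, 1, tolerance = 1e-9)
  expect_equal(rec$gamma, 2, tolerance = 1e-9)
  # extrapolation follows the closed form 2 + 0.5^(t-1)
  ex <- simulate_static(f, horizon = 2)
  expect_equal(tail(ex$values, 2), c(2.03125, 2.015625), tolerance = 1e-9)
  expect_length(simulate_static(f, 0)$values, 5)
})

test_that("a 4-point DNGM window interpolates its three equations exactly", {
  set.seed(11)
  s <- grey_series(exp(runif(4, 0, 2)))
  f <- fit_dngm(s)
  expect_equal(f$recursion_residuals, rep(0, 3), tolerance = 1e-9)
  expect_lt(f$in_sample_mape, 1e-8)
  expect_error(fit_dngm(grey_series(c(1, 2, 3))), "at least 4")
})

test_that("DNGM time response and reduction match the recursion path", {
  wp <- list(A = log(2), B = 2 * log(2), C = 2)
  expect_equal(dngm_time_response(wp, 1, 3), 5.75, tolerance = 1e-12)
  expect_equal(dngm_time_response(wp, 1, 5), 9.9375, tolerance = 1e-12)
  expect_equal(dngm_time_response(wp, 1, 1), 1)  # anchored at t = 1
  expect_equal(dngm_restore(wp, 1, 2), 2.5, tolerance = 1e-12)
  expect_equal(dngm_restore(wp, 1, 4), 2.125, tolerance = 1e-12)
  # the exponential term vanishes: limit is B/A
  expect_equal(dngm_restore(wp, 1, 400), 2, tolerance = 1e-12)
  expect_error(dngm_time_response(wp, 1, 0), ">= 1")
  expect_error(dngm_restore(wp, 1, 1), "anchored")
  expect_error(dngm_restore(list(A = NA, B = 1, C = 1), 1, 2), "unavailable")
})

test_that("restoration equals differenced time response; mappings round-trip", {
  set.seed(42)
  for (i in 1:30) {
    p <- rand_whitening()
    wp <- list(A = p$A, B = p$B, C = p$C)
    t <- 2:20
    lhs <- dngm_restore(wp, p$x1_initial, t)
    rhs <- dngm_time_response(wp, p$x1_initial, t) -
      dngm_time_response(wp, p$x1_initial, t - 1)
    scale <- abs(p$x1_initial) + (abs(p$B / p$A) + abs(p$B / p$A^2) +
      abs(p$C / p$A)) * max(exp(-p$A * (t - 1)), 1) * 20
    expect_lt(max(rel_dev(lhs, rhs, scale)), 1e-10)

    rec <- whitening_to_recursion(p$A, p$B, p$C)
    back <- recursion_to_whitening(rec$alpha, rec$beta, rec$gamma)
    expect_equal(back$A, p$A, tolerance = 1e-9)
    expect_equal(back$B, p$B, tolerance = 1e-9)
    expect_equal(back$C, p$C, tolerance = 1e-9)
  }
  expect_error(recursion_to_whitening(-0.5, 1, 1), "alpha")
  expect_error(recursion_to_whitening(1, 1, 1), "alpha")
})

test_that("GM on exact geometric data: exact difference equations, biased restoration", {
  g <- fit_gm(grey_series(c(2, 1, 0.5, 0.25)))
  expect_equal(g$params$a, 2 / 3, tolerance = 1e-9)
  expect_equal(g$params$b, 8 / 3, tolerance = 1e-9)
  expect_equal(g$recursion_residuals, rep(0, 3), tolerance = 1e-10)
  # restoration bias: (1 - e^(2/3)) * (-2) * e^(-2/3) != 1
  expect_equal(g$simulated[2], (1 - exp(2 / 3)) * (-2) * exp(-2 / 3),
               tolerance = 1e-9)
  expect_gt(abs(g$simulated[2] - 1), 0.02)
  # the restoration bias is nonzero at every index (restored ratio is
  # e^(-2/3) = 0.513.., not the data's 0.5)
  expect_true(all(abs(g$simulated[-1] - c(1, 0.5, 0.25)) > 1e-4))
  expect_error(fit_gm(grey_series(c(1, 2, 3))), "at least 4")
})

test_that("GM degenerates gracefully on constant data", {
  g <- fit_gm(grey_series(c(5, 5, 5, 5)))
  expect_lt(abs(g$params$a), 1e-12)
  expect_equal(g$simulated, rep(5, 4), tolerance = 1e-9)
  expect_equal(tail(simulate_static(g, 1)$values, 1), 5, tolerance = 1e-9)
  expect_match(paste(g$diagnostics, collapse = " "), "degenerate")
})

test_that("DGM is exact on geometric and arithmetic-accumulation data", {
  d <- fit_dgm(grey_series(c(2, 1, 0.5, 0.25)))
  expect_equal(d$params$beta1, 0.5, tolerance = 1e-9)
  expect_equal(d$params$beta2, 2, tolerance = 1e-9)
  expect_equal(d$simulated, c(2, 1, 0.5, 0.25), tolerance = 1e-12)
  expect_equal(tail(simulate_static(d, 1)$values, 1), 0.125, tolerance = 1e-9)

  # recursion-generated data on the accumulated scale, beta1 = 1.1
  x1 <- iterate_recursion(1.1, 0, 3, 5, 6)
  d2 <- fit_dgm(grey_series(iago(x1)))
  expect_equal(d2$params$beta1, 1.1, tolerance = 1e-9)
  expect_equal(d2$params$beta2, 3, tolerance = 1e-9)

  # constant window: accumulated scale is arithmetic, slope-1 recursion exact
  d3 <- fit_dgm(grey_series(c(5, 5, 5, 5)))
  expect_equal(d3$params$beta1, 1, tolerance = 1e-9)
  expect_equal(d3$params$beta2, 5, tolerance = 1e-9)
  expect_equal(tail(simulate_static(d3, 1)$values, 1), 5, tolerance = 1e-9)
})

test_that("IDGM recovers data generated by its own doubly accumulated recursion", {
  # x2 must grow fast enough that both difference passes stay positive
  x2 <- iterate_recursion(2, 0, 1, 1, 8)
  x0 <- iago(iago(x2))
  expect_true(all(x0 > 0))
  f <- fit_idgm(grey_series(x0))
  expect_equal(f$params$beta1, 2, tolerance = 1e-8)
  expect_equal(f$params$beta2, 1, tolerance = 1e-8)
  expect_equal(f$simulated, x0, tolerance = 1e-10)
  expect_lt(f$in_sample_mape, 1e-6)
})

test_that("IDGM is a distinct model class from DNGM and has no exact fit on constants", {
  # x2 of a constant series is quadratic in k, so the first-order
  # recursion cannot interpolate it: the fit is well posed but inexact
  f <- fit_idgm(grey_series(c(3, 3, 3, 3)))
  expect_true(f$well_posed)
  expect_gt(f$in_sample_mape, 0)
  expect_false(isTRUE(all.equal(f$simulated, rep(3, 4))))

  s <- worked_series()
  expect_false(isTRUE(all.equal(fit_idgm(s)$simulated, fit_dngm(s)$simulated)))
})

test_that("DDGM models the raw scale directly", {
  d1 <- fit_ddgm(grey_series(c(2, 1, 0.5, 0.25)))
  expect_equal(d1$params$beta1, 0.5, tolerance = 1e-9)
  expect_equal(d1$params$beta2, 0, tolerance = 1e-9)
  expect_equal(d1$simulated, c(2, 1, 0.5, 0.25), tolerance = 1e-12)

  d2 <- fit_ddgm(grey_series(c(4, 3, 2.5, 2.25)))  # 2 + 2 * 0.5^(k-1)
  expect_equal(d2$params$beta1, 0.5, tolerance = 1e-9)
  expect_equal(d2$params$beta2, 1, tolerance = 1e-9)
  expect_lt(d2$in_sample_mape, 1e-9)

  d3 <- fit_ddgm(grey_series(c(1, 2, 3, 4)))  # arithmetic limit
  expect_equal(d3$params$beta1, 1, tolerance = 1e-9)
  expect_equal(d3$params$beta2, 1, tolerance = 1e-9)

  expect_error(fit_ddgm(grey_series(c(1, 2))), "at least 3")
})

test_that("fitted DNGM restorations minus B/A decay geometrically at rate e^-A", {
  f <- fit_dngm(worked_series(8))
  resid <- f$simulated[-1] - f$whitening$B / f$whitening$A
  expect_equal(resid[-1] / resid[-length(resid)],
               rep(exp(-f$whitening$A), length(resid) - 1), tolerance = 1e-8)
})

test_that("every fit agrees with a Cramer's-rule normal-equations oracle", {
  set.seed(99)
  for (model in c("gm", "dgm", "dngm", "idgm", "ddgm")) {
    for (i in 1:20) {
      s <- rand_window(sample(4:8, 1))
      f <- fit_grey(s, model)
      sys <- oracle_system(model, s$values)
      expect_equal(unname(unlist(f$params)), cramer_lsq(sys$X, sys$y),
                   tolerance = 1e-8,
                   label = sprintf("%s params (draw %d)", model, i))
    }
  }
})

test_that("a negative recursion multiplier forecasts via the recursion alone", {
  # exact recursion with alpha < 0: no whitening form exists, but the
  # fitted recursion still simulates and extrapolates
  x1 <- iterate_recursion(-0.2, 5, 20, 10, 5)
  s <- grey_series(iago(x1))
  f <- fit_dngm(s)
  expect_true(f$well_posed)
  expect_equal(f$params$alpha, -0.2, tolerance = 1e-8)
  expect_null(f$whitening)
  expect_match(paste(f$diagnostics, collapse = " "), "recursion-based")
  ex <- simulate_static(f, 1)
  x1_next <- -0.2 * x1[5] + 5 * 5 + 20
  expect_equal(tail(ex$values, 1), x1_next - x1[5], tolerance = 1e-8)
})

test_that("singular designs are flagged, not fatal, and block simulation", {
  f <- fit_dngm(grey_series(c(5, 5, 5, 5)))  # x1 collinear with (k, 1)
  expect_false(f$well_posed)
  expect_match(paste(f$diagnostics, collapse = " "), "singular")
  expect_equal(f$simulated, rep(5, 4), tolerance = 1e-9)
  expect_error(simulate_static(f, 1), "ill-posed")
  expect_error(simulate_static(fit_dgm(grey_series(c(5, 5, 5, 5))), -1), ">= 0")
})
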