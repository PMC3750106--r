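test_that("an unlabeled feed converges to the unlabeled steady state", {
  fx <- toy_fixture(feed = c("0000" = 1))
  sys <- build_fluxomer_system(fx$network)
  u <- toy_flux_vector(1, 0.5, 0.7)
  ss <- solve_steady_state(u, sys)
  labeled <- sys$index$word != 0L
  expect_lt(max(abs(ss$x[labeled])), 1e-12)
  expect_lt(max(abs(as.numeric(sys$U %*% ss$x) - u[sys$flux_names])),
            1e-9)
})

test_that("a fixed point is stationary under the natural map", {
  sys <- toy_sys()
  u <- toy_flux_vector(1, 0.5, 0.7)[sys$flux_names]
  ss <- solve_steady_state(u, sys)
  x2 <- fixed_point_step(ss$x, u, sys)
  expect_lt(max(abs(x2 - ss$x)), 1e-12)
  # and the Newton correction is zero there
  expect_lt(max(abs(newton_correct(ss$x, u, sys) - ss$x)), 1e-10)
})

test_that("the iterate limit matches the brute-force isotopomer oracle", {
  fx <- toy_net()
  sys <- toy_sys()
  u <- toy_flux_vector(1, 0.5, 0.7)
  ss <- solve_steady_state(u, sys)
  orc <- brute_force_oracle(fx$network, u)
  xo <- oracle_fluxomers(fx$network, u, orc, sys)
  expect_lt(max(abs(ss$x - xo)), 1e-10)
})

test_that("one Newton step contracts the residual near a fixed point", {
  sys <- toy_sys()
  u <- toy_flux_vector(1, 0.5, 0.7)[sys$flux_names]
  ss <- solve_steady_state(u, sys)
  set.seed(11)
  delta <- rnorm(sys$m)
  delta[sys$boundary] <- 0
  x_pert <- ss$x + 1e-3 * delta / max(abs(delta))
  f0 <- max(abs(balance_residual(x_pert, u, sys)))
  x_corr <- newton_correct(x_pert, u, sys)
  f1 <- max(abs(balance_residual(x_corr, u, sys)))
  expect_lt(f1, f0 / 10)
})

test_that("the balance Jacobian matches central finite differences", {
  sys <- toy_sys()
  u <- toy_flux_vector(1, 0.5, 0.7)[sys$flux_names]
  ss <- solve_steady_state(u, sys)
  J <- as.matrix(balance_jacobian_x(ss$x, u, sys))
  h <- 1e-7
  set.seed(3)
  for (j in sample(which(!sys$boundary), 8L)) {
    xp <- ss$x; xp[j] <- xp[j] + h
    xm <- ss$x; xm[j] <- xm[j] - h
    fd <- (balance_residual(xp, u, sys) -
             balance_residual(xm, u, sys)) / (2 * h)
    denom <- pmax(abs(J[, j]), 1e-6)
    expect_lt(max(abs(fd - J[, j]) / denom), 1e-6)
  }
})

test_that("reduced and unreduced solves share the fixed point", {
  u <- toy_flux_vector(1.2, 0.4, 1.1)
  ss_r <- solve_steady_state(u, toy_sys())
  ss_f <- solve_steady_state(u, toy_sys_full(),
                             solver_config(reduced = FALSE))
  expect_lt(max(abs(ss_r$x - ss_f$x)), 1e-10)
})

test_that("pure natural iteration agrees with the hybrid and stays
          nonnegative", {
  u <- toy_flux_vector(1, 0.5, 0.7)
  cfg <- solver_config(use_newton = FALSE, reduced = FALSE,
                       eps_final = 1e-24, max_iter = 200000L)
  sys <- toy_sys_full()
  # track nonnegativity along the raw iteration
  g <- evaluate_g(u[sys$flux_names], sys)
  u_row <- u[sys$flux_names][match(sys$index$flux, sys$flux_names)]
  x <- as.numeric(u_row) * (sys$index$word == 0L)
  x[sys$boundary] <- g[sys$boundary]
  for (i in 1:200) {
    x <- fixed_point_step(x, u[sys$flux_names], sys, g)
    expect_true(all(x >= 0))
  }
  ss_nat <- solve_steady_state(u, sys, cfg)
  ss_newt <- solve_steady_state(u, toy_sys())
  expect_lt(max(abs(ss_nat$x - ss_newt$x)), 1e-9)
})

test_that("the steady state is degree-1 homogeneous in the fluxes", {
  sys <- toy_sys()
  u <- toy_flux_vector(0.8, 0.3, 0.5)
  ss1 <- solve_steady_state(u, sys)
  ss2 <- solve_steady_state(2 * u, sys)
  expect_lt(max(abs(ss2$x - 2 * ss1$x)) / max(ss1$x), 1e-10)
})

test_that("outgoing label fractions agree across a pool's outfluxes", {
  # the uniform-distribution property: B's isotopomer read from f2 and
  # from f5 must coincide, likewise D read from f3 and from f4
  sys <- toy_sys()
  u <- toy_flux_vector(1, 0.5, 0.7)[sys$flux_names]
  ss <- solve_steady_state(u, sys)
  for (w in c("00", "10", "01", "11")) {
    b_f2 <- fluxomer_sum(sys, ss$x, "f2", w) / u[["f2"]]
    b_f5 <- fluxomer_sum(sys, ss$x, "f5", w) / u[["f5"]]
    expect_equal(b_f2, b_f5, tolerance = 1e-9)
    d_f3 <- fluxomer_sum(sys, ss$x, "f3", w) / u[["f3"]]
    d_f4 <- fluxomer_sum(sys, ss$x, "f4",
                         paste0(w, "xx")) / u[["f4"]]
    expect_equal(d_f3, d_f4, tolerance = 1e-9)
  }
})

test_that("flux sensitivities match finite differences and Euler's
          identity", {
  fx <- toy_net()
  sys <- toy_sys()
  u <- toy_flux_vector(1, 0.5, 0.7)[sys$flux_names]
  ss <- solve_steady_state(u, sys)
  P <- flux_jacobian(ss, sys)
  # feasible directions (stay on Su = 0)
  dirs <- list(toy_flux_vector(1, 0, 0), toy_flux_vector(0, 1, 0),
               toy_flux_vector(0, 0, 1))
  h <- 1e-6
  for (d in dirs) {
    d <- d[sys$flux_names]
    xp <- solve_steady_state(u + h * d, sys)$x
    xm <- solve_steady_state(u - h * d, sys)$x
    fd <- (xp - xm) / (2 * h)
    an <- as.numeric(P %*% d)
    expect_lt(max(abs(fd - an)) / max(1, max(abs(an))), 1e-5)
  }
  # Euler identity for the degree-1 homogeneity
  expect_lt(max(abs(as.numeric(P %*% u) - ss$x)) /
              max(abs(ss$x)), 1e-8)
  # fluxes with no labeling path contribute nothing to labeled fluxomers
  fx0 <- toy_fixture(feed = c("0000" = 1))
  sys0 <- build_fluxomer_system(fx0$network)
  ss0 <- solve_steady_state(u, sys0)
  P0 <- flux_jacobian(ss0, sys0)
  labeled <- sys0$index$word != 0L
  expect_lt(max(abs(P0[labeled, ])), 1e-10)
})

test_that("non-convergence raises an informative error", {
  sys <- toy_sys()
  cfg <- solver_config(use_newton = FALSE, max_iter = 2L)
  expect_error(solve_steady_state(toy_flux_vector(1, .5, .7), sys, cfg),
               "did not converge")
})

test_that("solver configuration is validated", {
  expect_error(solver_config(eps_newton = 1e-12, eps_final = 1e-6))
  expect_error(solver_config(max_iter = 0))
})
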