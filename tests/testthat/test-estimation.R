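toy_problem <- function(sigma = 0, seed = 1, ...) {
  ms <- simulate_measurements(toy_net()$network,
                              toy_flux_vector(1, 0.5, 0.7),
                              sigma = sigma, seed = seed,
                              system = toy_sys(), ...)
  flux_problem(toy_net()$network, ms, system = toy_sys())
}

test_that("the initial point is strictly feasible with positive margin", {
  prob <- toy_problem()
  u0 <- initial_point(prob)
  expect_lt(max(abs(prob$S %*% u0[colnames(prob$S)])), 1e-8)
  expect_true(all(u0 > 0))
  expect_gt(attr(u0, "margin"), 0)
  # the regularization pins measured fluxes when lambda stays large
  expect_lt(abs(u0[["f1"]] - 1) / 1, 0.01)
})

test_that("a forced-zero flux narrows the margin to free coordinates", {
  net <- toy_fixture(flux_ub = c(f3 = 0))$network
  # f3 <= 0 forces f3 = 0; everything else keeps a positive margin
  ms <- simulate_measurements(net, toy_flux_vector(1, 0, 0.7),
                              sigma = 0, seed = 1)
  prob <- flux_problem(net, ms)
  u0 <- initial_point(prob)
  expect_equal(unname(u0[["f3"]]), 0)
  expect_gt(min(u0[setdiff(names(u0), "f3")]), 0)
})

test_that("objective gradient matches finite differences", {
  prob <- toy_problem(sigma = 0.002, seed = 3)
  u <- as_flux_vector(toy_flux_vector(1.1, 0.6, 0.5),
                      prob$system)
  ev <- objective_and_gradient(u, prob)
  dirs <- list(toy_flux_vector(1, 0, 0), toy_flux_vector(0, 1, 0),
               toy_flux_vector(0, 0, 1),
               toy_flux_vector(0.3, -0.2, 0.5),
               toy_flux_vector(-0.1, 0.4, 0.2))
  h <- 1e-6
  for (d in dirs) {
    d <- d[prob$system$flux_names]
    fp <- objective_and_gradient(u + h * d, prob)$value
    fm <- objective_and_gradient(u - h * d, prob)$value
    fd <- (fp - fm) / (2 * h)
    an <- sum(ev$gradient * d)
    expect_lt(abs(fd - an) / max(abs(an), 1e-8), 1e-4)
  }
})

test_that("a noiseless self-consistent problem fits to zero at u_true", {
  prob <- toy_problem()
  u_true <- as_flux_vector(toy_flux_vector(1, 0.5, 0.7), prob$system)
  expect_lt(objective_and_gradient(u_true, prob)$value, 1e-10)
  fit <- fia_fit(prob)
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-10)
  # identifiable fluxes recovered (the D/B cycle split f2 - f3 is a
  # structurally flat direction of this network and is excluded)
  for (f in c("f1", "f4", "fout", "f5", "f5r")) {
    expect_lt(abs(fit$u_star[[f]] - u_true[[f]]), 1e-4)
  }
})

test_that("fitting is deterministic", {
  prob1 <- toy_problem(sigma = 0.002, seed = 8)
  fit1 <- fia_fit(prob1)
  prob2 <- toy_problem(sigma = 0.002, seed = 8)
  fit2 <- fia_fit(prob2)
  expect_identical(fit1$u_star, fit2$u_star)
  expect_identical(fit1$objective, fit2$objective)
})

test_that("synthetic recovery lands within a few combined sigma", {
  u_true <- toy_flux_vector(1, 0.5, 0.7)
  ms <- simulate_measurements(toy_net()$network, u_true, sigma = 0.002,
                              seed = 17, system = toy_sys())
  prob <- flux_problem(toy_net()$network, ms, system = toy_sys())
  fit <- fia_fit(prob)
  expect_true(fit$converged)
  for (f in c("f1", "f4", "fout", "f5")) {
    expect_lt(abs(fit$u_star[[f]] - u_true[[f]]), 0.05)
  }
})

test_that("objective and fit are invariant to per-group rescaling", {
  ms <- simulate_measurements(toy_net()$network,
                              toy_flux_vector(1, 0.5, 0.7),
                              sigma = 0.002, seed = 4,
                              system = toy_sys())
  prob <- flux_problem(toy_net()$network, ms, system = toy_sys())
  fit <- fia_fit(prob)
  set.seed(123)
  scaled <- ms
  scaled$groups <- lapply(ms$groups, function(g) {
    g$values <- g$values * runif(1, 0.1, 10)
    g$normalized <- FALSE
    g
  })
  prob2 <- flux_problem(toy_net()$network, scaled, system = toy_sys())
  u_probe <- as_flux_vector(toy_flux_vector(1.2, 0.7, 0.4),
                            prob$system)
  v1 <- objective_and_gradient(u_probe, prob)$value
  v2 <- objective_and_gradient(u_probe, prob2)$value
  expect_lt(abs(v1 - v2) / max(v1, 1e-12), 1e-10)
  fit2 <- fia_fit(prob2)
  expect_lt(max(abs(fit2$u_star - fit$u_star)) /
              max(abs(fit$u_star)), 1e-6)
})

test_that("feasibility and monotone objective hold along the outer
          path", {
  prob <- toy_problem(sigma = 0.002, seed = 6)
  fit <- fia_fit(prob)
  expect_lt(max(abs(prob$S %*% fit$u_star[colnames(prob$S)])), 1e-9)
  expect_true(all(fit$u_star >= 0))
  expect_true(all(fit$u_star <= prob$u_ub + 1e-9))
  if (nrow(fit$trace) > 1L) {
    expect_true(all(diff(fit$trace$objective) <= 1e-14))
  }
})

test_that("a missing scale anchor is rejected up front", {
  ms <- simulate_measurements(toy_net()$network,
                              toy_flux_vector(1, 0.5, 0.7),
                              sigma = 0, system = toy_sys())
  ms_nofl <- measurement_set(ms$groups)
  expect_error(flux_problem(toy_net()$network, ms_nofl,
                            system = toy_sys()),
               "scale")
})

test_that("noise study is seeded, reproducible, and collapses at
          sigma 0", {
  prob <- toy_problem()
  base <- fia_fit(prob)
  n1 <- noise_study(prob, sigma = 0.002, n_reps = 3L, seed = 21,
                    base_fit = base)
  n2 <- noise_study(prob, sigma = 0.002, n_reps = 3L, seed = 21,
                    base_fit = base)
  expect_identical(attr(n1, "replicates"), attr(n2, "replicates"))
  n0 <- noise_study(prob, sigma = 0, n_reps = 2L, seed = 21,
                    base_fit = base)
  reps <- attr(n0, "replicates")
  for (f in c("f1", "f4", "fout", "f5")) {
    expect_lt(max(abs(reps[, f] - base$u_star[[f]])), 1e-6)
  }
})

test_that("tidiers and plots carry the fit content", {
  cached <- empp_fit_cached()
  td <- tidy(cached$fit)
  expect_equal(td$flux, names(cached$fit$u_star))
  gl <- glance(cached$fit)
  expect_true(gl$converged)
  p1 <- autoplot(cached$fit)
  expect_s3_class(p1, "ggplot")
  fm <- fitted_measurements(cached$fit)
  expect_true(all(is.finite(fm$predicted)))
  expect_equal(nrow(fm), 15L)  # 5 + 4 + 3 + 3 label rows
})
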