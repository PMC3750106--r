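toy_steady <- function() {
  u <- toy_flux_vector(1, 0.5, 0.7)
  list(u = u, ss = solve_steady_state(u, toy_sys()))
}

test_that("group transforms sum the documented fluxomer sets", {
  sys <- toy_sys()
  # positional enrichment on a 2-atom pool: #1x = atom 1 labeled
  g <- label_group("NMR-1H", "B", specs = c("#1x", "#x1"),
                   values = c(0.3, 0.1), sd = 0.002)
  tr <- build_group_transform(g, sys)
  expect_equal(tr$reporter, "f2")  # first declared consumer
  expect_equal(which(as.numeric(tr$T[1, ]) > 0),
               sort(fluxomer_rows(sys, "f2", "1x")))
  # M0 of a 2-atom fragment is the single all-unlabeled word
  gms <- label_group("MS", "B", specs = 0:2,
                     values = c(.5, .3, .2), sd = 0.002)
  trms <- build_group_transform(gms, sys)
  expect_equal(which(as.numeric(trms$T[1, ]) > 0),
               fluxomer_rows(sys, "f2", "00"))
  expect_equal(Matrix::rowSums(trms$T), c(1, 2, 1))
  # MS fragment atoms must lie inside the pool
  bad <- label_group("MS", "B", specs = 0:1, values = c(.5, .5),
                     sd = 0.002, atoms = c(1, 3))
  expect_error(build_group_transform(bad, sys), "subset")
})

test_that("the reporter choice is immaterial at steady state", {
  st <- toy_steady()
  sys <- toy_sys()
  frac <- isotopomer_fractions(st$ss, sys, pools = "B")$B
  # read B through each of its consumers by hand
  for (consumer in c("f2", "f5")) {
    rows <- which(sys$index$flux == consumer)
    sub <- sys$index$word[rows]
    pred <- as.numeric(rowsum(st$ss$x[rows], sub)) /
      sum(st$ss$x[rows])
    expect_lt(max(abs(pred - unname(frac))), 1e-9)
  }
})

test_that("residuals vanish when measurements equal model fractions", {
  st <- toy_steady()
  sys <- toy_sys()
  ms <- simulate_measurements(toy_net()$network, st$u, sigma = 0,
                              system = sys)
  model <- assemble_objective(ms, sys)
  r <- model_residuals(model, st$ss$x)
  expect_lt(max(abs(r)), 1e-8)
})

test_that("the objective only sees relative intensities within a group", {
  st <- toy_steady()
  sys <- toy_sys()
  ms <- simulate_measurements(toy_net()$network, st$u, sigma = 0.002,
                              seed = 5, system = sys)
  model <- assemble_objective(ms, sys)
  base <- sum(model_residuals(model, st$ss$x)^2)
  set.seed(99)
  scaled <- ms
  scaled$groups <- lapply(ms$groups, function(g) {
    g$values <- g$values * runif(1, 0.2, 5)
    g$normalized <- FALSE
    g
  })
  model2 <- assemble_objective(scaled, sys)
  expect_lt(abs(sum(model_residuals(model2, st$ss$x)^2) - base) /
              base, 1e-10)
})

test_that("dropping a row of a group still yields finite residuals", {
  st <- toy_steady()
  sys <- toy_sys()
  g <- label_group("MS", "E", specs = 0:4,
                   values = c(.4, .3, .2, .07, .03), sd = 0.002)
  g_partial <- label_group("MS", "E", specs = 0:2,
                           values = c(.4, .3, .2), sd = 0.002,
                           normalized = FALSE)
  for (gg in list(g, g_partial)) {
    ms <- measurement_set(list(gg),
                          tibble::tibble(flux = "f1", value = 1,
                                         sd = 0.001))
    model <- assemble_objective(ms, sys)
    r <- model_residuals(model, st$ss$x)
    expect_true(all(is.finite(r)))
  }
})

test_that("natural-abundance correction reduces to known cases", {
  expect_equal(natural_abundance_correction("", 3), diag(3))
  # one extra carbon: columns are the shifted binomial (1-p, p)
  p <- 0.0107
  C1 <- natural_abundance_correction("C1", 3)
  expect_equal(C1[, 1], c(1 - p, p, 0))
  expect_equal(C1[, 2], c(0, 1 - p, p))
  # n extra carbons against a direct binomial enumeration oracle
  for (n in c(2, 5)) {
    Cn <- natural_abundance_correction(paste0("C", n), n + 1)
    expect_equal(Cn[, 1], dbinom(0:n, n, p))
  }
  # probability-mass structure for a realistic silylated fragment
  Cm <- natural_abundance_correction("C11H26NO2Si2", 4, n_backbone = 3)
  expect_true(all(Cm >= 0))
  expect_true(all(colSums(Cm) <= 1 + 1e-12))
  expect_true(all(Cm[upper.tri(Cm)] == 0))
  expect_error(natural_abundance_correction("C2Xx3", 3),
               "unknown element")
  expect_error(natural_abundance_correction("C2", 3, n_backbone = 4),
               "fewer carbons")
})

test_that("correction by a formula shifts MS predictions as a
          convolution", {
  st <- toy_steady()
  sys <- toy_sys()
  g_raw <- label_group("MS", "B", specs = 0:2, values = c(.6, .3, .1),
                       sd = .002)
  g_cor <- label_group("MS", "B", specs = 0:2, values = c(.6, .3, .1),
                       sd = .002, formula = "C3H7O2")
  t_raw <- build_group_transform(g_raw, sys)
  t_cor <- build_group_transform(g_cor, sys)
  Cm <- natural_abundance_correction("C3H7O2", 3, n_backbone = 2)
  expect_lt(max(abs(as.matrix(t_cor$T) - Cm %*% as.matrix(t_raw$T))),
            1e-12)
})

test_that("the assembled objective has b = 0 except for flux rows", {
  model <- empp_fit_cached()$problem$model
  nlab <- sum(model$info$type == "label")
  expect_true(all(model$b[seq_len(nlab)] == 0))
  expect_true(any(model$b[-seq_len(nlab)] != 0))
  expect_equal(model$info$pool[model$info$type == "flux"], "upt")
})

test_that("group order does not change the objective", {
  st <- toy_steady()
  sys <- toy_sys()
  ms <- simulate_measurements(toy_net()$network, st$u, sigma = 0.002,
                              seed = 2, system = sys)
  m1 <- assemble_objective(ms, sys)
  ms_perm <- measurement_set(rev(ms$groups), ms$fluxes)
  m2 <- assemble_objective(ms_perm, sys)
  expect_equal(sum(model_residuals(m1, st$ss$x)^2),
               sum(model_residuals(m2, st$ss$x)^2), tolerance = 1e-12)
})

test_that("no measurements at all is rejected as unidentifiable", {
  expect_error(assemble_objective(measurement_set(), toy_sys()),
               "unidentifiable")
})
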