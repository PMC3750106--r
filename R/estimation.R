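#' Set up a flux estimation problem
#'
#' Bundles the network, the fluxomer system, the measurement residual
#' model and the feasible flux polytope Q = {u : S u = 0, 0 <= u <= ub}.
#' At least one absolute flux measurement is required: steady-state
#' labeling is degree-0 homogeneous in the fluxes, so label data alone
#' cannot identify the scale.
#'
#' @param network a [flux_network()].
#' @param measurements a [measurement_set()].
#' @param system optionally a prebuilt `fluxomer_system` (built, with LU
#'   reduction, when omitted).
#' @param correction,cov_weighting passed to [assemble_objective()].
#' @param lambda_init initial regularization weight of the interior-point
#'   search (see [initial_point()]).
#' @return a `flux_problem` object.
#' @export
flux_problem <- function(network, measurements, system = NULL,
                         correction = TRUE, cov_weighting = FALSE,
                         lambda_init = 1e3) {
  if (is.null(system)) system <- build_fluxomer_system(network)
  if (nrow(measurements$fluxes) == 0L) {
    stop("at least one absolute flux measurement is required: labeling ",
         "ratios cannot identify the flux scale", call. = FALSE)
  }
  model <- assemble_objective(measurements, system,
                              correction = correction,
                              cov_weighting = cov_weighting)
  structure(list(network = network, system = system, model = model,
                 measurements = measurements,
                 S = build_stoichiometry(network),
                 u_ub = network$flux_ub,
                 lambda_init = lambda_init,
                 cache = new.env(parent = emptyenv())),
            class = "flux_problem")
}

#' Feasible, interior initial flux vector
#'
#' Solves the convex program
#' max_{u, s} s - lambda ||(u_meas - u_hat) / sd||^2 subject to S u = 0,
#' u >= s, ub - u >= s (margin applied to the free coordinates only),
#' halving lambda until the optimal margin s* is positive. The
#' regularization pulls the start toward the measured fluxes; the margin
#' keeps it strictly inside the polytope so the rational prefactor g(u)
#' is well defined.
#'
#' @param problem a [flux_problem()].
#' @param lambda starting regularization weight.
#' @return named flux vector u0 with attributes `margin` and `lambda`.
#' @export
initial_point <- function(problem, lambda = problem$lambda_init) {
  n <- problem$system$n
  S <- problem$S
  ub <- as.numeric(problem$u_ub)
  fixed <- ub <= 1e-12
  free <- which(!fixed)
  fl <- problem$measurements$fluxes
  Af <- NULL; uhat <- NULL; wf <- NULL
  if (nrow(fl) > 0L) {
    Af <- matrix(0, nrow(fl), n)
    Af[cbind(seq_len(nrow(fl)),
             match(fl$flux, problem$system$flux_names))] <- 1
    uhat <- fl$value
    wf <- 1 / fl$sd
  }
  ridge <- 1e-8
  smax <- max(ub) / 2
  repeat {
    # variables z = (u, s)
    H <- diag(ridge, n + 1L)
    d <- c(numeric(n), -1)
    if (!is.null(Af)) {
      AW <- Af * wf
      H[1:n, 1:n] <- H[1:n, 1:n] + 2 * lambda * crossprod(AW)
      d[1:n] <- d[1:n] - 2 * lambda * as.numeric(crossprod(AW, wf * uhat))
    }
    Aeq <- cbind(S, 0)
    Ain <- rbind(cbind(-diag(n)[free, , drop = FALSE], 1),
                 cbind(diag(n)[free, , drop = FALSE], 1))
    bin <- c(numeric(length(free)), ub[free])
    sol <- pracma::quadprog(H, d, A = Ain, b = bin,
                            Aeq = Aeq, beq = numeric(nrow(Aeq)),
                            lb = c(numeric(n), -max(ub)),
                            ub = c(ub, smax))
    s_star <- sol$xmin[n + 1L]
    if (s_star > 1e-9 || lambda < 1e-9) break
    lambda <- lambda / 2
  }
  if (s_star <= 1e-9) {
    if (length(free) == 0L || all(abs(sol$xmin[1:n]) < 1e-9)) {
      stop("ill-structured network: no strictly feasible flux vector ",
           "exists in Q", call. = FALSE)
    }
  }
  u0 <- stats::setNames(pmax(sol$xmin[1:n], 0), problem$system$flux_names)
  attr(u0, "margin") <- s_star
  attr(u0, "lambda") <- lambda
  u0
}

#' Objective value and gradient of the flux estimation problem
#'
#' value = ||A x(u) - b||^2 with x(u) the steady-state fluxomers;
#' gradient = 2 (A dx/du)^T (A x(u) - b) via the implicit-function
#' sensitivities. Steady-state solves warm-start from the previous call
#' on the same problem.
#'
#' @param u strictly feasible flux vector.
#' @param problem a [flux_problem()].
#' @param config solver configuration for the inner solves.
#' @param want_jacobian also return the residual Jacobian J = A dx/du
#'   (used by the sequential least-squares outer loop).
#' @return list with `value`, `gradient`, `residuals`, and optionally
#'   `jacobian` and the `steady_state`.
#' @export
objective_and_gradient <- function(u, problem, config = solver_config(),
                                   want_jacobian = FALSE) {
  u <- as_flux_vector(u, problem$system)
  ss <- solve_steady_state(u, problem$system, config,
                           y0 = problem$cache$y_warm)
  problem$cache$y_warm <- ss$y
  r <- model_residuals(problem$model, ss$x)
  P <- flux_jacobian(ss, problem$system)
  J <- as.matrix(problem$model$A %*% P)
  out <- list(value = sum(r^2),
              gradient = as.numeric(2 * crossprod(J, r)),
              residuals = r, steady_state = ss)
  if (want_jacobian) out$jacobian <- J
  out
}

#' Estimate metabolic fluxes from labeling measurements
#'
#' Minimizes the scaling-invariant measurement objective over the flux
#' polytope by deterministic sequential least squares: each outer
#' iteration linearizes the residual at the current iterate and solves a
#' damped, equality- and box-constrained quadratic subproblem
#' (`pracma::quadprog`), accepting steps that decrease the true
#' objective and inflating the damping otherwise. There is no random
#' restart; the run is fully reproducible.
#'
#' @param problem a [flux_problem()].
#' @param u0 starting flux vector (default [initial_point()]).
#' @param config inner solver configuration.
#' @param max_outer outer iteration cap.
#' @param tol_obj stop when the relative objective decrease falls below
#'   this and the step is small.
#' @param tol_u step-size tolerance, relative to 1 + max|u|.
#' @param interior_eps fluxes are kept at or above this value during
#'   inner solves.
#' @param quiet suppress per-iteration messages.
#' @return a `fia_fit` object with entries `u_star`, `x_star`,
#'   `objective`, `iterations`, `converged`, `trace`.
#' @export
fia_fit <- function(problem, u0 = NULL, config = solver_config(),
                    max_outer = 500L, tol_obj = 1e-9, tol_u = 1e-8,
                    interior_eps = 1e-9, quiet = TRUE) {
  sysm <- problem$system
  n <- sysm$n
  S <- problem$S
  ub <- as.numeric(problem$u_ub)
  if (is.null(u0)) u0 <- initial_point(problem)
  u <- pmin(pmax(as_flux_vector(u0, sysm), interior_eps), ub)
  # re-project onto Su = 0 in case clipping moved u off the constraint
  u <- project_onto_null(u, S, ub, interior_eps)
  ev <- objective_and_gradient(u, problem, config, want_jacobian = TRUE)
  radius <- 0.25 * (1 + max(abs(u)))
  ridge <- 1e-8
  trace <- list()
  converged <- FALSE
  iter <- 0L
  while (iter < max_outer) {
    iter <- iter + 1L
    J <- ev$jacobian
    r <- ev$residuals
    Hq <- 2 * (crossprod(J) + diag(ridge * (1 + sum(J^2) / n), n))
    dq <- 2 * as.numeric(crossprod(J, r))
    accepted <- FALSE
    for (try in 1:20) {
      lb_step <- pmax(-u + interior_eps, -radius)
      ub_step <- pmin(ub - u, radius)
      sol <- tryCatch(
        pracma::quadprog(Hq, dq, Aeq = S, beq = numeric(nrow(S)),
                         lb = lb_step, ub = ub_step),
        error = function(e) NULL)
      if (is.null(sol)) { radius <- radius / 3; next }
      step <- sol$xmin
      pred_dec <- -(sum(dq * step) +
                      as.numeric(t(step) %*% (Hq %*% step)) / 2)
      ucand <- u + step
      ev_cand <- tryCatch(
        objective_and_gradient(ucand, problem, config,
                               want_jacobian = TRUE),
        error = function(e) NULL)
      if (!is.null(ev_cand)) {
        act_dec <- ev$value - ev_cand$value
        rho <- act_dec / max(pred_dec, 1e-300)
        if (act_dec >= 0) {
          accepted <- TRUE
          # grow the region when the model was good and the step bound
          # was active
          if (rho > 0.75 && max(abs(step)) > 0.9 * radius) {
            radius <- radius * 2
          } else if (rho < 0.25) {
            radius <- radius / 2
          }
          break
        }
      }
      radius <- radius / 3
      if (radius < 1e-14 * (1 + max(abs(u)))) break
    }
    if (!accepted) {
      # no trust-region step decreases the objective: numerical floor
      converged <- TRUE
      break
    }
    rel_dec <- (ev$value - ev_cand$value) / max(ev$value, 1e-30)
    step_inf <- max(abs(step))
    if (!quiet) {
      message(sprintf("outer %3d: obj %.6e -> %.6e, step %.3e, radius %.1e",
                      iter, ev$value, ev_cand$value, step_inf, radius))
    }
    u <- ucand
    ev <- ev_cand
    trace[[iter]] <- c(iter = iter, objective = ev$value,
                       step = step_inf, radius = radius)
    if (rel_dec < tol_obj && step_inf < tol_u * (1 + max(abs(u)))) {
      converged <- TRUE
      break
    }
  }
  structure(list(u_star = stats::setNames(u, sysm$flux_names),
                 x_star = ev$steady_state$x,
                 steady_state = ev$steady_state,
                 objective = ev$value,
                 gradient = ev$gradient,
                 iterations = iter,
                 inner_iterations = ev$steady_state$iterations,
                 converged = converged,
                 trace = if (length(trace) > 0L) {
                   tibble::as_tibble(do.call(rbind, trace))
                 } else tibble::tibble(),
                 problem = problem),
            class = "fia_fit")
}

# small ridge QP to restore Su = 0 after clipping
project_onto_null <- function(u, S, ub, interior_eps) {
  if (max(abs(S %*% u)) < 1e-12) return(u)
  n <- length(u)
  sol <- pracma::quadprog(diag(2, n), -2 * as.numeric(u),
                          Aeq = S, beq = numeric(nrow(S)),
                          lb = rep(interior_eps, n), ub = ub)
  stats::setNames(sol$xmin, names(u))
}

#' @export
print.fia_fit <- function(x, ...) {
  cat("<fia_fit> objective", format(x$objective, digits = 6),
      if (x$converged) "(converged)" else "(NOT converged)",
      "after", x$iterations, "outer iterations\n")
  print(round(x$u_star, 4))
  invisible(x)
}

#' Noise-robustness study of a flux fit
#'
#' Re-fits the problem under seeded Gaussian perturbations of the label
#' measurements and reports the per-flux spread of the estimates. Flux
#' measurements are left unperturbed. Replicates that fail to converge
#' are recorded and excluded from the moments.
#'
#' @param problem a [flux_problem()].
#' @param sigma noise standard deviation added to each label value
#'   (fraction scale).
#' @param n_reps number of replicates.
#' @param seed integer seed; same seed, same table.
#' @param base_fit optionally the noiseless [fia_fit()] (computed when
#'   omitted); replicates warm-start from its optimum.
#' @param config,max_outer passed to the re-fits.
#' @return a `fia_noise_study`: a tibble with per-flux mean, sd, var and
#'   mse (against the base estimate), with the replicate estimates in
#'   `attr(, "replicates")`.
#' @export
noise_study <- function(problem, sigma, n_reps = 10L, seed = 1L,
                        base_fit = NULL, config = solver_config(),
                        max_outer = 500L) {
  if (is.null(base_fit)) base_fit <- fia_fit(problem, config = config)
  rng <- local_rng(seed)
  est <- matrix(NA_real_, n_reps, problem$system$n,
                dimnames = list(NULL, problem$system$flux_names))
  failed <- integer(0)
  for (rep in seq_len(n_reps)) {
    ms <- problem$measurements
    groups <- lapply(ms$groups, function(g) {
      g$values <- g$values + rng$rnorm(length(g$values), 0, sigma)
      g
    })
    ms_noisy <- measurement_set(groups = groups, fluxes = ms$fluxes)
    prob_rep <- flux_problem(problem$network, ms_noisy,
                             system = problem$system,
                             correction = problem$model$correction,
                             cov_weighting = problem$model$cov_weighting)
    fit_rep <- tryCatch(
      fia_fit(prob_rep, u0 = base_fit$u_star, config = config,
              max_outer = max_outer),
      error = function(e) NULL)
    if (is.null(fit_rep) || !fit_rep$converged) {
      failed <- c(failed, rep)
    } else {
      est[rep, ] <- fit_rep$u_star
    }
  }
  ok <- setdiff(seq_len(n_reps), failed)
  tab <- tibble::tibble(
    flux = problem$system$flux_names,
    base = as.numeric(base_fit$u_star),
    mean = colMeans(est[ok, , drop = FALSE]),
    sd = apply(est[ok, , drop = FALSE], 2, stats::sd),
    var = apply(est[ok, , drop = FALSE], 2, stats::var),
    mse = colMeans((est[ok, , drop = FALSE] -
                      matrix(base_fit$u_star, length(ok),
                             ncol(est), byrow = TRUE))^2),
    n_ok = length(ok)
  )
  structure(tab, class = c("fia_noise_study", class(tab)),
            replicates = est, failed = failed, sigma = sigma, seed = seed)
}
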