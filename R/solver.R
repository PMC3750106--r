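#' Solver configuration for the steady-state labeling solve
#'
#' @param eps_newton threshold on the (squared, by default) step change
#'   above which a Newton correction follows each propagation step.
#' @param eps_final convergence threshold on the step change.
#' @param max_iter iteration cap.
#' @param newton_first number of leading iterations that always take a
#'   Newton correction.
#' @param metric step-change metric: `"l2sq"` (squared Euclidean norm of
#'   the change in the working coordinates) or `"max"` (largest absolute
#'   coordinate change).
#' @param reduced use the LU-reduced coordinates when the system carries a
#'   valid factorization.
#' @param use_newton set `FALSE` for the plain "natural" fixed-point
#'   iteration with no corrections.
#' @return a `solver_config` list.
#' @export
solver_config <- function(eps_newton = 1e-6, eps_final = 1e-12,
                          max_iter = 5000L, newton_first = 2L,
                          metric = c("l2sq", "max"),
                          reduced = TRUE, use_newton = TRUE) {
  metric <- match.arg(metric)
  stopifnot(eps_final > 0, eps_newton > eps_final, max_iter >= 1L)
  structure(list(eps_newton = eps_newton, eps_final = eps_final,
                 max_iter = as.integer(max_iter),
                 newton_first = as.integer(newton_first),
                 metric = metric, reduced = isTRUE(reduced),
                 use_newton = isTRUE(use_newton)),
            class = "solver_config")
}

#' Evaluate the rational flux prefactor g(u)
#'
#' g_i = (G1 u)_i / ((G2 u)_i (G3 u)_i), the flux-dependent coefficient of
#' the trilinear steady-state relation. Fluxomers whose own flux is
#' (numerically) zero get g = 0; a pool that is fed but has zero total
#' outflux raises a singular-g error naming the pool.
#'
#' @param u named flux vector (length n, order of `system$flux_names`).
#' @param system a `fluxomer_system`.
#' @return numeric vector of length m.
#' @export
evaluate_g <- function(u, system) {
  u <- as.numeric(u)
  stopifnot(length(u) == system$n)
  tiny <- 1e-12 * max(1, max(abs(u)))
  # a fed pool with zero total outflux cannot be at steady state and
  # would make the prefactor singular downstream: report it by name
  network <- system$network
  for (p in network$pools$name[network$pools$role == "intermediate"]) {
    outflux <- sum(u[match(pool_consumers(network, p),
                           system$flux_names)])
    if (outflux > tiny) next
    inflow <- sum(vapply(pool_producers(network, p), function(pr)
      u[match(pr$flux, system$flux_names)], numeric(1)))
    if (inflow > tiny) {
      stop("singular g(u): pool '", p,
           "' has zero total outflux while carrying inflow ",
           format(inflow), call. = FALSE)
    }
  }
  a <- as.numeric(system$G1 %*% u)
  b <- as.numeric(system$G2 %*% u) + system$g2c
  cc <- as.numeric(system$G3 %*% u) + system$g3c
  # fluxomers of (numerically) zero fluxes are dead: their pools may
  # have zero outflux without harm
  dead <- (b <= tiny | cc <= tiny)
  g <- numeric(system$m)
  ok <- !dead
  g[ok] <- a[ok] / (b[ok] * cc[ok])
  g
}

# propagation operators in the configured coordinates
solver_ops <- function(system, config) {
  if (config$reduced && !is.null(system$lu) && isTRUE(system$lu$ok)) {
    list(L1 = system$lu$L1, L2 = system$lu$L2, UH = system$lu$UH,
         reduced = TRUE)
  } else {
    list(L1 = system$H1, L2 = system$H2, UH = NULL, reduced = FALSE)
  }
}

#' One "natural" fixed-point step of the fluxomer propagation
#'
#' Applies x_next = g(u) o (H1 x) o (H2 x) in fluxomer coordinates.
#' Boundary (input-substrate) fluxomers are constant under the map, which
#' is how the feed labeling is clamped.
#'
#' @param x fluxomer vector (length m).
#' @param u flux vector.
#' @param system a `fluxomer_system`.
#' @param g optionally a precomputed [evaluate_g()] vector.
#' @return the propagated fluxomer vector.
#' @export
fixed_point_step <- function(x, u, system, g = NULL) {
  if (is.null(g)) g <- evaluate_g(u, system)
  g * (as.numeric(system$H1 %*% x) + system$h1c) *
    (as.numeric(system$H2 %*% x) + system$h2c)
}

#' Residual of the steady-state fluxomer balance
#'
#' F(x, u) = g(u) o (H1 x) o (H2 x) - x; its root is the steady state.
#'
#' @inheritParams fixed_point_step
#' @return numeric vector of length m.
#' @export
balance_residual <- function(x, u, system, g = NULL) {
  fixed_point_step(x, u, system, g) - x
}

#' Jacobian of the balance residual in the fluxomers
#'
#' F'_x = D(g o H1 x) H2 + D(g o H2 x) H1 - I with D() the diagonal
#' operator; boundary rows reduce to -I because their source rows are
#' constant.
#'
#' @inheritParams fixed_point_step
#' @return a sparse m-by-m matrix.
#' @export
balance_jacobian_x <- function(x, u, system, g = NULL) {
  if (is.null(g)) g <- evaluate_g(u, system)
  l1 <- as.numeric(system$H1 %*% x) + system$h1c
  l2 <- as.numeric(system$H2 %*% x) + system$h2c
  Matrix::Diagonal(x = g * l1) %*% system$H2 +
    Matrix::Diagonal(x = g * l2) %*% system$H1 -
    Matrix::Diagonal(system$m)
}

#' Newton correction of a fluxomer iterate
#'
#' Solves F'_x(x, u) r = F(x, u) and returns x - r. If the Jacobian is
#' singular the iterate is returned unchanged with a warning (the caller
#' falls back to plain fixed-point stepping).
#'
#' @inheritParams fixed_point_step
#' @return the corrected fluxomer vector.
#' @export
newton_correct <- function(x, u, system, g = NULL) {
  if (is.null(g)) g <- evaluate_g(u, system)
  J <- balance_jacobian_x(x, u, system, g)
  Fv <- balance_residual(x, u, system, g)
  r <- tryCatch(as.numeric(Matrix::solve(J, Fv)),
                error = function(e) {
                  warning("singular balance Jacobian; skipping Newton ",
                          "correction", call. = FALSE)
                  NULL
                })
  if (is.null(r)) x else x - r
}

#' Solve the steady-state fluxomer balance equations
#'
#' Runs the hybrid Newton/fixed-point iteration of the fluxomer method,
#' by default in the LU-reduced coordinates y = UH x: starting from the
#' boundary-only labeling, each pass propagates
#' y <- UH (g(u) o (L1 y) o (L2 y)) and, while the step change exceeds
#' `eps_newton` (or during the first `newton_first` passes), follows with
#' a Newton correction solved on the reduced Jacobian. Iteration stops
#' when the step change drops below `eps_final`.
#'
#' @param u named or ordered flux vector (nonnegative, stoichiometrically
#'   balanced).
#' @param system a `fluxomer_system`.
#' @param config a [solver_config()].
#' @param y0 optional warm-start working coordinates from a previous solve
#'   at nearby fluxes.
#' @return a `steady_state` object: fluxomer vector `x` (named
#'   `flux(label)`), working coordinates `y`, `iterations`,
#'   `newton_steps`, `final_change`, and the flux vector `u`.
#' @export
solve_steady_state <- function(u, system, config = solver_config(),
                               y0 = NULL) {
  u <- as_flux_vector(u, system)
  g <- evaluate_g(u, system)
  ops <- solver_ops(system, config)
  propagate <- function(y) {
    x1 <- as.numeric(ops$L1 %*% y) + system$h1c
    x2 <- as.numeric(ops$L2 %*% y) + system$h2c
    phi <- g * x1 * x2
    if (ops$reduced) as.numeric(ops$UH %*% phi) else phi
  }
  newton_y <- function(y) {
    x1 <- as.numeric(ops$L1 %*% y) + system$h1c
    x2 <- as.numeric(ops$L2 %*% y) + system$h2c
    Fy <- {
      phi <- g * x1 * x2
      (if (ops$reduced) as.numeric(ops$UH %*% phi) else phi) - y
    }
    Jin <- Matrix::Diagonal(x = g * x1) %*% ops$L2 +
      Matrix::Diagonal(x = g * x2) %*% ops$L1
    J <- (if (ops$reduced) ops$UH %*% Jin else Jin) -
      Matrix::Diagonal(system$m)
    r <- tryCatch(as.numeric(Matrix::solve(J, Fy)),
                  error = function(e) NULL)
    if (is.null(r)) y else y - r
  }
  # start from the unlabeled steady state: each flux carries its full
  # value on the all-zero label word. This start satisfies the partition
  # closure U x = u, which the natural map preserves exactly and which
  # singles out the physical root of the trilinear system.
  u_row <- u[match(system$index$flux, system$flux_names)]
  x0 <- as.numeric(u_row) * (system$index$word == 0L)
  x0[system$boundary] <- g[system$boundary]
  y <- if (!is.null(y0)) y0
       else if (ops$reduced) as.numeric(ops$UH %*% x0) else x0
  change <- Inf
  prev_change <- Inf
  newton_steps <- 0L
  iter <- 0L
  while (iter < config$max_iter) {
    iter <- iter + 1L
    ynew <- propagate(y)
    change <- step_change(ynew, y, config$metric)
    # Newton while the step change is large, plus a stall guard: if the
    # plain propagation is contracting slowly (spectral radius near 1,
    # as happens with strongly exchanging reversible pairs), keep
    # correcting rather than crawling to the tolerance
    stalled <- change > config$eps_final &&
      is.finite(prev_change) && change > 0.09 * prev_change
    if (config$use_newton &&
        (iter <= config$newton_first || change > config$eps_newton ||
         stalled)) {
      ycorr <- newton_y(ynew)
      newton_steps <- newton_steps + 1L
      change <- step_change(ycorr, y, config$metric)
      ynew <- ycorr
    }
    prev_change <- change
    y <- ynew
    if (change <= config$eps_final) break
  }
  if (change > config$eps_final) {
    stop("steady-state solve did not converge in ", config$max_iter,
         " iterations (last step change ", format(change), ")",
         call. = FALSE)
  }
  x <- g * (as.numeric(ops$L1 %*% y) + system$h1c) *
    (as.numeric(ops$L2 %*% y) + system$h2c)
  names(x) <- paste0(system$index$flux, "(", system$index$label, ")")
  structure(list(x = x, y = y, u = u, iterations = iter,
                 newton_steps = newton_steps, final_change = change,
                 reduced = ops$reduced),
            class = "steady_state")
}

step_change <- function(ynew, y, metric) {
  if (metric == "l2sq") sum((ynew - y)^2) else max(abs(ynew - y))
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state> m =", length(x$x), "fluxomers;",
      x$iterations, "iterations (", x$newton_steps, "Newton ),",
      "final step change", format(x$final_change), "\n")
  invisible(x)
}

#' Flux sensitivities of the steady-state fluxomers
#'
#' Computes dx/du at a converged steady state via the implicit function
#' theorem: F'_x (dx/du) = -F'_u, with F'_u obtained by quotient-rule
#' differentiation of the rational prefactor g(u).
#'
#' @param steady_state a converged [solve_steady_state()] result.
#' @param system the `fluxomer_system` used for the solve.
#' @param u optionally the flux vector (defaults to the one recorded in
#'   the steady state).
#' @return a dense m-by-n matrix with fluxomer rows and flux columns.
#' @export
flux_jacobian <- function(steady_state, system, u = NULL) {
  if (is.null(u)) u <- steady_state$u
  u <- as_flux_vector(u, system)
  x <- as.numeric(steady_state$x)
  g <- evaluate_g(u, system)
  a <- as.numeric(system$G1 %*% u)
  b <- as.numeric(system$G2 %*% u) + system$g2c
  cc <- as.numeric(system$G3 %*% u) + system$g3c
  l1 <- as.numeric(system$H1 %*% x) + system$h1c
  l2 <- as.numeric(system$H2 %*% x) + system$h2c
  live <- b > 0 & cc > 0
  s <- numeric(system$m); s[live] <- l1[live] * l2[live] / (b * cc)[live]
  s2 <- numeric(system$m); s2[live] <- (a * l1 * l2 / (b^2 * cc))[live]
  s3 <- numeric(system$m); s3[live] <- (a * l1 * l2 / (b * cc^2))[live]
  Fu <- Matrix::Diagonal(x = s) %*% system$G1 -
    Matrix::Diagonal(x = s2) %*% system$G2 -
    Matrix::Diagonal(x = s3) %*% system$G3
  if (!is.null(system$lu) && isTRUE(system$lu$ok)) {
    # reduced-space solve: with H = L UH the balance Jacobian factors as
    # F'_x = (D1 L2 + D2 L1) UH - I, so substituting Q = UH P turns
    # F'_x P = -F'_u into the sparse system (UH B - I) Q = -UH F'_u
    # followed by the (permuted-triangular) solve UH P = Q
    L1 <- system$lu$L1; L2 <- system$lu$L2; UH <- system$lu$UH
    l1 <- as.numeric(system$H1 %*% x) + system$h1c
    l2 <- as.numeric(system$H2 %*% x) + system$h2c
    B <- Matrix::Diagonal(x = g * l1) %*% L2 +
      Matrix::Diagonal(x = g * l2) %*% L1
    Jy <- UH %*% B - Matrix::Diagonal(system$m)
    Q <- Matrix::solve(Jy, -(UH %*% Fu))
    out <- as.matrix(Matrix::solve(UH, Q))
  } else {
    Fx <- balance_jacobian_x(x, u, system, g)
    out <- as.matrix(-Matrix::solve(Fx, Fu))
  }
  dimnames(out) <- list(paste0(system$index$flux, "(",
                               system$index$label, ")"),
                        system$flux_names)
  out
}

# coerce/validate a flux vector against the system's flux order
as_flux_vector <- function(u, system) {
  if (!is.null(names(u))) {
    missing <- setdiff(system$flux_names, names(u))
    if (length(missing) > 0L) {
      stop("flux vector is missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    u <- u[system$flux_names]
  } else if (length(u) != system$n) {
    stop("flux vector has length ", length(u), ", expected ", system$n,
         call. = FALSE)
  }
  stats::setNames(as.numeric(u), system$flux_names)
}

#' Isotopomer fractions implied by a fluxomer steady state
#'
#' For every tracked pool, the isotopomer distribution is recovered from
#' any one consuming flux as the ratio of its slot-restricted fluxomers to
#' the total flux (the uniform-distribution property guarantees the choice
#' of consumer is immaterial at steady state).
#'
#' @param steady_state a [solve_steady_state()] result.
#' @param system the `fluxomer_system`.
#' @param pools pool names (default: all tracked non-input pools with a
#'   consumer).
#' @return a named list of named fraction vectors (names are label words).
#' @export
isotopomer_fractions <- function(steady_state, system, pools = NULL) {
  network <- system$network
  if (is.null(pools)) {
    pools <- network$pools$name[network$pools$role != "input" &
                                  network$pools$n_atoms > 0L]
    pools <- pools[vapply(pools,
                          function(p) length(pool_consumers(network, p)) > 0,
                          logical(1))]
  }
  x <- as.numeric(steady_state$x)
  out <- list()
  for (p in pools) {
    cons <- pool_consumers(network, p)
    if (length(cons) == 0L) {
      stop("pool '", p, "' has no consuming flux to read fractions from",
           call. = FALSE)
    }
    # read through the first consumer carrying positive flux (a zero
    # consumer has no fluxomer mass to normalize by)
    tot <- 0
    for (cand in cons) {
      fx <- network$fluxes[[cand]]
      slot <- which(fx$substrates == p)[1]
      rows <- which(system$index$flux == fx$flux)
      sub <- extract_subword(system$index$word[rows],
                             fx$slot_pos[[slot]])
      tot <- sum(x[rows])
      if (tot > 0) break
    }
    if (tot <= 0) {
      stop("pool '", p, "' carries no outgoing fluxomer mass",
           call. = FALSE)
    }
    k <- pool_atoms(network, p)
    fr <- as.numeric(rowsum(x[rows], sub, reorder = TRUE))
    words <- sort(unique(sub))
    full <- numeric(2^k)
    full[words + 1L] <- fr / tot
    names(full) <- word_to_string(0:(2^k - 1L), k)
    out[[p]] <- full
  }
  out
}
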