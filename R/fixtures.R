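#' Five-pool demonstration network
#'
#' A small network with one labeled input A (4 carbons), an internal
#' B/C/D cycle including the reversible exchange pair f5/f5r, a
#' condensation f4 (D + C -> E), and an efflux. Atom routing: f1 splits A
#' into B (atoms 1,2) and C (atoms 3,4); f2: B -> D; f3: D -> B;
#' f5/f5r: B <-> C; f4 condenses one D and one C molecule into E whose
#' label word is [D-atoms, C-atoms]; fout drains E. Stoichiometric steady
#' state forces f1 = f4 = fout, f2 = f3 + f4 and f5 = f5r, leaving three
#' degrees of freedom (scale, the D/B cycle flux f3, and the exchange
#' magnitude f5).
#'
#' @param feed named feed distribution for pool A (default: 50% of
#'   molecules labeled at atom 1 only).
#' @param u_true optional named flux vector stored with the fixture
#'   (default `(f1, f2, f3, f4, f5, f5r, fout) = (1, 1.5, 0.5, 1, 0.7,
#'   0.7, 1)`).
#' @param flux_ub upper flux bound (default 100).
#' @return a list with `network`, `u_true`, and `provenance`.
#' @export
toy_fixture <- function(feed = c("1000" = 0.5, "0000" = 0.5),
                        u_true = c(f1 = 1, f2 = 1.5, f3 = 0.5, f4 = 1,
                                   f5 = 0.7, f5r = 0.7, fout = 1),
                        flux_ub = 100) {
  pools <- list(
    flux_pool("A", 4, role = "input", feed = feed),
    flux_pool("B", 2),
    flux_pool("C", 2),
    flux_pool("D", 2),
    flux_pool("E", 4)
  )
  reactions <- list(
    flux_reaction("f1", "A", list(B = 1:2, C = 3:4)),
    flux_reaction("f2", "B", list(D = 1:2)),
    flux_reaction("f3", "D", list(B = 1:2)),
    flux_reaction("f5", "B", list(C = 1:2), reversible = TRUE),
    flux_reaction("f4", c("D", "C"), list(E = 1:4)),
    flux_reaction("fout", "E", list())
  )
  network <- flux_network(pools, reactions, flux_ub = flux_ub)
  list(network = network, u_true = u_true[network$flux_names],
       provenance = "five-pool demonstration network")
}

#' Feasible flux vectors for the demonstration network
#'
#' Parameterizes the three stoichiometric degrees of freedom: the input
#' scale `f1`, the D-to-B cycle flux `f3`, and the B/C exchange magnitude
#' `f5`.
#'
#' @param f1,f3,f5 nonnegative flux values.
#' @return a named flux vector satisfying the steady-state balances.
#' @export
toy_flux_vector <- function(f1 = 1, f3 = 0.5, f5 = 0.7) {
  c(f1 = f1, f2 = f3 + f1, f3 = f3, f5 = f5, f5r = f5, f4 = f1,
    fout = f1)
}

#' Embden-Meyerhof plus pentose-phosphate example network
#'
#' The classic upper-glycolysis (EMP) / pentose-phosphate (PPP) network of
#' E. coli central metabolism with standard carbon transitions: glucose
#' uptake, the G6P branch point between glycolysis and the oxidative PPP
#' (which releases carbon 1 as CO2), the reversible
#' epimerase/isomerase/transketolase/transaldolase block, the aldolase
#' split of FBP into two trioses, and the triose chain down to PEP. The
#' fixture carries the tutorial labeling experiment: a feed of 50%
#' [1-13C] glucose with 1.1% of molecules single-labeled at each of the
#' other positions, positional-enrichment measurements (sd 0.002) on
#' Rul5P, Ery4P, GA3P and PEP, and a glucose-uptake measurement of 1.02
#' (sd 0.001) that anchors the absolute flux scale.
#'
#' @param flux_ub upper flux bound applied to every unidirectional flux
#'   (default 20; the exchange magnitudes of the reversible PPP pairs are
#'   weakly identified and need a finite search box).
#' @return a list with `network`, `u_table` (a reference steady-state flux
#'   vector at which the fixture's measurements are self-consistent),
#'   `measurements`, and `provenance`.
#' @export
empp_fixture <- function(flux_ub = 20) {
  pools <- list(
    flux_pool("GLC", 6, role = "input",
              feed = c("000000" = 0.445, "100000" = 0.500,
                       "000001" = 0.011, "000010" = 0.011,
                       "000100" = 0.011, "001000" = 0.011,
                       "010000" = 0.011)),
    flux_pool("G6P", 6), flux_pool("F6P", 6), flux_pool("FBP", 6),
    flux_pool("GA3P", 3), flux_pool("PGA", 3), flux_pool("PEP", 3),
    flux_pool("Rul5P", 5), flux_pool("X5P", 5), flux_pool("R5P", 5),
    flux_pool("S7P", 7), flux_pool("Ery4P", 4), flux_pool("CO2", 1)
  )
  reactions <- list(
    flux_reaction("upt", "GLC", list(G6P = 1:6)),
    flux_reaction("emp1", "G6P", list(F6P = 1:6)),
    flux_reaction("emp2", "F6P", list(FBP = 1:6)),
    # aldolase + triose phosphate isomerase: the DHAP-derived triose is
    # carbon-reversed
    flux_reaction("emp3", "FBP", list(GA3P = c(3, 2, 1), GA3P = 4:6)),
    flux_reaction("emp4", "GA3P", list(PGA = 1:3)),
    flux_reaction("emp5", "PGA", list(PEP = 1:3)),
    flux_reaction("emp6", "PEP", list()),
    # oxidative PPP: carbon 1 leaves as CO2
    flux_reaction("ppp1", "G6P", list(CO2 = 1, Rul5P = 2:6)),
    flux_reaction("ppp2", "Rul5P", list(X5P = 1:5), reversible = TRUE),
    flux_reaction("ppp3", "Rul5P", list(R5P = 1:5), reversible = TRUE),
    # transketolase 2: X5P + Ery4P <-> GA3P + F6P (the strongly
    # exchanging pair; its reverse carries F6P C1 label back into the
    # pentose block, which the measured Rul5P C1 enrichment pins down)
    flux_reaction("ppp4", c("X5P", "Ery4P"),
                  list(GA3P = 3:5, F6P = c(1, 2, 6, 7, 8, 9)),
                  reversible = TRUE),
    # transketolase 1: X5P + R5P <-> GA3P + S7P
    flux_reaction("ppp5", c("X5P", "R5P"),
                  list(GA3P = 3:5, S7P = c(1, 2, 6:10)),
                  reversible = TRUE),
    # transaldolase: S7P + GA3P <-> Ery4P + F6P
    flux_reaction("ppp6", c("S7P", "GA3P"),
                  list(Ery4P = 4:7, F6P = c(1, 2, 3, 8, 9, 10)),
                  reversible = TRUE),
    flux_reaction("coOut", "CO2", list())
  )
  network <- flux_network(pools, reactions, flux_ub = flux_ub)
  u_table <- c(upt = 1.02,
               emp1 = 0.51, emp2 = 0.85, emp3 = 0.85,
               emp4 = 1.87, emp5 = 1.87, emp6 = 1.87,
               ppp1 = 0.51,
               ppp2 = 4.4234, ppp2r = 4.0834,
               ppp3 = 4.4689, ppp3r = 4.2989,
               ppp4 = 4.2468, ppp4r = 4.0768,
               ppp5 = 0.4238, ppp5r = 0.2538,
               ppp6 = 0.4250, ppp6r = 0.2550,
               coOut = 0.51)
  meas <- measurement_set(
    groups = list(
      label_group("NMR-1H", "Rul5P",
                  specs = c("#1xxxx", "#x1xxx", "#xx1xx", "#xxx1x",
                            "#xxxx1"),
                  values = c(0.1979, 0.0153, 0.0284, 0.0122, 0.0976),
                  sd = 0.002),
      label_group("NMR-1H", "Ery4P",
                  specs = c("#1xxx", "#x1xx", "#xx1x", "#xxx1"),
                  values = c(0.0568, 0.0229, 0.0118, 0.0704),
                  sd = 0.002),
      label_group("NMR-1H", "GA3P",
                  specs = c("#1xx", "#x1x", "#xx1"),
                  values = c(0.0330, 0.0126, 0.1207),
                  sd = 0.002),
      label_group("NMR-1H", "PEP",
                  specs = c("#1xx", "#x1x", "#xx1"),
                  values = c(0.0330, 0.0126, 0.1207),
                  sd = 0.002)
    ),
    fluxes = tibble::tibble(flux = "upt", value = 1.02, sd = 0.001)
  )
  list(network = network, u_table = u_table[network$flux_names],
       measurements = meas,
       provenance = "EMP/PPP tutorial network with labeling experiment")
}

#' Simulate a labeling measurement set at known fluxes
#'
#' Solves the steady state at `u_true`, reads the model-predicted group
#' intensities through the measurement transforms, and adds seeded
#' Gaussian noise of standard deviation `sigma` on the fraction scale.
#' Optionally multiplies each group's raw intensities by a random positive
#' constant to emulate non-normalized MS data (the scaling-invariant
#' objective must be indifferent to this). A flux measurement on the
#' uptake flux anchors the absolute scale.
#'
#' @param network a [flux_network()].
#' @param u_true feasible flux vector.
#' @param sigma Gaussian noise standard deviation in fraction units.
#' @param seed integer seed; the simulation is a pure function of
#'   (arguments, seed).
#' @param pools pools to measure (default: all tracked non-input pools
#'   with at least one consumer).
#' @param kind measurement kind to emit: `"MS"` mass-isotopomer groups or
#'   `"NMR-1H"` positional enrichments.
#' @param rescale_groups multiply each group by exp(U(-1, 1)) to emulate
#'   arbitrary intensity units.
#' @param sd_report standard deviation attached to the label rows for
#'   weighting (default: `max(sigma, 0.002)`, the conventional fraction
#'   -scale uncertainty).
#' @param flux_sd standard deviation reported for the anchoring flux
#'   measurement.
#' @param system optionally a prebuilt `fluxomer_system` for `network`.
#' @return a [measurement_set()].
#' @export
simulate_measurements <- function(network, u_true, sigma = 0, seed = 1L,
                                  pools = NULL, kind = c("MS", "NMR-1H"),
                                  rescale_groups = FALSE, sd_report = NULL,
                                  flux_sd = 0.001, system = NULL) {
  kind <- match.arg(kind)
  if (is.null(sd_report)) sd_report <- max(sigma, 0.002)
  if (is.null(system)) system <- build_fluxomer_system(network)
  u_true <- as_flux_vector(u_true, system)
  ss <- solve_steady_state(u_true, system)
  frac <- isotopomer_fractions(ss, system, pools = pools)
  rng <- local_rng(seed)
  groups <- list()
  for (p in names(frac)) {
    k <- pool_atoms(network, p)
    if (kind == "MS") {
      wt <- word_weight(0:(2^k - 1L), k)
      vals <- as.numeric(rowsum(frac[[p]], wt))
      specs <- 0:k
    } else {
      specs <- vapply(seq_len(k), function(a) {
        s <- rep("x", k); s[a] <- "1"; paste0("#", paste0(s, collapse = ""))
      }, character(1))
      vals <- vapply(seq_len(k), function(a) {
        w <- 0:(2^k - 1L)
        sum(frac[[p]][bitwAnd(bitwShiftR(w, a - 1L), 1L) == 1L])
      }, numeric(1))
    }
    if (sigma > 0) vals <- vals + rng$rnorm(length(vals), 0, sigma)
    if (rescale_groups) vals <- vals * exp(rng$runif(1, -1, 1))
    groups[[length(groups) + 1L]] <-
      label_group(kind, p, specs = specs, values = vals, sd = sd_report,
                  normalized = !rescale_groups)
  }
  # anchor the scale on the flux that drains the input substrate
  roles <- stats::setNames(network$pools$role, network$pools$name)
  upt <- names(network$fluxes)[vapply(network$fluxes, function(fx)
    any(roles[fx$substrates] == "input"), logical(1))][1]
  measurement_set(groups = groups,
                  fluxes = tibble::tibble(flux = upt,
                                          value = unname(u_true[upt]),
                                          sd = flux_sd))
}

# self-contained RNG stream so fixtures never disturb the global seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      } else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
      out
    }
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif),
       sample_int = draw(sample.int))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Brute-force isotopomer steady state (independent oracle)
#'
#' Solves the classical pool-isotopomer balance equations directly, with
#' no shared machinery with the fluxomer solver: each balanced pool's
#' isotopomer fraction vector is iterated as the flux-weighted mixture of
#' its inflows, with condensation reactions forming products by outer
#' products of their source-pool distributions. Intended as a
#' cross-validation oracle on small networks.
#'
#' @param network a [flux_network()].
#' @param u feasible flux vector (named).
#' @param tol convergence tolerance on the largest fraction change.
#' @param max_iter iteration cap.
#' @param max_states refuse networks with more total isotopomer states.
#' @return named list of per-pool isotopomer fraction vectors (names are
#'   label words).
#' @export
brute_force_oracle <- function(network, u, tol = 1e-13, max_iter = 100000L,
                               max_states = 10000L) {
  pools_tbl <- network$pools
  nstates <- sum(2^pools_tbl$n_atoms)
  if (nstates > max_states) {
    stop("network has ", nstates, " isotopomer states (cap ", max_states,
         ")", call. = FALSE)
  }
  if (is.null(names(u))) names(u) <- network$flux_names
  u <- u[network$flux_names]
  dist <- list()
  for (i in seq_len(nrow(pools_tbl))) {
    p <- pools_tbl$name[i]
    k <- pools_tbl$n_atoms[i]
    dist[[p]] <- if (pools_tbl$role[i] == "input") {
      pools_tbl$feed[[i]]
    } else {
      c(1, numeric(2^k - 1L))  # start unlabeled
    }
  }
  balanced <- pools_tbl$name[pools_tbl$role == "intermediate"]
  # precompute, per balanced pool, its producing (flux, delivery-index) set
  deliveries <- list()
  for (p in balanced) {
    dl <- list()
    for (fx in network$fluxes) {
      hits <- which(names(fx$products) == p)
      if (length(hits) == 0L) next
      subs <- fx$substrates
      ks <- vapply(subs, function(s) pool_atoms(network, s), integer(1))
      words <- 0:(2^sum(ks) - 1L)
      for (h in hits) {
        dl[[length(dl) + 1L]] <- list(
          flux = fx$flux, subs = subs, ks = ks,
          sub1 = extract_subword(words, fx$slot_pos[[1]]),
          sub2 = if (length(subs) > 1L)
            extract_subword(words, fx$slot_pos[[2]]) else NULL,
          to = extract_subword(words, fx$products[[h]]) + 1L
        )
      }
    }
    deliveries[[p]] <- dl
  }
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (p in balanced) {
      k <- pool_atoms(network, p)
      inflow <- numeric(2^k)
      total <- 0
      for (d in deliveries[[p]]) {
        f <- u[[d$flux]]
        if (f <= 0) next
        pr <- dist[[d$subs[1]]][d$sub1 + 1L]
        if (!is.null(d$sub2)) pr <- pr * dist[[d$subs[2]]][d$sub2 + 1L]
        rs <- rowsum(pr, d$to)
        agg <- numeric(2^k)
        agg[as.integer(rownames(rs))] <- rs[, 1]
        inflow <- inflow + f * agg
        total <- total + f
      }
      if (total <= 0) next
      newp <- inflow / total
      # project back onto the simplex: the quadratic condensation terms
      # would otherwise amplify roundoff in the distribution sums
      newp <- newp / sum(newp)
      delta <- max(delta, max(abs(newp - dist[[p]])))
      dist[[p]] <- newp
    }
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop("oracle iteration did not converge (last change ", format(delta),
         ")", call. = FALSE)
  }
  for (p in names(dist)) {
    names(dist[[p]]) <- word_to_string(0:(2^pool_atoms(network, p) - 1L),
                                       pool_atoms(network, p))
  }
  dist
}

#' Fluxomer vector implied by oracle isotopomer fractions
#'
#' Forms x[flux, word] = u[flux] * prod of source-pool isotopomer
#' fractions, the uniform-distribution relation, from an independent set
#' of per-pool fractions.
#'
#' @param network a [flux_network()].
#' @param u named flux vector.
#' @param fractions per-pool fractions as returned by
#'   [brute_force_oracle()].
#' @param system a `fluxomer_system` (defines the index order).
#' @return numeric vector of length `system$m`.
#' @export
oracle_fluxomers <- function(network, u, fractions, system) {
  u <- as_flux_vector(u, system)
  x <- numeric(system$m)
  roles <- stats::setNames(network$pools$role, network$pools$name)
  for (fx in network$fluxes) {
    rows <- which(system$index$flux == fx$flux)
    words <- system$index$word[rows]
    pr <- rep(1, length(rows))
    for (slot in seq_along(fx$substrates)) {
      p <- fx$substrates[slot]
      sub <- extract_subword(words, fx$slot_pos[[slot]])
      pp <- if (roles[[p]] == "input") {
        network$pools$feed[[match(p, network$pools$name)]]
      } else {
        fractions[[p]]
      }
      pr <- pr * pp[sub + 1L]
    }
    x[rows] <- u[[fx$flux]] * pr
  }
  x
}
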