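#' Declare a metabolite pool
#'
#' A pool is a balanced intracellular metabolite, an input substrate with a
#' known isotopomer feed distribution, or an unbalanced output sink.
#'
#' @param name pool identifier.
#' @param n_atoms number of tracked backbone carbon atoms (may be 0 for
#'   untracked co-substrates).
#' @param role one of `"intermediate"`, `"input"`, `"output"`.
#' @param feed for input pools, the isotopomer distribution of the feed:
#'   a named numeric vector whose names are label words written atom-1
#'   leftmost (optionally `#`-prefixed), e.g. `c("000000" = 0.445,
#'   "100000" = 0.5)`. Unlisted isotopomers are 0; the listed values must
#'   be nonnegative and sum to 1.
#' @return a `flux_pool` list.
#' @export
#' @examples
#' flux_pool("GLC", 6, role = "input",
#'           feed = c("000000" = 0.5, "100000" = 0.5))
flux_pool <- function(name, n_atoms,
                      role = c("intermediate", "input", "output"),
                      feed = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nchar(name) > 0L)
  n_atoms <- as.integer(n_atoms)
  if (is.na(n_atoms) || n_atoms < 0L) {
    stop("pool '", name, "': n_atoms must be a nonnegative integer",
         call. = FALSE)
  }
  dist <- NULL
  if (role == "input") {
    if (is.null(feed)) {
      stop("input pool '", name, "' needs a feed distribution", call. = FALSE)
    }
    words <- string_to_word(sub("^#", "", names(feed)))
    if (anyDuplicated(words)) {
      stop("pool '", name, "': duplicate feed isotopomers", call. = FALSE)
    }
    if (any(nchar(sub("^#", "", names(feed))) != n_atoms)) {
      stop("pool '", name, "': feed label words must have ", n_atoms,
           " atoms", call. = FALSE)
    }
    if (any(feed < 0)) {
      stop("pool '", name, "': feed fractions must be nonnegative",
           call. = FALSE)
    }
    if (abs(sum(feed) - 1) > 1e-9) {
      stop("pool '", name, "': feed fractions must sum to 1 (got ",
           format(sum(feed)), ")", call. = FALSE)
    }
    dist <- numeric(2^n_atoms)
    dist[words + 1L] <- as.numeric(feed)
  } else if (!is.null(feed)) {
    stop("pool '", name, "': only input pools carry a feed distribution",
         call. = FALSE)
  }
  structure(list(name = name, n_atoms = n_atoms, role = role, feed = dist),
            class = "flux_pool")
}

#' Declare an atom-mapped reaction
#'
#' A reaction consumes one molecule from each of at most two substrate
#' pools and routes every consumed carbon to a product position. The
#' reaction's label word is the concatenation of the substrate molecules'
#' atoms in declaration order (substrate 1 first); each product slot names
#' the word positions its molecule receives, in product-atom order.
#'
#' @param id reaction/flux identifier. The reverse direction of a
#'   reversible reaction is named `paste0(id, "r")`.
#' @param substrates character vector (length 1 or 2) of consumed pools.
#' @param products named list mapping product pool names to integer vectors
#'   of word positions (duplicate names allowed, e.g. an aldolase producing
#'   two trioses). An empty list declares an efflux whose atoms leave the
#'   modeled system.
#' @param reversible logical; reversible reactions are expanded into a
#'   forward/reverse pair of nonnegative unidirectional fluxes.
#' @return a `flux_reaction` list.
#' @export
#' @examples
#' # transketolase: X5P + R5P <-> GA3P + S7P
#' flux_reaction("ppp4", c("X5P", "R5P"),
#'               list(GA3P = 3:5, S7P = c(1, 2, 6:10)), reversible = TRUE)
flux_reaction <- function(id, substrates, products = list(),
                          reversible = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nchar(id) > 0L)
  stopifnot(is.character(substrates), length(substrates) >= 1L)
  if (length(substrates) > 2L) {
    stop("reaction '", id, "' draws from more than 2 source pools; ",
         "introduce an explicit intermediate pool to split the condensation",
         call. = FALSE)
  }
  if (anyDuplicated(substrates)) {
    stop("reaction '", id, "' consumes the same pool twice; ",
         "this formulation supports one molecule per substrate pool",
         call. = FALSE)
  }
  if (!is.list(products)) stop("products must be a list", call. = FALSE)
  if (length(products) > 0L && is.null(names(products))) {
    stop("products must be a named list", call. = FALSE)
  }
  structure(list(id = id, substrates = substrates, products = products,
                 reversible = isTRUE(reversible)),
            class = "flux_reaction")
}

# Expand one direction of a reaction into the internal slot form used by
# the fluxomer machinery.
expand_direction <- function(rx, pools_tbl, direction = c("fwd", "rev")) {
  direction <- match.arg(direction)
  natoms <- stats::setNames(pools_tbl$n_atoms, pools_tbl$name)
  if (direction == "fwd") {
    subs <- rx$substrates
    prods <- rx$products
    flux <- rx$id
  } else {
    # reverse: consume the product molecules, emit the substrates
    prod_pools <- names(rx$products)
    from_concat <- unlist(rx$products, use.names = FALSE)
    subs <- prod_pools
    # product slot for original substrate s: where do its atoms live in the
    # reverse word (= concatenation of forward product molecules)?
    offs <- 0L
    prods <- list()
    for (s in rx$substrates) {
      idx <- offs + seq_len(natoms[[s]])
      prods[[length(prods) + 1L]] <- match(idx, from_concat)
      offs <- offs + natoms[[s]]
    }
    names(prods) <- rx$substrates
    flux <- paste0(rx$id, "r")
  }
  ks <- unname(natoms[subs])
  k <- sum(ks)
  # word positions occupied by each substrate slot
  slot_pos <- split(seq_len(k), rep(seq_along(subs), ks))
  list(flux = flux, reaction = rx$id, direction = direction,
       substrates = subs, slot_pos = unname(slot_pos),
       products = prods, k = k)
}

#' Assemble and validate a metabolic network
#'
#' Expands reversible reactions into forward/reverse flux pairs, checks
#' atom conservation and pool connectivity, and records flux bounds.
#'
#' @param pools list of [flux_pool()] objects.
#' @param reactions list of [flux_reaction()] objects.
#' @param flux_ub upper bound(s) on the unidirectional fluxes: a single
#'   number or a named vector keyed by flux name (defaults applied to the
#'   rest).
#' @return a `flux_network` object.
#' @export
flux_network <- function(pools, reactions, flux_ub = 100) {
  if (inherits(pools, "flux_pool")) pools <- list(pools)
  if (inherits(reactions, "flux_reaction")) reactions <- list(reactions)
  stopifnot(all(vapply(pools, inherits, logical(1), "flux_pool")),
            all(vapply(reactions, inherits, logical(1), "flux_reaction")))
  pools_tbl <- tibble::tibble(
    name = vapply(pools, `[[`, character(1), "name"),
    n_atoms = vapply(pools, `[[`, integer(1), "n_atoms"),
    role = vapply(pools, `[[`, character(1), "role"),
    feed = lapply(pools, `[[`, "feed")
  )
  if (anyDuplicated(pools_tbl$name)) {
    stop("duplicate pool names", call. = FALSE)
  }
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids", call. = FALSE)
  natoms <- stats::setNames(pools_tbl$n_atoms, pools_tbl$name)

  for (rx in reactions) {
    for (p in c(rx$substrates, names(rx$products))) {
      if (!p %in% pools_tbl$name) {
        stop("reaction '", rx$id, "' references undeclared pool '", p, "'",
             call. = FALSE)
      }
    }
    k <- sum(natoms[rx$substrates])
    from <- unlist(rx$products, use.names = FALSE)
    if (length(rx$products) > 0L) {
      lens <- vapply(rx$products, length, integer(1))
      bad <- lens != natoms[names(rx$products)]
      if (any(bad)) {
        stop("reaction '", rx$id, "': product '",
             names(rx$products)[bad][1],
             "' does not receive one position per atom", call. = FALSE)
      }
      if (length(from) != k || anyDuplicated(from) ||
          !all(sort(from) == seq_len(k))) {
        stop("reaction '", rx$id, "' does not conserve atoms: consumed ",
             k, " but routed ", length(unique(from)),
             " distinct positions to products", call. = FALSE)
      }
    }
    if (rx$reversible) {
      if (length(rx$products) == 0L) {
        stop("reaction '", rx$id,
             "': an efflux cannot be reversible", call. = FALSE)
      }
      if (length(rx$products) > 2L ||
          anyDuplicated(names(rx$products))) {
        stop("reaction '", rx$id, "': the reverse direction would draw on ",
             "more than 2 source molecules", call. = FALSE)
      }
    }
    roles <- stats::setNames(pools_tbl$role, pools_tbl$name)
    if (any(roles[rx$substrates] == "input") && length(rx$substrates) > 1L) {
      stop("reaction '", rx$id, "': an input substrate cannot condense ",
           "with a second pool; route it through an intermediate",
           call. = FALSE)
    }
    if (any(roles[rx$substrates] == "output")) {
      stop("reaction '", rx$id, "' consumes an output pool", call. = FALSE)
    }
  }

  expanded <- list()
  for (rx in reactions) {
    expanded[[length(expanded) + 1L]] <- expand_direction(rx, pools_tbl, "fwd")
    if (rx$reversible) {
      expanded[[length(expanded) + 1L]] <-
        expand_direction(rx, pools_tbl, "rev")
    }
  }
  flux_names <- vapply(expanded, `[[`, character(1), "flux")
  if (anyDuplicated(flux_names)) {
    stop("duplicate flux names after reversible expansion", call. = FALSE)
  }
  names(expanded) <- flux_names

  ub <- rep(if (is.null(names(flux_ub))) flux_ub[[1]] else 100,
            length(flux_names))
  names(ub) <- flux_names
  if (!is.null(names(flux_ub))) {
    unknown <- setdiff(names(flux_ub), flux_names)
    if (length(unknown) > 0L) {
      stop("flux_ub names not in network: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    ub[names(flux_ub)] <- flux_ub
  }

  net <- structure(list(pools = pools_tbl, reactions = reactions,
                        fluxes = expanded, flux_names = flux_names,
                        flux_ub = ub),
                   class = "flux_network")
  net$S <- build_stoichiometry(net, check = TRUE)
  net
}

#' Stoichiometric matrix of a network
#'
#' One row per balanced pool (every pool that is neither an input substrate
#' nor an output sink), one column per unidirectional flux; +c for a flux
#' producing c molecules into the pool, -c for consumption. Metabolic
#' steady state is `S %*% u = 0`.
#'
#' @param network a [flux_network()].
#' @param check also verify that every balanced pool has at least one
#'   inflow and one outflow.
#' @return a dense integer matrix with dimnames (pool, flux).
#' @export
build_stoichiometry <- function(network, check = FALSE) {
  pools_tbl <- network$pools
  balanced <- pools_tbl$name[pools_tbl$role == "intermediate"]
  S <- matrix(0L, nrow = length(balanced), ncol = length(network$flux_names),
              dimnames = list(balanced, network$flux_names))
  for (fx in network$fluxes) {
    j <- fx$flux
    for (s in fx$substrates) {
      if (s %in% balanced) S[s, j] <- S[s, j] - 1L
    }
    for (p in names(fx$products)) {
      if (p %in% balanced) S[p, j] <- S[p, j] + 1L
    }
  }
  if (check) {
    for (p in balanced) {
      has_out <- any(S[p, ] < 0)
      has_in <- any(S[p, ] > 0)
      if (!has_out || !has_in) {
        stop("pool '", p, "' is declared balanced but has ",
             if (!has_in) "no inflow" else "no outflow", call. = FALSE)
      }
    }
  }
  S
}

#' @export
print.flux_network <- function(x, ...) {
  cat("<flux_network> ", nrow(x$pools), " pools, ",
      length(x$reactions), " reactions (",
      length(x$flux_names), " unidirectional fluxes)\n", sep = "")
  cat("  pools: ", paste0(x$pools$name, "(", x$pools$n_atoms, ")",
                          collapse = " "), "\n", sep = "")
  cat("  fluxes: ", paste(x$flux_names, collapse = " "), "\n", sep = "")
  invisible(x)
}

# internal: role lookup
pool_role <- function(network, pool) {
  network$pools$role[match(pool, network$pools$name)]
}

pool_atoms <- function(network, pool) {
  network$pools$n_atoms[match(pool, network$pools$name)]
}

# consumers of each pool: flux names that draw a molecule from it
pool_consumers <- function(network, pool) {
  keep <- vapply(network$fluxes, function(fx) pool %in% fx$substrates,
                 logical(1))
  names(network$fluxes)[keep]
}

# producers: list of (flux, from-positions) delivering a molecule into pool
pool_producers <- function(network, pool) {
  out <- list()
  for (fx in network$fluxes) {
    hits <- which(names(fx$products) == pool)
    for (h in hits) {
      out[[length(out) + 1L]] <- list(flux = fx$flux,
                                      from = fx$products[[h]])
    }
  }
  out
}
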