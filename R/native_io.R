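#' Write a model in the native YAML schema
#'
#' @param network a [flux_network()].
#' @param measurements optional [measurement_set()].
#' @param path output file; `NULL` returns the YAML string.
#' @return the YAML string, invisibly when written to a file.
#' @export
write_model_yaml <- function(network, measurements = NULL, path = NULL) {
  pools <- lapply(seq_len(nrow(network$pools)), function(i) {
    p <- list(name = network$pools$name[i],
              n_atoms = network$pools$n_atoms[i],
              role = network$pools$role[i])
    if (p$role == "input") {
      feed <- network$pools$feed[[i]]
      nz <- which(feed > 0)
      p$feed <- as.list(stats::setNames(
        feed[nz], word_to_string(nz - 1L, p$n_atoms)))
    }
    p
  })
  reactions <- lapply(network$reactions, function(rx) {
    list(id = rx$id, substrates = as.list(rx$substrates),
         products = lapply(seq_along(rx$products), function(j) {
           list(pool = names(rx$products)[j],
                from = as.list(rx$products[[j]]))
         }),
         reversible = rx$reversible)
  })
  doc <- list(pools = pools, reactions = reactions,
              flux_ub = as.list(network$flux_ub))
  if (!is.null(measurements)) {
    doc$measurements <- list(
      groups = lapply(measurements$groups, function(g) {
        out <- list(kind = g$kind, pool = g$pool,
                    specs = as.list(g$specs),
                    values = as.list(g$values), sd = as.list(g$sd),
                    normalized = g$normalized)
        if (!is.null(g$atoms)) out$atoms <- as.list(g$atoms)
        if (!is.null(g$formula)) out$formula <- g$formula
        out
      }),
      fluxes = lapply(seq_len(nrow(measurements$fluxes)), function(i) {
        as.list(measurements$fluxes[i, ])
      })
    )
  }
  s <- yaml::as.yaml(doc, precision = 15L)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read a model from the native YAML schema
#'
#' @param path file path (or a YAML string containing a newline).
#' @return list with `network` and `measurements` (the latter `NULL` when
#'   the document has none).
#' @export
read_model_yaml <- function(path) {
  doc <- if (grepl("\n", path)) yaml::yaml.load(path)
         else yaml::read_yaml(path)
  pools <- lapply(doc$pools, function(p) {
    flux_pool(p$name, p$n_atoms, role = p$role,
              feed = if (!is.null(p$feed)) unlist(p$feed) else NULL)
  })
  reactions <- lapply(doc$reactions, function(rx) {
    prods <- lapply(rx$products, function(pr) as.integer(unlist(pr$from)))
    names(prods) <- vapply(rx$products, `[[`, character(1), "pool")
    flux_reaction(rx$id, unlist(rx$substrates), prods,
                  reversible = isTRUE(rx$reversible))
  })
  ub <- unlist(doc$flux_ub)
  network <- flux_network(pools, reactions, flux_ub = ub)
  measurements <- NULL
  if (!is.null(doc$measurements)) {
    groups <- lapply(doc$measurements$groups, function(g) {
      label_group(g$kind, g$pool, specs = unlist(g$specs),
                  values = unlist(g$values), sd = unlist(g$sd),
                  atoms = if (!is.null(g$atoms)) unlist(g$atoms) else NULL,
                  formula = g$formula,
                  normalized = isTRUE(g$normalized))
    })
    fluxes <- dplyr::bind_rows(lapply(doc$measurements$fluxes,
                                      tibble::as_tibble))
    if (nrow(fluxes) == 0L) {
      fluxes <- tibble::tibble(flux = character(0), value = numeric(0),
                               sd = numeric(0))
    }
    measurements <- measurement_set(groups = groups, fluxes = fluxes)
  }
  list(network = network, measurements = measurements)
}

#' Write a fitted flux table and JSON diagnostics sidecar
#'
#' Emits a tab-separated table with one row per unidirectional flux in
#' declaration order (columns `flux`, `estimate`, and per-flux noise
#' spread columns when a noise study is supplied) plus a
#' `<path>.json` sidecar carrying the residual norm, iteration counts and
#' solver settings.
#'
#' @param fit a [fia_fit()] result.
#' @param path output TSV path.
#' @param noise optional [noise_study()] table to merge.
#' @return `path`, invisibly.
#' @export
write_results <- function(fit, path, noise = NULL) {
  if (!inherits(fit, "fia_fit")) {
    stop("write_results() expects a fia_fit object", call. = FALSE)
  }
  if (length(fit$u_star) == 0L) {
    stop("fit carries no flux estimates", call. = FALSE)
  }
  tab <- tibble::tibble(flux = names(fit$u_star),
                        estimate = as.numeric(fit$u_star))
  if (!is.null(noise)) {
    tab <- dplyr::left_join(
      tab, dplyr::select(tibble::as_tibble(noise), "flux", "mean",
                         "sd", "mse"),
      by = "flux")
  }
  # 17 significant digits so the decimal strings round-trip bit-exactly
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::where(is.numeric),
                                          ~ sprintf("%.17g", .x)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- list(objective = fit$objective,
               residual_norm = sqrt(fit$objective),
               outer_iterations = fit$iterations,
               inner_iterations = fit$inner_iterations,
               converged = fit$converged,
               n_fluxes = length(fit$u_star))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
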