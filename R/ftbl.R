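#' Parse a 13CFLUX-style FTBL model document
#'
#' Reads the tab-separated FTBL dialect used by the 13CFLUX software
#' family, covering the sections a tutorial model uses: `NETWORK` (atom
#' transitions as `#ABC`-style letter codes, educt atoms concatenated in
#' declaration order), `FLUXES` (`XCH`/`F` marks a reaction reversible;
#' `NET`/`C` fixes a net flux, imported as a tight flux measurement;
#' free-flux declarations and initial-value hints are parsed and
#' ignored), `LABEL_INPUT`, `LABEL_MEASUREMENTS` (cumomer-style patterns,
#' imported as positional/pattern enrichments), `MASS_SPECTROMETRY`, and
#' `FLUX_MEASUREMENTS`. Unknown sections are skipped with a warning.
#'
#' @param text FTBL document as a single string or character vector of
#'   lines.
#' @param flux_ub upper flux bound applied to the network.
#' @return list with `network` (a [flux_network()]) and `measurements`
#'   (a [measurement_set()]).
#' @export
parse_ftbl <- function(text, flux_ub = 100) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  lines <- sub("//.*$", "", lines)
  lines <- lines[!grepl("^\\s*$", lines)]
  is_header <- !grepl("^\t", lines)
  section <- cumsum(is_header)
  sections <- split(lines, section)
  names(sections) <- vapply(sections, function(s) trimws(s[[1]]),
                            character(1))

  known <- c("NETWORK", "FLUXES", "LABEL_INPUT", "LABEL_MEASUREMENTS",
             "MASS_SPECTROMETRY", "FLUX_MEASUREMENTS")
  for (nm in setdiff(names(sections), known)) {
    warning("ignoring unknown FTBL section '", nm, "'", call. = FALSE)
  }
  if (!"NETWORK" %in% names(sections)) {
    stop("FTBL document has no NETWORK section", call. = FALSE)
  }

  fields <- function(s) {
    rows <- s[-1]
    lapply(strsplit(rows, "\t", fixed = TRUE),
           function(f) trimws(f[-1]))  # drop the indent column
  }

  # ---- NETWORK ----
  rows <- fields(sections$NETWORK)
  rows <- Filter(length, rows)
  if (length(rows) > 0L && identical(rows[[1]][1], "FLUX_NAME")) {
    rows <- rows[-1]
  }
  get_col <- function(r, i) if (length(r) >= i) r[i] else ""
  rxrows <- list()
  i <- 1L
  while (i <= length(rows)) {
    r <- rows[[i]]
    if (nchar(get_col(r, 1)) == 0L) {
      stop("malformed NETWORK section: expected a reaction row, got '",
           paste(r, collapse = "\t"), "'", call. = FALSE)
    }
    if (i + 1L > length(rows) || nchar(get_col(rows[[i + 1L]], 1)) > 0L) {
      stop("reaction '", r[1], "' has no atom-transition row",
           call. = FALSE)
    }
    a <- rows[[i + 1L]]
    rxrows[[length(rxrows) + 1L]] <-
      list(id = r[1],
           educts = Filter(nchar, c(get_col(r, 2), get_col(r, 3))),
           products = Filter(nchar, c(get_col(r, 4), get_col(r, 5))),
           educt_atoms = Filter(nchar, c(get_col(a, 2), get_col(a, 3))),
           product_atoms = Filter(nchar, c(get_col(a, 4), get_col(a, 5))))
    i <- i + 2L
  }

  # ---- FLUXES: reversibility and fixed net values ----
  xch_free <- character(0)
  net_fixed <- tibble::tibble(flux = character(0), value = numeric(0))
  if ("FLUXES" %in% names(sections)) {
    sub <- NA_character_
    for (r in fields(sections$FLUXES)) {
      while (length(r) > 0L && !nzchar(r[1])) r <- r[-1]  # extra indent
      if (length(r) == 0L) next
      if (r[1] %in% c("NET", "XCH")) { sub <- r[1]; next }
      if (identical(r[1], "NAME")) next
      fcd <- if (length(r) >= 2L) r[2] else ""
      val <- if (length(r) >= 3L) suppressWarnings(as.numeric(r[3]))
             else NA_real_
      if (identical(sub, "XCH")) {
        if (identical(fcd, "F") || identical(fcd, "D")) {
          xch_free <- c(xch_free, r[1])
        } else if (identical(fcd, "C") && isTRUE(val > 0)) {
          xch_free <- c(xch_free, r[1])
        }
      } else if (identical(sub, "NET")) {
        if (identical(fcd, "C") && is.finite(val)) {
          net_fixed <- dplyr::bind_rows(
            net_fixed, tibble::tibble(flux = r[1], value = val))
        }
        # FCD F/D: free-flux declarations and initial values are ignored
      }
    }
  }

  # ---- LABEL_INPUT ----
  feeds <- list()
  if ("LABEL_INPUT" %in% names(sections)) {
    pool <- NA_character_
    for (r in fields(sections$LABEL_INPUT)) {
      if (length(r) == 0L || identical(r[1], "META_NAME")) next
      if (nchar(r[1]) > 0L) pool <- r[1]
      iso <- sub("^#", "", r[2])
      feeds[[pool]] <- c(feeds[[pool]],
                         stats::setNames(as.numeric(r[3]), iso))
    }
  }

  # assemble pools and reactions
  atoms_of <- function(code) nchar(sub("^#", "", code))
  pool_atoms_seen <- integer(0)
  note_pool <- function(p, k) {
    if (p %in% names(pool_atoms_seen)) {
      if (pool_atoms_seen[[p]] != k) {
        stop("pool '", p, "' appears with both ", pool_atoms_seen[[p]],
             " and ", k, " atoms", call. = FALSE)
      }
    } else {
      pool_atoms_seen[[p]] <<- k
    }
  }
  for (rx in rxrows) {
    if (length(rx$educts) != length(rx$educt_atoms) ||
        length(rx$products) != length(rx$product_atoms)) {
      stop("reaction '", rx$id,
           "': atom row does not match the reaction row", call. = FALSE)
    }
    purrr::walk2(rx$educts, rx$educt_atoms,
                 function(p, a) note_pool(p, atoms_of(a)))
    purrr::walk2(rx$products, rx$product_atoms,
                 function(p, a) note_pool(p, atoms_of(a)))
  }
  reactions <- lapply(rxrows, function(rx) {
    letters_in <- strsplit(paste0(sub("^#", "", rx$educt_atoms),
                                  collapse = ""), "")[[1]]
    prods <- list()
    for (j in seq_along(rx$products)) {
      pl <- strsplit(sub("^#", "", rx$product_atoms[j]), "")[[1]]
      pos <- match(pl, letters_in)
      if (anyNA(pos)) {
        stop("reaction '", rx$id, "': product atom code '",
             rx$product_atoms[j],
             "' uses letters not present on the educt side",
             call. = FALSE)
      }
      prods[[length(prods) + 1L]] <- pos
    }
    names(prods) <- rx$products
    flux_reaction(rx$id, rx$educts, prods,
                  reversible = rx$id %in% xch_free)
  })
  all_pools <- names(pool_atoms_seen)
  consumed <- unique(unlist(lapply(rxrows, `[[`, "educts")))
  produced <- unique(unlist(lapply(rxrows, `[[`, "products")))
  pools <- lapply(all_pools, function(p) {
    role <- if (p %in% names(feeds)) "input"
            else if (!p %in% consumed) "output"
            else "intermediate"
    flux_pool(p, pool_atoms_seen[[p]], role = role,
              feed = if (role == "input") feeds[[p]] else NULL)
  })
  network <- flux_network(pools, reactions, flux_ub = flux_ub)

  # ---- measurements ----
  groups <- list()
  if ("LABEL_MEASUREMENTS" %in% names(sections)) {
    tab <- list()
    pool <- NA_character_
    for (r in fields(sections$LABEL_MEASUREMENTS)) {
      if (length(r) == 0L || identical(r[1], "META_NAME")) next
      if (nchar(r[1]) > 0L) pool <- r[1]
      key <- paste(pool, r[2], sep = "\r")
      tab[[key]] <- c(tab[[key]], list(list(
        value = as.numeric(r[3]), sd = as.numeric(r[4]), pattern = r[5])))
    }
    for (key in names(tab)) {
      pool <- strsplit(key, "\r", fixed = TRUE)[[1]][1]
      rowsk <- tab[[key]]
      groups[[length(groups) + 1L]] <- label_group(
        "NMR-1H", pool,
        specs = vapply(rowsk, `[[`, character(1), "pattern"),
        values = vapply(rowsk, `[[`, numeric(1), "value"),
        sd = vapply(rowsk, `[[`, numeric(1), "sd"))
    }
  }
  if ("MASS_SPECTROMETRY" %in% names(sections)) {
    tab <- list()
    pool <- NA_character_; frag <- ""
    for (r in fields(sections$MASS_SPECTROMETRY)) {
      if (length(r) == 0L || identical(r[1], "META_NAME")) next
      if (nchar(r[1]) > 0L) { pool <- r[1]; frag <- r[2] }
      key <- paste(pool, frag, sep = "\r")
      tab[[key]] <- c(tab[[key]], list(list(
        weight = as.integer(r[3]), value = as.numeric(r[4]),
        sd = as.numeric(r[5]),
        formula = if (length(r) >= 6L && nchar(r[6]) > 0L) r[6] else NULL)))
    }
    for (key in names(tab)) {
      parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
      pool <- parts[1]
      frag <- if (length(parts) > 1L) parts[2] else ""
      atoms <- parse_fragment(frag)
      rowsk <- tab[[key]]
      formula <- rowsk[[1]]$formula
      groups[[length(groups) + 1L]] <- label_group(
        "MS", pool,
        specs = vapply(rowsk, `[[`, integer(1), "weight"),
        values = vapply(rowsk, `[[`, numeric(1), "value"),
        sd = vapply(rowsk, `[[`, numeric(1), "sd"),
        atoms = atoms, formula = formula)
    }
  }
  fluxes <- tibble::tibble(flux = character(0), value = numeric(0),
                           sd = numeric(0))
  if ("FLUX_MEASUREMENTS" %in% names(sections)) {
    for (r in fields(sections$FLUX_MEASUREMENTS)) {
      if (length(r) == 0L || identical(r[1], "FLUX_NAME")) next
      fluxes <- dplyr::bind_rows(
        fluxes, tibble::tibble(flux = r[1], value = as.numeric(r[2]),
                               sd = as.numeric(r[3])))
    }
  }
  # fixed net fluxes imported as tight flux measurements (absolute scale)
  if (nrow(net_fixed) > 0L) {
    extra <- net_fixed[!net_fixed$flux %in% fluxes$flux, , drop = FALSE]
    if (nrow(extra) > 0L) {
      fluxes <- dplyr::bind_rows(
        fluxes, tibble::tibble(flux = extra$flux, value = extra$value,
                               sd = 0.001))
    }
  }
  for (g in groups) {
    if (!g$pool %in% network$pools$name) {
      stop("measurement on unknown pool '", g$pool, "'", call. = FALSE)
    }
  }
  unknown_flux <- setdiff(fluxes$flux, network$flux_names)
  if (length(unknown_flux) > 0L) {
    stop("flux measurement on unknown flux: ",
         paste(unknown_flux, collapse = ", "), call. = FALSE)
  }
  list(network = network,
       measurements = measurement_set(groups = groups, fluxes = fluxes))
}

parse_fragment <- function(frag) {
  frag <- trimws(frag)
  if (nchar(frag) == 0L || identical(frag, "*")) return(NULL)
  parts <- strsplit(frag, ",", fixed = TRUE)[[1]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
      out <- c(out, ab[1]:ab[2])
    } else {
      out <- c(out, as.integer(p))
    }
  }
  out
}

#' Read an FTBL model file
#'
#' @param path file path.
#' @param ... passed to [parse_ftbl()].
#' @return list with `network` and `measurements`.
#' @export
read_ftbl <- function(path, ...) {
  parse_ftbl(readLines(path, warn = FALSE), ...)
}

#' Write a network (and measurements) as an FTBL document
#'
#' Emits the dialect [parse_ftbl()] reads; `parse_ftbl(write_ftbl(...))`
#' round-trips the model structurally.
#'
#' @param network a [flux_network()].
#' @param measurements optional [measurement_set()].
#' @param path optional output file; when `NULL` the document is returned
#'   as a character vector of lines.
#' @return the lines, invisibly when written to a file.
#' @export
write_ftbl <- function(network, measurements = NULL, path = NULL) {
  code_letters <- c(LETTERS, letters)
  out <- c("NETWORK",
           "\tFLUX_NAME\tEDUCT_1\tEDUCT_2\tPRODUCT_1\tPRODUCT_2")
  natoms <- stats::setNames(network$pools$n_atoms, network$pools$name)
  for (rx in network$reactions) {
    ks <- natoms[rx$substrates]
    offs <- cumsum(c(0, ks))
    educt_codes <- vapply(seq_along(rx$substrates), function(s) {
      paste0("#", paste0(code_letters[offs[s] + seq_len(ks[s])],
                         collapse = ""))
    }, character(1))
    prod_codes <- vapply(rx$products, function(pos) {
      paste0("#", paste0(code_letters[pos], collapse = ""))
    }, character(1))
    pad <- function(v, n) c(v, rep("", n - length(v)))
    out <- c(out,
             paste(c("", rx$id, pad(rx$substrates, 2L),
                     pad(names(rx$products), 2L)), collapse = "\t"),
             paste(c("", "", pad(educt_codes, 2L),
                     pad(prod_codes, 2L)), collapse = "\t"))
  }
  out <- c(out, "FLUXES", "\tXCH", "\t\tNAME\tFCD\tVALUE")
  for (rx in network$reactions) {
    out <- c(out, paste0("\t\t", rx$id, "\t",
                         if (rx$reversible) "F" else "C\t0"))
  }
  inputs <- which(network$pools$role == "input")
  if (length(inputs) > 0L) {
    out <- c(out, "LABEL_INPUT", "\tMETA_NAME\tISOTOPOMER\tVALUE")
    for (i in inputs) {
      feed <- network$pools$feed[[i]]
      k <- network$pools$n_atoms[i]
      nz <- which(feed > 0)
      labs <- word_to_string(nz - 1L, k)
      first <- TRUE
      for (j in seq_along(nz)) {
        out <- c(out, paste0("\t",
                             if (first) network$pools$name[i] else "",
                             "\t#", labs[j], "\t",
                             format(feed[nz[j]], digits = 15)))
        first <- FALSE
      }
    }
  }
  if (!is.null(measurements)) {
    enr <- Filter(function(g) g$kind != "MS", measurements$groups)
    if (length(enr) > 0L) {
      out <- c(out, "LABEL_MEASUREMENTS",
               "\tMETA_NAME\tGROUP\tVALUE\tDEVIATION\tCUM_CONSTRAINT")
      for (gi in seq_along(enr)) {
        g <- enr[[gi]]
        for (r in seq_along(g$specs)) {
          out <- c(out, paste0("\t", if (r == 1L) g$pool else "", "\t",
                               gi, "\t", format(g$values[r], digits = 15),
                               "\t", format(g$sd[r], digits = 15), "\t",
                               if (grepl("^#", g$specs[r])) g$specs[r]
                               else paste0("#", g$specs[r])))
        }
      }
    }
    msg <- Filter(function(g) g$kind == "MS", measurements$groups)
    if (length(msg) > 0L) {
      out <- c(out, "MASS_SPECTROMETRY",
               "\tMETA_NAME\tFRAGMENT\tWEIGHT\tVALUE\tDEVIATION\tFORMULA")
      for (g in msg) {
        frag <- if (is.null(g$atoms)) "" else
          paste(g$atoms, collapse = ",")
        for (r in seq_along(g$specs)) {
          out <- c(out, paste0("\t", if (r == 1L) g$pool else "", "\t",
                               if (r == 1L) frag else "", "\t",
                               g$specs[r], "\t",
                               format(g$values[r], digits = 15), "\t",
                               format(g$sd[r], digits = 15), "\t",
                               if (r == 1L && !is.null(g$formula))
                                 g$formula else ""))
        }
      }
    }
    if (nrow(measurements$fluxes) > 0L) {
      out <- c(out, "FLUX_MEASUREMENTS", "\tFLUX_NAME\tVALUE\tDEVIATION")
      for (r in seq_len(nrow(measurements$fluxes))) {
        out <- c(out, paste0("\t", measurements$fluxes$flux[r], "\t",
                             format(measurements$fluxes$value[r],
                                    digits = 15), "\t",
                             format(measurements$fluxes$sd[r],
                                    digits = 15)))
      }
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
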