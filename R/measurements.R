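#' Declare one group of labeling measurements
#'
#' A group is a set of quantities measured on the same pool (or fragment)
#' whose raw intensities share an unknown proportionality constant. For
#' `"MS"` and `"NMR-13C"` groups only the relative intensities carry
#' information and the measured fractions are formed internally as
#' y_j = m_j / sum(m); for `"NMR-1H"` positional enrichments the values
#' are absolute fractional enrichments (1H spectra resolve both isotopes,
#' so they normalize directly).
#'
#' @param kind `"MS"`, `"NMR-1H"` or `"NMR-13C"`.
#' @param pool measured metabolite.
#' @param specs for MS, the mass-isotopomer weights (integers, M+k);
#'   otherwise label patterns over the pool's atoms such as `"#1xxxx"`
#'   (positional enrichment) or `"#011x"` (multiplet-style pattern).
#' @param values raw intensities (MS/13C) or fractional enrichments (1H).
#' @param sd measurement standard deviation(s), recycled across rows;
#'   must be positive.
#' @param atoms for MS, the fragment's atom positions within the pool
#'   (default: the full carbon backbone).
#' @param formula optional molecular formula of the measured (derivatized)
#'   fragment, e.g. `"C9H20O5NSi2"`, enabling natural-abundance
#'   correction of non-backbone atoms.
#' @param normalized whether the values are already on a fraction scale
#'   (informational; the residual model only ever uses ratios for MS/13C
#'   groups).
#' @return a `label_group` object.
#' @export
label_group <- function(kind = c("MS", "NMR-1H", "NMR-13C"), pool, specs,
                        values, sd, atoms = NULL, formula = NULL,
                        normalized = TRUE) {
  kind <- match.arg(kind)
  stopifnot(length(specs) == length(values), length(values) >= 1L)
  sd <- rep_len(as.numeric(sd), length(values))
  if (any(!is.finite(sd) | sd <= 0)) {
    stop("measurement standard deviations must be positive", call. = FALSE)
  }
  if (kind == "MS") {
    specs <- as.integer(specs)
    if (any(specs < 0L)) stop("mass weights must be >= 0", call. = FALSE)
  } else {
    specs <- as.character(specs)
  }
  structure(list(kind = kind, pool = pool, specs = specs,
                 values = as.numeric(values), sd = sd,
                 atoms = if (!is.null(atoms)) as.integer(atoms) else NULL,
                 formula = formula, normalized = isTRUE(normalized)),
            class = "label_group")
}

#' Bundle label groups and flux measurements
#'
#' @param groups list of [label_group()] objects.
#' @param fluxes tibble with columns `flux`, `value`, `sd`: absolute flux
#'   measurements (at least one is needed to identify the flux scale,
#'   since steady-state labeling is invariant to rescaling all fluxes).
#' @return a `measurement_set` object.
#' @export
measurement_set <- function(groups = list(),
                            fluxes = tibble::tibble(flux = character(0),
                                                    value = numeric(0),
                                                    sd = numeric(0))) {
  if (inherits(groups, "label_group")) groups <- list(groups)
  stopifnot(all(vapply(groups, inherits, logical(1), "label_group")))
  fluxes <- tibble::as_tibble(fluxes)
  stopifnot(all(c("flux", "value", "sd") %in% names(fluxes)))
  if (nrow(fluxes) > 0L && any(fluxes$sd <= 0)) {
    stop("flux measurement standard deviations must be positive",
         call. = FALSE)
  }
  structure(list(groups = groups, fluxes = fluxes),
            class = "measurement_set")
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set>", length(x$groups), "label group(s),",
      nrow(x$fluxes), "flux measurement(s)\n")
  for (g in x$groups) {
    cat("  ", g$kind, " ", g$pool, ": ", length(g$values), " rows\n",
        sep = "")
  }
  invisible(x)
}

#' Measurement rows as a tibble
#'
#' @param x a `measurement_set`.
#' @param ... unused.
#' @method as_tibble measurement_set
#' @export
as_tibble.measurement_set <- function(x, ...) {
  lab <- purrr::imap_dfr(x$groups, function(g, i) {
    tibble::tibble(type = "label", group = i, kind = g$kind,
                   pool = g$pool, spec = as.character(g$specs),
                   value = g$values, sd = g$sd)
  })
  flx <- if (nrow(x$fluxes) > 0L) {
    tibble::tibble(type = "flux", group = NA_integer_, kind = "flux",
                   pool = x$fluxes$flux, spec = x$fluxes$flux,
                   value = x$fluxes$value, sd = x$fluxes$sd)
  } else NULL
  dplyr::bind_rows(lab, flx)
}

#' Fluxomer transform rows of a measurement group
#'
#' Designates a reporter outflux of the measured pool (the first declared
#' consumer) and builds one sparse row per measured quantity summing the
#' reporter's fluxomers whose label words match it: mass isotopomer M+k
#' sums all fragment words of weight k, a pattern such as `#1xxxx` sums
#' the matching wildcard set. At steady state all outfluxes of a pool
#' carry identical label proportions, so the reporter choice only scales
#' the rows, which the scaling-invariant residual cancels. When the group
#' carries a molecular formula the rows are premultiplied by the
#' natural-abundance correction matrix.
#'
#' @param group a [label_group()].
#' @param system a `fluxomer_system`.
#' @param correction apply the natural-abundance correction when a
#'   formula is present.
#' @return list with sparse matrix `T` (rows x m), the full reporter sum
#'   row `total`, and the reporter flux name.
#' @export
build_group_transform <- function(group, system, correction = TRUE) {
  network <- system$network
  pool <- group$pool
  if (!pool %in% network$pools$name) {
    stop("measurement on unknown pool '", pool, "'", call. = FALSE)
  }
  cons <- pool_consumers(network, pool)
  if (length(cons) == 0L) {
    stop("measured pool '", pool, "' has no outgoing flux", call. = FALSE)
  }
  reporter <- cons[1]
  fx <- network$fluxes[[reporter]]
  slot <- which(fx$substrates == pool)[1]
  rows <- which(system$index$flux == reporter)
  k <- pool_atoms(network, pool)
  sub <- extract_subword(system$index$word[rows], fx$slot_pos[[slot]])
  atoms <- group$atoms %||% seq_len(k)
  if (!all(atoms %in% seq_len(k))) {
    stop("fragment atoms of group on '", pool,
         "' are not a subset of the pool's ", k, " atoms", call. = FALSE)
  }
  frag <- extract_subword(sub, atoms)
  nr <- length(group$specs)
  trip_i <- integer(0); trip_j <- integer(0)
  for (r in seq_len(nr)) {
    if (group$kind == "MS") {
      sel <- word_weight(frag, length(atoms)) == group$specs[r]
    } else {
      sel <- sub %in% words_matching(group$specs[r], k)
    }
    trip_i <- c(trip_i, rep.int(r, sum(sel)))
    trip_j <- c(trip_j, rows[sel])
  }
  Tm <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = 1,
                             dims = c(nr, system$m))
  if (correction && !is.null(group$formula) && group$kind == "MS") {
    Cm <- natural_abundance_correction(group$formula, nr,
                                       n_backbone = length(atoms))
    Tm <- methods::as(Cm %*% Tm, "CsparseMatrix")
  }
  total <- Matrix::sparseMatrix(i = rep.int(1L, length(rows)), j = rows,
                                x = 1, dims = c(1L, system$m))
  list(T = Tm, total = total, reporter = reporter)
}

#' Natural-abundance correction matrix from a molecular formula
#'
#' Builds the lower-triangular convolution matrix that maps a
#' backbone-carbon mass-isotopomer distribution to the observed one when
#' the fragment additionally carries naturally labeled atoms: the first
#' `n_backbone` carbons are the isotopically tracked skeleton and every
#' remaining atom contributes its natural heavy-isotope mass shifts.
#' Column c holds the mass-shift distribution added to a backbone species
#' of mass M+c, truncated to the measured window, so columns are
#' nonnegative with sums at most 1.
#'
#' @param formula molecular formula string over C, H, N, O, P, S, Si,
#'   e.g. `"C11H26N O2 Si2"` (spaces ignored).
#' @param n_rows number of measured mass rows (M+0 ... M+(n_rows-1)).
#' @param n_backbone number of tracked backbone carbons (excluded from
#'   the correction).
#' @param abundances optional override of the natural heavy-isotope
#'   abundance table; a named list of per-element mass-shift
#'   distributions starting at shift 0.
#' @return a dense n_rows-by-n_rows lower-triangular matrix.
#' @export
natural_abundance_correction <- function(formula, n_rows, n_backbone = 0L,
                                         abundances = NULL) {
  counts <- parse_formula(formula)
  iso <- abundances %||% fia_isotope_abundances()
  if ("C" %in% names(counts)) {
    if (counts[["C"]] < n_backbone) {
      stop("formula has fewer carbons than the tracked backbone",
           call. = FALSE)
    }
    counts[["C"]] <- counts[["C"]] - n_backbone
  } else if (n_backbone > 0L) {
    stop("formula has fewer carbons than the tracked backbone",
         call. = FALSE)
  }
  pmf <- 1
  for (el in names(counts)) {
    if (!el %in% names(iso)) {
      stop("unknown element symbol '", el, "'", call. = FALSE)
    }
    for (i in seq_len(counts[[el]])) pmf <- convolve_pmf(pmf, iso[[el]])
  }
  out <- matrix(0, n_rows, n_rows)
  for (cc in seq_len(n_rows)) {
    span <- cc:n_rows
    shifts <- span - cc + 1L
    vals <- ifelse(shifts <= length(pmf), pmf[shifts], 0)
    out[span, cc] <- vals
  }
  out
}

#' Natural heavy-isotope abundance table
#'
#' Mass-shift distributions (starting at shift 0) for the elements the
#' correction supports: 13C 0.0107; 2H 0.000115; 15N 0.00364; 17O/18O
#' 0.00038/0.00205; 33S/34S/36S 0.0075/0.0425/0.0001; 29Si/30Si
#' 0.0468/0.0310; P monoisotopic.
#'
#' @return named list of numeric mass-shift distributions.
#' @export
fia_isotope_abundances <- function() {
  list(
    C = c(1 - 0.0107, 0.0107),
    H = c(1 - 0.000115, 0.000115),
    N = c(1 - 0.00364, 0.00364),
    O = c(1 - 0.00038 - 0.00205, 0.00038, 0.00205),
    S = c(1 - 0.0075 - 0.0425 - 0.0001, 0.0075, 0.0425, 0, 0.0001),
    Si = c(1 - 0.0468 - 0.0310, 0.0468, 0.0310),
    P = 1
  )
}

convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) {
    idx <- i:(i + length(a) - 1L)
    out[idx] <- out[idx] + a * b[i]
  }
  out
}

parse_formula <- function(formula) {
  s <- gsub("[[:space:]]", "", formula)
  if (nchar(s) == 0L) return(stats::setNames(integer(0), character(0)))
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  parts <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*)", s))[[1]]
  if (sum(nchar(parts)) != nchar(s)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  counts <- integer(0)
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    num <- sub("^[A-Z][a-z]?", "", p)
    n <- if (nchar(num) == 0L) 1L else as.integer(num)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Assemble the scaling-invariant measurement objective
#'
#' Stacks every measurement into the affine form `A x - b` whose squared
#' norm is the fit objective. Label rows enter as
#' (T_j - y_hat_j * d) / sd_j, where d is the group denominator row (the
#' group sum for MS/13C groups, the full reporter sum for 1H
#' enrichments), so they vanish under any rescaling of a group's raw
#' intensities and have b = 0. Flux-measurement rows are U[f, ] / sd with
#' b = value / sd, the only nonzero entries of b.
#'
#' @param measurements a [measurement_set()].
#' @param system a `fluxomer_system`.
#' @param correction apply natural-abundance corrections where formulas
#'   are present.
#' @param cov_weighting use the full within-group residual covariance
#'   (whitening by its symmetric inverse square root on its range)
#'   instead of the default diagonal 1/sd weighting.
#' @return a `residual_model` with sparse `A`, numeric `b`, and a row
#'   info tibble.
#' @export
assemble_objective <- function(measurements, system, correction = TRUE,
                               cov_weighting = FALSE) {
  if (length(measurements$groups) == 0L &&
      nrow(measurements$fluxes) == 0L) {
    stop("no measurements: the flux estimation problem is unidentifiable",
         call. = FALSE)
  }
  blocks <- list()
  info <- list()
  for (gi in seq_along(measurements$groups)) {
    g <- measurements$groups[[gi]]
    tr <- build_group_transform(g, system, correction = correction)
    yhat <- group_fractions(g)
    if (g$kind == "NMR-1H") {
      dsum <- tr$total
    } else {
      cs <- Matrix::colSums(tr$T)
      nz <- which(cs > 0)
      dsum <- Matrix::sparseMatrix(i = rep.int(1L, length(nz)), j = nz,
                                   x = cs[nz], dims = c(1L, system$m))
    }
    R <- tr$T - methods::as(Matrix::Matrix(yhat, ncol = 1), "CsparseMatrix") %*% dsum
    W <- if (cov_weighting) {
      whiten_group(yhat, g$sd)
    } else {
      Matrix::Diagonal(x = 1 / g$sd)
    }
    blocks[[length(blocks) + 1L]] <- methods::as(W %*% R, "CsparseMatrix")
    info[[length(info) + 1L]] <- tibble::tibble(
      type = "label", group = gi, kind = g$kind, pool = g$pool,
      spec = as.character(g$specs), value = g$values, yhat = yhat,
      sd = g$sd)
  }
  nflux <- nrow(measurements$fluxes)
  bvals <- numeric(0)
  if (nflux > 0L) {
    unknown <- setdiff(measurements$fluxes$flux, system$flux_names)
    if (length(unknown) > 0L) {
      stop("flux measurement on unknown flux: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    Wf <- Matrix::Diagonal(x = 1 / measurements$fluxes$sd)
    blocks[[length(blocks) + 1L]] <- methods::as(
      Wf %*% system$U[measurements$fluxes$flux, , drop = FALSE],
      "CsparseMatrix")
    bvals <- measurements$fluxes$value / measurements$fluxes$sd
    info[[length(info) + 1L]] <- tibble::tibble(
      type = "flux", group = NA_integer_, kind = "flux",
      pool = measurements$fluxes$flux, spec = measurements$fluxes$flux,
      value = measurements$fluxes$value, yhat = NA_real_,
      sd = measurements$fluxes$sd)
  }
  A <- do.call(rbind, blocks)
  b <- c(numeric(nrow(A) - nflux), bvals)
  structure(list(A = A, b = b, info = dplyr::bind_rows(info),
                 measurements = measurements,
                 correction = correction,
                 cov_weighting = cov_weighting),
            class = "residual_model")
}

# measured fractions of one group
group_fractions <- function(g) {
  if (g$kind == "NMR-1H") return(g$values)
  tot <- sum(g$values)
  if (tot <= 0) {
    stop("group on pool '", g$pool, "' has non-positive total intensity",
         call. = FALSE)
  }
  g$values / tot
}

# whitening transform for the correlated within-group residual
# eps = (I - yhat 1^T) e, Cov = (I - yhat 1^T) D(sd^2) (.)^T; complete
# groups make Cov singular, so whiten on its range via eigendecomposition
whiten_group <- function(yhat, sd) {
  P <- diag(length(yhat)) - outer(yhat, rep(1, length(yhat)))
  Cov <- P %*% diag(sd^2, length(sd)) %*% t(P)
  e <- eigen(Cov, symmetric = TRUE)
  keep <- e$values > max(e$values) * 1e-10
  W <- t(e$vectors[, keep, drop = FALSE]) / sqrt(e$values[keep])
  Matrix::Matrix(W)
}

#' Weighted measurement residuals at a fluxomer vector
#'
#' @param model a `residual_model` from [assemble_objective()].
#' @param x fluxomer vector.
#' @return numeric residual vector (A x - b).
#' @export
model_residuals <- function(model, x) {
  as.numeric(model$A %*% x) - model$b
}
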