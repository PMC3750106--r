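#' Enumerate the fluxomer index space of a network
#'
#' A fluxomer is the rate at which one unidirectional flux carries one
#' specific labeling pattern of its consumed atoms. For a flux consuming k
#' tracked atoms this emits 2^k fluxomers in increasing label-word order;
#' fluxes are visited in declaration order (forward direction immediately
#' followed by its reverse).
#'
#' @param network a [flux_network()].
#' @param max_atoms refuse reactions consuming more than this many tracked
#'   atoms (the index grows as 2^k).
#' @return a tibble with columns `flux`, `word` (integer label word),
#'   `label` (printed word), `k`.
#' @export
enumerate_fluxomers <- function(network, max_atoms = 20L) {
  parts <- lapply(network$fluxes, function(fx) {
    if (fx$k > max_atoms) {
      stop("flux '", fx$flux, "' consumes ", fx$k,
           " tracked atoms (> max_atoms = ", max_atoms, ")", call. = FALSE)
    }
    w <- 0:(2^fx$k - 1L)
    tibble::tibble(flux = fx$flux, word = w,
                   label = word_to_string(w, fx$k), k = fx$k)
  })
  dplyr::bind_rows(parts)
}

#' Build the fluxomer system matrices
#'
#' Constructs the constant matrices of the fluxomer balance equations for a
#' validated network: the flux-summation matrix `U` (u = U x), the source
#' selection matrices `H1`/`H2` (one row per fluxomer; the row of `H1`
#' sums all incoming fluxomers that deliver exactly the label pattern the
#' fluxomer draws from its first ("left") source pool, `H2` likewise for
#' the second), the flux-selection matrices `G1`/`G2`/`G3` behind the
#' rational prefactor g(u) = (G1 u) / ((G2 u) o (G3 u)), and the LU-reduced
#' factors of the stacked source matrix.
#'
#' The fluxomer vector is augmented with one constant slot fixed at 1 and
#' the flux vector with one unit flux: single-substrate fluxomers point
#' their `H2` row at the constant slot and their `G3` row at the unit flux,
#' so the steady-state relation x = g(u) o (H1 x) o (H2 x) is exactly
#' trilinear for every row. Fluxomers of fluxes that consume an input
#' substrate are boundary rows: their `G1` row carries the feed fraction of
#' their label word on the uptake flux and both `H` rows point at the
#' constant slot, which clamps them to u_uptake * feed fraction.
#' Internally the constant slot is kept as an additive offset (`h1c`,
#' `h2c`) rather than a matrix column.
#'
#' @param network a [flux_network()].
#' @param reduce logical; compute the sparsity-increasing LU factorization
#'   of the stacked source matrix (see [lu_reduce()]).
#' @param max_atoms passed to [enumerate_fluxomers()].
#' @return a `fluxomer_system` object.
#' @export
build_fluxomer_system <- function(network, reduce = TRUE, max_atoms = 20L) {
  index <- enumerate_fluxomers(network, max_atoms)
  m <- nrow(index)
  flux_names <- network$flux_names
  n <- length(flux_names)
  # row ranges of each flux in the index
  offs <- c(0L, cumsum(2^vapply(network$fluxes, `[[`, integer(1), "k")))
  row_of <- function(flux) {
    j <- match(flux, flux_names)
    (offs[j] + 1L):offs[j + 1L]
  }

  Ut <- Matrix::sparseMatrix(i = match(index$flux, flux_names),
                             j = seq_len(m), x = 1,
                             dims = c(n, m),
                             dimnames = list(flux_names, NULL))

  roles <- stats::setNames(network$pools$role, network$pools$name)

  # triplet accumulators for H1/H2 (m x m) and const offsets
  H_tr <- list(list(i = integer(0), j = integer(0)),
               list(i = integer(0), j = integer(0)))
  hc <- list(numeric(m), numeric(m))
  # G triplets (m x n) and aug-flux offsets (value of the n+1 column)
  G_tr <- list(list(i = integer(0), j = integer(0), x = numeric(0)),
               list(i = integer(0), j = integer(0), x = numeric(0)),
               list(i = integer(0), j = integer(0), x = numeric(0)))
  gc <- list(numeric(m), numeric(m), numeric(m))

  add_G <- function(slot, i, j, x) {
    G_tr[[slot]]$i <<- c(G_tr[[slot]]$i, i)
    G_tr[[slot]]$j <<- c(G_tr[[slot]]$j, j)
    G_tr[[slot]]$x <<- c(G_tr[[slot]]$x, x)
  }

  producers <- lapply(stats::setNames(network$pools$name,
                                      network$pools$name),
                      function(p) pool_producers(network, p))
  consumers <- lapply(stats::setNames(network$pools$name,
                                      network$pools$name),
                      function(p) pool_consumers(network, p))

  boundary <- logical(m)
  for (fx in network$fluxes) {
    rows <- row_of(fx$flux)
    jflux <- match(fx$flux, flux_names)
    words <- index$word[rows]
    is_boundary <- any(roles[fx$substrates] == "input")
    boundary[rows] <- is_boundary
    # G1: own flux; boundary rows weight it by the feed fraction
    if (is_boundary) {
      pool <- fx$substrates[1]
      feed <- network$pools$feed[[match(pool, network$pools$name)]]
      add_G(1L, rows, rep(jflux, length(rows)), feed[words + 1L])
      gc[[2]][rows] <- 1
      gc[[3]][rows] <- 1
      hc[[1]][rows] <- 1
      hc[[2]][rows] <- 1
      next
    }
    add_G(1L, rows, rep(jflux, length(rows)), rep(1, length(rows)))
    for (slot in c(1L, 2L)) {
      if (slot > length(fx$substrates)) {
        # single-source: constant slot / unit augmentation flux
        hc[[slot]][rows] <- 1
        gc[[slot + 1L]][rows] <- 1
        next
      }
      pool <- fx$substrates[slot]
      cons <- consumers[[pool]]
      add_G(slot + 1L, rep(rows, length(cons)),
            rep(match(cons, flux_names), each = length(rows)),
            rep(1, length(rows) * length(cons)))
      req <- extract_subword(words, fx$slot_pos[[slot]])
      for (pr in producers[[pool]]) {
        prows <- row_of(pr$flux)
        delivered <- extract_subword(index$word[prows], pr$from)
        ii <- split(rows, req)
        jj <- split(prows, delivered)
        common <- intersect(names(ii), names(jj))
        for (v in common) {
          ni <- length(ii[[v]]); nj <- length(jj[[v]])
          H_tr[[slot]]$i <- c(H_tr[[slot]]$i, rep(ii[[v]], times = nj))
          H_tr[[slot]]$j <- c(H_tr[[slot]]$j, rep(jj[[v]], each = ni))
        }
      }
    }
  }

  H1 <- Matrix::sparseMatrix(i = H_tr[[1]]$i, j = H_tr[[1]]$j,
                             x = 1, dims = c(m, m))
  H2 <- Matrix::sparseMatrix(i = H_tr[[2]]$i, j = H_tr[[2]]$j,
                             x = 1, dims = c(m, m))
  G1 <- Matrix::sparseMatrix(i = G_tr[[1]]$i, j = G_tr[[1]]$j,
                             x = G_tr[[1]]$x, dims = c(m, n))
  G2 <- Matrix::sparseMatrix(i = G_tr[[2]]$i, j = G_tr[[2]]$j,
                             x = G_tr[[2]]$x, dims = c(m, n))
  G3 <- Matrix::sparseMatrix(i = G_tr[[3]]$i, j = G_tr[[3]]$j,
                             x = G_tr[[3]]$x, dims = c(m, n))

  sys <- structure(list(network = network, index = index, m = m, n = n,
                        flux_names = flux_names,
                        U = Ut, H1 = H1, H2 = H2,
                        h1c = hc[[1]], h2c = hc[[2]],
                        G1 = G1, G2 = G2, G3 = G3,
                        g2c = gc[[2]], g3c = gc[[3]],
                        boundary = boundary,
                        lu = NULL),
                   class = "fluxomer_system")
  if (reduce) sys$lu <- lu_reduce(H1, H2)
  sys
}

#' @export
print.fluxomer_system <- function(x, ...) {
  cat("<fluxomer_system> m =", x$m, "fluxomers, n =", x$n, "fluxes\n")
  cat("  nnz(H1) =", Matrix::nnzero(x$H1),
      " nnz(H2) =", Matrix::nnzero(x$H2), "\n")
  if (!is.null(x$lu) && x$lu$ok) {
    cat("  LU-reduced: nnz(L1) + nnz(L2) + nnz(UH) =",
        Matrix::nnzero(x$lu$L1) + Matrix::nnzero(x$lu$L2) +
          Matrix::nnzero(x$lu$UH), "\n")
  }
  invisible(x)
}

#' Resolve a wildcard fluxomer query to index rows
#'
#' @param system a `fluxomer_system`.
#' @param flux flux name.
#' @param pattern label word with optional `x` wildcards, atom-1 leftmost.
#' @return integer vector of rows into the fluxomer index.
#' @export
fluxomer_rows <- function(system, flux, pattern) {
  rows <- which(system$index$flux == flux)
  if (length(rows) == 0L) stop("unknown flux '", flux, "'", call. = FALSE)
  k <- system$index$k[rows[1]]
  rows[system$index$word[rows] %in% words_matching(pattern, k)]
}

#' Sum fluxomers matching a wildcard pattern
#'
#' Evaluates wildcard sums such as `f1(01xx)` on a fluxomer vector.
#'
#' @param system a `fluxomer_system`.
#' @param x fluxomer vector of length `system$m`.
#' @param flux flux name.
#' @param pattern wildcard label pattern.
#' @return the summed rate.
#' @export
fluxomer_sum <- function(system, x, flux, pattern) {
  sum(x[fluxomer_rows(system, flux, pattern)])
}

#' Sparsity-increasing LU reduction of the stacked source matrices
#'
#' Stacks the two source-selection matrices into `H = rbind(H1, H2)` and
#' computes a row/column-pivoted LU factorization `H[p, q] = L %*% UH`
#' with `L` lower trapezoidal and `UH` square, upper triangular and
#' invertible. Splitting `L` back into the `H1` and `H2` halves gives
#' `H1 = L1 %*% UH` and `H2 = L2 %*% UH` (exactly, up to roundoff), so the
#' change of variables y = UH x turns the steady-state propagation into a
#' much sparser system. Pivots are chosen Markowitz-style (minimum row
#' fill, then sparsest column, then largest magnitude), which on labeling
#' networks mostly eliminates the many duplicated source rows outright.
#'
#' @param H1,H2 m-by-m sparse source matrices (constant column excluded).
#' @return a list with `L1`, `L2`, `UH` (sparse matrices), the pivot
#'   orders `rowperm`, `colperm`, and `ok`. If the stack is structurally
#'   rank deficient the identity transform is returned with `ok = FALSE`
#'   and a warning.
#' @export
lu_reduce <- function(H1, H2) {
  m <- ncol(H1)
  stopifnot(nrow(H1) == m, identical(dim(H1), dim(H2)))
  fallback <- function() {
    warning("stacked source matrix is structurally singular; ",
            "falling back to the identity transform", call. = FALSE)
    list(L1 = methods::as(H1, "CsparseMatrix"),
         L2 = methods::as(H2, "CsparseMatrix"),
         UH = Matrix::Diagonal(m), rowperm = integer(0),
         colperm = integer(0), ok = FALSE)
  }
  res <- sparse_tall_lu(rbind(H1, H2), m)
  if (is.null(res)) return(fallback())
  L <- Matrix::sparseMatrix(i = res$li, j = res$lj, x = res$lx,
                            dims = c(2L * m, m))
  UH <- Matrix::sparseMatrix(i = res$ui, j = res$uj, x = res$ux,
                             dims = c(m, m))
  list(L1 = L[seq_len(m), , drop = FALSE],
       L2 = L[m + seq_len(m), , drop = FALSE],
       UH = UH, rowperm = res$rowperm, colperm = res$colperm, ok = TRUE)
}

# Right-looking sparse Gaussian elimination of a tall (M x m) matrix with
# full row/column pivoting. Returns triplets of L (M x m) and U (m x m,
# upper triangular under the recorded column order) or NULL on rank
# deficiency. Entries below `tol` after an update are dropped, which also
# removes the exactly cancelled pivot-column entries.
sparse_tall_lu <- function(Hstack, m, tol = 1e-12) {
  Ht <- methods::as(Hstack, "TsparseMatrix")
  M <- nrow(Hstack)
  rfac <- factor(Ht@i + 1L, levels = seq_len(M))
  rowsj <- split(Ht@j + 1L, rfac)
  rowsv <- split(Ht@x, rfac)
  col_rows <- split(Ht@i + 1L, factor(Ht@j + 1L, levels = seq_len(m)))
  active <- rep(TRUE, M)
  rnnz <- lengths(rowsj)
  colpiv <- rep(FALSE, m)
  cap <- max(64L, 4L * length(Ht@x))
  li <- integer(cap); lj <- integer(cap); lx <- numeric(cap); nl <- 0L
  ui <- integer(cap); uj <- integer(cap); ux <- numeric(cap); nu <- 0L
  push_l <- function(i, j, x) {
    k <- length(i)
    if (nl + k > length(li)) {
      newcap <- max(2L * length(li), nl + k)
      length(li) <<- newcap; length(lj) <<- newcap; length(lx) <<- newcap
    }
    idx <- nl + seq_len(k)
    li[idx] <<- i; lj[idx] <<- j; lx[idx] <<- x; nl <<- nl + k
  }
  push_u <- function(i, j, x) {
    k <- length(i)
    if (nu + k > length(ui)) {
      newcap <- max(2L * length(ui), nu + k)
      length(ui) <<- newcap; length(uj) <<- newcap; length(ux) <<- newcap
    }
    idx <- nu + seq_len(k)
    ui[idx] <<- i; uj[idx] <<- j; ux[idx] <<- x; nu <<- nu + k
  }
  rowperm <- integer(0); colperm <- integer(0)
  work <- rnnz
  for (s in seq_len(m)) {
    work[] <- rnnz
    work[!active] <- NA_integer_
    work[work == 0L] <- NA_integer_
    if (all(is.na(work))) break  # every remaining row already eliminated
    p <- which.min(work)
    cols <- rowsj[[p]]; vals <- rowsv[[p]]
    # sparsest column in the pivot row (candidate counts are upper bounds);
    # break ties on magnitude for stability
    cnt <- lengths(col_rows[cols])
    best <- which(cnt == min(cnt))
    if (length(best) > 1L) best <- best[which.max(abs(vals[best]))]
    c0 <- cols[best[1]]
    pv <- vals[best[1]]
    rowperm <- c(rowperm, p); colperm <- c(colperm, c0)
    push_u(rep.int(s, length(cols)), cols, vals)
    push_l(p, s, 1)
    cand <- col_rows[[c0]]
    cand <- cand[active[cand] & cand != p]
    for (r in cand) {
      jr <- rowsj[[r]]
      pos <- match(c0, jr)
      if (is.na(pos)) next  # stale candidate
      vr <- rowsv[[r]]
      mult <- vr[pos] / pv
      hit <- match(cols, jr)
      ok <- !is.na(hit)
      vr[hit[ok]] <- vr[hit[ok]] - mult * vals[ok]
      newj <- cols[!ok]
      if (length(newj) > 0L) {
        jr <- c(jr, newj)
        vr <- c(vr, -mult * vals[!ok])
        for (cc in newj) col_rows[[cc]] <- c(col_rows[[cc]], r)
      }
      keep <- abs(vr) > tol
      rowsj[[r]] <- jr[keep]
      rowsv[[r]] <- vr[keep]
      rnnz[r] <- sum(keep)
      push_l(r, s, mult)
    }
    active[p] <- FALSE
    colpiv[c0] <- TRUE
    col_rows[[c0]] <- integer(0)
  }
  # columns never pivoted (e.g. terminal fluxomers that feed nothing) get
  # unit rows in U with empty L columns: L U still reconstructs H and U
  # stays invertible
  rest <- which(!colpiv)
  if (length(rest) > 0L) {
    push_u(length(colperm) + seq_along(rest), rest, rep(1, length(rest)))
    colperm <- c(colperm, rest)
  }
  list(li = li[seq_len(nl)], lj = lj[seq_len(nl)], lx = lx[seq_len(nl)],
       ui = ui[seq_len(nu)], uj = uj[seq_len(nu)], ux = ux[seq_len(nu)],
       rowperm = rowperm, colperm = colperm)
}
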