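#' Directional percolation fraction
#'
#' Percentage of phase voxels belonging to 26-connected components that
#' touch both the inlet and the outlet face along the transport axis.
#'
#' @param volume Binary [voxel_volume()] or 0/1 array.
#' @param axis Transport axis (1, 2 or 3).
#' @return Percolating percentage of the phase volume.
#' @export
percolation_fraction <- function(volume, axis = 3L) {
  g <- phase_grid(volume)
  if (sum(g) == 0L) stop("empty phase")
  lab <- .label3d_cpp(as.integer(g != 0), dim(g))
  dim(lab) <- dim(g)
  inlet <- switch(as.character(axis), "1" = lab[1, , ],
                  "2" = lab[, 1, ], "3" = lab[, , 1])
  n <- dim(g)[axis]
  outlet <- switch(as.character(axis), "1" = lab[n, , ],
                   "2" = lab[, n, ], "3" = lab[, , n])
  span <- intersect(setdiff(unique(as.vector(inlet)), 0L),
                    setdiff(unique(as.vector(outlet)), 0L))
  100 * sum(lab %in% span & lab > 0L) / sum(g != 0L)
}

# neighbour index pairs between active voxels along one axis, with optional
# periodic wrap; `idx` holds 1..n_unknowns for active voxels, 0 elsewhere.
axis_pairs <- function(idx, axis, periodic = FALSE) {
  d <- dim(idx)
  n <- d[axis]
  take <- function(range, ax) {
    switch(as.character(ax),
           "1" = idx[range, , , drop = FALSE],
           "2" = idx[, range, , drop = FALSE],
           "3" = idx[, , range, drop = FALSE])
  }
  a <- as.vector(take(seq_len(n - 1L), axis))
  b <- as.vector(take(1L + seq_len(n - 1L), axis))
  keep <- a > 0L & b > 0L
  pairs <- cbind(a[keep], b[keep])
  if (periodic && n > 2L) {
    a <- as.vector(take(n, axis))
    b <- as.vector(take(1L, axis))
    keep <- a > 0L & b > 0L
    pairs <- rbind(pairs, cbind(a[keep], b[keep]))
  }
  pairs
}

# diagonally preconditioned conjugate gradient on a sparse SPD system
cg_solve <- function(A, b, tol = 1e-12, maxit = 20000L) {
  x <- rep(0, length(b))
  r <- b - as.numeric(A %*% x)
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(list(x = x, iters = 0L, relres = 0))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) / bnorm < tol)
      return(list(x = x, iters = it, relres = sqrt(sum(r^2)) / bnorm))
    z <- Minv * r
    rz_new <- sum(r * z)
    beta <- rz_new / rz
    rz <- rz_new
    p <- z + beta * p
  }
  list(x = x, iters = maxit, relres = sqrt(sum(r^2)) / bnorm)
}

#' Diffusive tortuosity factor of a binary phase
#'
#' Solves the steady-state Laplace (diffusion) equation on the phase with
#' voxel-centred finite volumes: unit concentration on the inlet face, zero
#' on the outlet face (Dirichlet:Dirichlet via half-voxel links), and
#' either periodic or insulating lateral boundaries.  Only components
#' connected to the inlet or outlet faces enter the linear system (isolated
#' clusters carry no flux).  The effective diffusivity ratio follows from
#' the steady flux, and the tortuosity factor is defined through
#' \deqn{D_{eff} = D\,\varepsilon/\tau \quad\Rightarrow\quad
#'       \tau = \varepsilon \, / \, (D_{eff}/D),}
#' with \eqn{\varepsilon} the phase volume fraction.  (The factor is a
#' transport reduction, not a geometric path-length ratio.)
#'
#' @param volume Binary [voxel_volume()] or 0/1 array (foreground = the
#'   conducting/diffusing phase).
#' @param axis Transport axis (1, 2 or 3).
#' @param lateral `"periodic"` (default) or `"insulating"` side boundaries.
#' @param tol Relative inlet/outlet flux mismatch accepted as converged.
#' @param method `"cg"` (diagonally preconditioned conjugate gradient) or
#'   `"direct"` (sparse Cholesky via Matrix; the cross-check oracle).
#' @return List of class `transport_result`: `tortuosity_factor`,
#'   `d_eff_ratio`, `volume_fraction` (%), `percolation` (%), `axis`,
#'   `lateral`, `converged`, `residual`, `iterations`.
#' @export
tortuosity <- function(volume, axis = 3L,
                       lateral = c("periodic", "insulating"),
                       tol = 1e-6, method = c("cg", "direct")) {
  lateral <- match.arg(lateral)
  method <- match.arg(method)
  g <- phase_grid(volume)
  d <- dim(g)
  perc <- percolation_fraction(g, axis)
  if (perc == 0)
    stop("phase does not percolate along the axis (infinite tortuosity)")

  # restrict to components touching inlet or outlet (others are flux-free
  # and would make the system singular)
  lab <- .label3d_cpp(as.integer(g != 0), dim(g))
  dim(lab) <- d
  n_ax <- d[axis]
  face <- function(pos) switch(as.character(axis), "1" = lab[pos, , ],
                               "2" = lab[, pos, ], "3" = lab[, , pos])
  touched <- setdiff(unique(c(as.vector(face(1L)), as.vector(face(n_ax)))),
                     0L)
  active <- array(lab %in% touched & lab > 0L, d)

  idx <- array(0L, d)
  idx[active] <- seq_len(sum(active))
  nunk <- sum(active)

  lat_axes <- setdiff(1:3, axis)
  pairs <- rbind(
    axis_pairs(idx, axis, periodic = FALSE),
    axis_pairs(idx, lat_axes[1], periodic = lateral == "periodic"),
    axis_pairs(idx, lat_axes[2], periodic = lateral == "periodic"))

  diag_counts <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = nunk)
  inlet_ids <- switch(as.character(axis),
                      "1" = idx[1, , ], "2" = idx[, 1, ], "3" = idx[, , 1])
  outlet_ids <- switch(as.character(axis),
                       "1" = idx[n_ax, , ], "2" = idx[, n_ax, ],
                       "3" = idx[, , n_ax])
  inlet_ids <- inlet_ids[inlet_ids > 0L]
  outlet_ids <- outlet_ids[outlet_ids > 0L]
  diag_vals <- diag_counts
  diag_vals[inlet_ids] <- diag_vals[inlet_ids] + 2
  diag_vals[outlet_ids] <- diag_vals[outlet_ids] + 2

  A <- Matrix::sparseMatrix(
    i = c(seq_len(nunk), pairs[, 1], pairs[, 2]),
    j = c(seq_len(nunk), pairs[, 2], pairs[, 1]),
    x = c(diag_vals, rep(-1, 2 * nrow(pairs))),
    dims = c(nunk, nunk))
  b <- rep(0, nunk)
  b[inlet_ids] <- b[inlet_ids] + 2  # c_inlet = 1

  if (method == "direct") {
    x <- as.numeric(Matrix::solve(A, b))
    iters <- NA_integer_
  } else {
    sol <- cg_solve(A, b, tol = min(1e-12, tol * 1e-4))
    x <- sol$x
    iters <- sol$iters
  }

  q_in <- sum(2 * (1 - x[inlet_ids]))
  q_out <- sum(2 * x[outlet_ids])
  residual <- abs(q_in - q_out) / max(abs(q_in), abs(q_out), 1e-300)
  q <- (q_in + q_out) / 2
  area <- prod(d[lat_axes])
  d_eff_ratio <- q * n_ax / area
  vf <- 100 * sum(g != 0L) / length(g)
  tau <- (vf / 100) / d_eff_ratio

  structure(list(tortuosity_factor = tau,
                 d_eff_ratio = d_eff_ratio,
                 volume_fraction = vf,
                 percolation = perc,
                 axis = axis, lateral = lateral,
                 converged = residual < tol,
                 residual = residual,
                 iterations = iters,
                 solution = x),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Transport (axis %d, %s lateral): tau = %.4g | D_eff/D = %.4g | ",
    "vf = %.3g%% | percolation = %.3g%% | %s (residual %.2g)\n"),
    x$axis, x$lateral, x$tortuosity_factor, x$d_eff_ratio,
    x$volume_fraction, x$percolation,
    if (x$converged) "converged" else "NOT converged", x$residual))
  invisible(x)
}

#' Bundle a converged transport result for field estimation
#'
#' @param result A converged `transport_result`.
#' @param volume_id Identifier of the analysed volume.
#' @return List with the tortuosity factor and provenance fields, suitable
#'   for JSON serialization and for [effective_field()].
#' @export
field_context <- function(result, volume_id = "volume") {
  stopifnot(inherits(result, "transport_result"))
  if (!isTRUE(result$converged))
    stop("refusing an unconverged transport result")
  list(volume_id = volume_id,
       tortuosity_factor = result$tortuosity_factor,
       d_eff_ratio = result$d_eff_ratio,
       volume_fraction = result$volume_fraction,
       percolation = result$percolation,
       axis = result$axis,
       lateral = result$lateral,
       residual = result$residual)
}
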