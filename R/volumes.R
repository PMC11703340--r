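#' Voxel volume container
#'
#' A 3D scalar lattice with a physical voxel size.  `kind` distinguishes
#' 8-bit grayscale volumes (values 0-255), binary phase masks ({0,1}) and
#' label volumes ({0 void, 1 foam, 2 cell}).
#'
#' @param grid 3D array.
#' @param voxel_size_um Edge length of a voxel, micrometres.
#' @param origin Physical offset of the first voxel, micrometres.
#' @param kind One of `"binary"`, `"grayscale"`, `"label"`.
#' @return Object of class `voxel_volume`.
#' @export
voxel_volume <- function(grid, voxel_size_um,
                         origin = c(0, 0, 0),
                         kind = c("binary", "grayscale", "label")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(grid)) == 3L, all(dim(grid) >= 1L),
            voxel_size_um > 0, length(origin) == 3L)
  vals <- unique(as.vector(grid))
  if (kind == "binary" && !all(vals %in% c(0L, 1L)))
    stop("binary grids may contain only {0, 1}")
  if (kind == "label" && !all(vals %in% c(0L, 1L, 2L)))
    stop("label grids may contain only {0, 1, 2}")
  if (kind == "grayscale" && (min(vals) < 0 || max(vals) > 255))
    stop("grayscale grids must lie in [0, 255]")
  structure(list(grid = grid, voxel_size_um = voxel_size_um,
                 origin = origin, kind = kind),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("voxel volume: %d x %d x %d %s, %.3g um/voxel\n",
              d[1], d[2], d[3], x$kind, x$voxel_size_um))
  invisible(x)
}

#' Write / read a voxel volume as a multi-page TIFF
#'
#' One page per Z slice, 8-bit; a JSON sidecar (`<path>.json`) records the
#' voxel size, kind, origin and dimensions so volumes round-trip exactly.
#'
#' @param volume A [voxel_volume()].
#' @param path Output `.tif` path.
#' @return `write_volume` returns `path` invisibly; `read_volume` the
#'   reconstructed [voxel_volume()].
#' @export
write_volume <- function(volume, path) {
  d <- dim(volume$grid)
  pages <- lapply(seq_len(d[3]), function(k) volume$grid[, , k] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  meta <- list(voxel_size_um = volume$voxel_size_um, kind = volume$kind,
               origin = volume$origin, dims = d)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- as.integer(meta$dims)
  grid <- array(0L, d)
  for (k in seq_len(d[3]))
    grid[, , k] <- as.integer(round(pages[[k]] * 255))
  voxel_volume(grid, meta$voxel_size_um, as.numeric(meta$origin), meta$kind)
}

# squared distance from grid voxels inside a bounding box to a 3D segment;
# updates the running minimum field in place (returns modified field).
segment_distance_update <- function(dist2, p1, p2, rmax) {
  d <- dim(dist2)
  lo <- pmax(1L, floor(pmin(p1, p2) - rmax))
  hi <- pmin(d, ceiling(pmax(p1, p2) + rmax))
  if (any(lo > hi)) return(dist2)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  gx <- array(xs, dim = c(length(xs), length(ys), length(zs)))
  gy <- array(rep(ys, each = length(xs)),
              dim = c(length(xs), length(ys), length(zs)))
  gz <- array(rep(zs, each = length(xs) * length(ys)),
              dim = c(length(xs), length(ys), length(zs)))
  v <- p2 - p1
  vv <- sum(v^2)
  wx <- gx - p1[1]; wy <- gy - p1[2]; wz <- gz - p1[3]
  tpar <- if (vv > 0) (wx * v[1] + wy * v[2] + wz * v[3]) / vv else 0
  tpar <- pmin(1, pmax(0, tpar))
  dx <- wx - tpar * v[1]; dy <- wy - tpar * v[2]; dz <- wz - tpar * v[3]
  d2 <- dx^2 + dy^2 + dz^2
  cur <- dist2[xs, ys, zs]
  dist2[xs, ys, zs] <- pmin(cur, d2)
  dist2
}

#' Generate a foam-like scaffold volume
#'
#' Emulates an open-cell conductive foam as a connected strut network:
#' seeded random nodes (plus a few nodes pinned to every grid face so the
#' network reaches the boundaries), a k-nearest-neighbour graph augmented
#' with its minimum spanning tree for guaranteed connectivity, and edges
#' rasterized as cylinders.  The strut radius is set implicitly by
#' order-statistic thresholding of the distance-to-network field, so the
#' realized porosity matches the target to well within 0.5 percentage
#' points.  The generator is a geometric stand-in for a real CVD foam
#' microstructure, not a physical growth model.
#'
#' @param shape Integer vector of 3 grid dimensions.
#' @param target_porosity Target empty-voxel percentage in (0, 100).
#' @param voxel_size_um Voxel edge, micrometres.
#' @param seed Integer seed.
#' @param node_spacing Mean node spacing in voxels (controls pore size).
#' @param max_radius Maximum strut radius considered, voxels.
#' @return A binary [voxel_volume()] with attributes `realized_porosity`
#'   (%) and `n_nodes`.
#' @export
generate_foam_volume <- function(shape, target_porosity = 97,
                                 voxel_size_um = 2.43, seed = 1L,
                                 node_spacing = 20, max_radius = 8) {
  stopifnot(length(shape) == 3L, all(shape >= 8L))
  if (target_porosity <= 0 || target_porosity >= 100)
    stop("target_porosity must lie in (0, 100)")
  n_total <- prod(shape)
  n_solid <- round(n_total * (1 - target_porosity / 100))

  withr::with_seed(seed, {
    n_nodes <- max(8L, round(n_total / node_spacing^3))
    nodes <- cbind(stats::runif(n_nodes, 1, shape[1]),
                   stats::runif(n_nodes, 1, shape[2]),
                   stats::runif(n_nodes, 1, shape[3]))
    # pin two nodes to each face so the network reaches every boundary
    for (ax in 1:3) for (side in c(1, shape[ax])) {
      extra <- cbind(stats::runif(2, 1, shape[1]),
                     stats::runif(2, 1, shape[2]),
                     stats::runif(2, 1, shape[3]))
      extra[, ax] <- side
      nodes <- rbind(nodes, extra)
    }
  })
  nn <- nrow(nodes)

  # k-NN edges + MST over the complete graph for connectivity
  dmat <- as.matrix(stats::dist(nodes))
  k <- min(3L, nn - 1L)
  edges <- matrix(integer(0), ncol = 2)
  for (i in seq_len(nn)) {
    nb <- order(dmat[i, ])[2:(k + 1L)]
    edges <- rbind(edges, cbind(i, nb))
  }
  edges <- unique(t(apply(edges, 1, sort)))
  # Prim's MST
  intree <- c(TRUE, rep(FALSE, nn - 1L))
  mst <- matrix(integer(0), ncol = 2)
  mind <- dmat[1, ]
  parent <- rep(1L, nn)
  while (!all(intree)) {
    cand <- which(!intree)
    j <- cand[which.min(mind[cand])]
    mst <- rbind(mst, c(parent[j], j))
    intree[j] <- TRUE
    upd <- !intree & dmat[j, ] < mind
    mind[upd] <- dmat[j, upd]
    parent[upd] <- j
  }
  edges <- unique(rbind(edges, t(apply(mst, 1, sort))))

  dist2 <- array(Inf, shape)
  for (e in seq_len(nrow(edges)))
    dist2 <- segment_distance_update(dist2, nodes[edges[e, 1], ],
                                     nodes[edges[e, 2], ], max_radius)

  dvals <- dist2[is.finite(dist2)]
  if (length(dvals) < n_solid)
    stop("shape too small to reach the target porosity with this network")
  if (n_solid == 0L) {
    grid <- array(0L, shape)
  } else {
    thr <- sort(dvals, partial = n_solid)[n_solid]
    grid <- array(0L, shape)
    grid[dist2 <= thr] <- 1L
  }
  realized <- 100 * (1 - sum(grid) / n_total)
  if (abs(realized - target_porosity) > 0.5)
    stop(sprintf("realized porosity %.2f%% misses target %.2f%%",
                 realized, target_porosity))
  out <- voxel_volume(grid, voxel_size_um, kind = "binary")
  attr(out, "realized_porosity") <- realized
  attr(out, "n_nodes") <- nn
  out
}

#' Seed spherical cell blobs into a foam volume
#'
#' Places `n_cells` spherical blobs in the void phase, mutually
#' non-overlapping; when `attach_to_phase` each blob must touch the foam
#' phase (within one voxel of its surface).  Emulates gold-labelled cells
#' adherent to scaffold struts.
#'
#' @param volume Binary foam [voxel_volume()].
#' @param n_cells Number of blobs to place.
#' @param radius_range_um Min/max blob radius, micrometres.
#' @param attach_to_phase Require contact with the foam phase.
#' @param seed Integer seed.
#' @param max_retries Placement attempts per cell before giving up.
#' @return A label [voxel_volume()] (0 void, 1 foam, 2 cell) with
#'   attributes `n_placed` and `cell_radii_um`.
#' @export
seed_cells_in_foam <- function(volume, n_cells,
                               radius_range_um = c(6, 12),
                               attach_to_phase = TRUE, seed = 1L,
                               max_retries = 500L) {
  stopifnot(inherits(volume, "voxel_volume"), n_cells >= 0)
  if (any(radius_range_um <= 0)) stop("radii must be positive")
  grid <- volume$grid
  d <- dim(grid)
  vs <- volume$voxel_size_um
  radii <- numeric(0)
  if (n_cells > 0) {
    withr::with_seed(seed, {
      placed <- 0L
      tries <- 0L
      while (placed < n_cells) {
        tries <- tries + 1L
        if (tries > max_retries * n_cells)
          stop("cannot place ", n_cells,
               " non-overlapping cells after bounded retries")
        r_um <- stats::runif(1, radius_range_um[1], radius_range_um[2])
        r <- r_um / vs
        ctr <- c(stats::runif(1, 1 + r, d[1] - r),
                 stats::runif(1, 1 + r, d[2] - r),
                 stats::runif(1, 1 + r, d[3] - r))
        lo <- pmax(1L, floor(ctr - r - 1))
        hi <- pmin(d, ceiling(ctr + r + 1))
        xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
        sub <- grid[xs, ys, zs]
        gx <- array(xs - ctr[1], dim = dim(sub))
        gy <- array(rep(ys - ctr[2], each = length(xs)), dim = dim(sub))
        gz <- array(rep(zs - ctr[3], each = length(xs) * length(ys)),
                    dim = dim(sub))
        d2 <- gx^2 + gy^2 + gz^2
        ball <- d2 <= r^2
        if (any(sub[ball] != 0L)) next          # overlaps foam or a cell
        if (attach_to_phase) {
          shell <- d2 <= (r + 1.8)^2
          if (!any(sub[shell] == 1L)) next      # not touching the foam
        }
        sub[ball] <- 2L
        grid[xs, ys, zs] <- sub
        placed <- placed + 1L
        radii <- c(radii, r_um)
      }
    })
  }
  out <- voxel_volume(grid, vs, volume$origin, kind = "label")
  attr(out, "n_placed") <- n_cells
  attr(out, "cell_radii_um") <- radii
  out
}

#' Analytic phantom volumes
#'
#' Binary phantoms with closed-form ground truth attached, used as oracle
#' fixtures for the morphometry and transport operations.
#'
#' Kinds and their `params`:
#' \describe{
#'   \item{sphere}{`radius` (voxels), `margin`.  Truth: volume
#'     `4/3 pi r^3`, surface `4 pi r^2`, Euler characteristic 1.}
#'   \item{torus}{`major`, `minor` radii (voxels).  Truth: volume
#'     `2 pi^2 R r^2`, surface `4 pi^2 R r`, Euler characteristic 0.}
#'   \item{slab}{`side`, `thickness` (voxels).  Truth: local thickness
#'     equals `thickness` away from the rim.}
#'   \item{cylinder}{`radius`, `length` (voxels), axis z. Truth: local
#'     thickness equals the diameter.}
#'   \item{straight_channel}{`n` (cubic grid side), `width`, `n_channels`:
#'     square channels spanning the z axis. Truth: tortuosity 1, volume
#'     fraction from the construction.}
#'   \item{serpentine_channel}{`n`, `width`: a single square-section
#'     channel following an S-shaped polyline from the z inlet to the z
#'     outlet. Truth: centreline length `L_e` and the geometric estimate
#'     `tortuosity ~ (L_e/L)^2`.}
#'   \item{disjoint_blobs}{`k`, `radius`: k well-separated spheres.
#'     Truth: object count k, Euler characteristic k.}
#' }
#'
#' @param kind Phantom type, see Details.
#' @param params Named list of geometric parameters (voxels).
#' @param voxel_size_um Voxel edge, micrometres.
#' @return Binary [voxel_volume()] with attribute `analytic_truth`.
#' @export
generate_phantom <- function(kind = c("sphere", "torus", "slab", "cylinder",
                                      "straight_channel",
                                      "serpentine_channel",
                                      "disjoint_blobs"),
                             params = list(), voxel_size_um = 1) {
  kind <- match.arg(kind)
  p <- params
  grid <- NULL
  truth <- list()

  ball_mask <- function(dims, ctr, r) {
    gx <- array(seq_len(dims[1]) - ctr[1], dim = dims)
    gy <- array(rep(seq_len(dims[2]) - ctr[2], each = dims[1]), dim = dims)
    gz <- array(rep(seq_len(dims[3]) - ctr[3], each = dims[1] * dims[2]),
                dim = dims)
    (gx^2 + gy^2 + gz^2) <= r^2
  }

  if (kind == "sphere") {
    r <- p$radius %||% 20
    m <- p$margin %||% 4
    n <- 2L * ceiling(r + m) + 1L
    dims <- c(n, n, n)
    ctr <- rep((n + 1) / 2, 3)
    if (r + 1 > (n - 1) / 2) stop("sphere exceeds grid bounds")
    grid <- array(0L, dims)
    grid[ball_mask(dims, ctr, r)] <- 1L
    truth <- list(volume_voxels = 4 / 3 * pi * r^3,
                  surface_voxels2 = 4 * pi * r^2,
                  s_over_v = 3 / r, euler = 1L, radius = r)
  } else if (kind == "torus") {
    R <- p$major %||% 15
    r <- p$minor %||% 5
    m <- p$margin %||% 4
    n <- 2L * ceiling(R + r + m) + 1L
    nz <- 2L * ceiling(r + m) + 1L
    dims <- c(n, n, nz)
    cx <- (n + 1) / 2; cz <- (nz + 1) / 2
    gx <- array(seq_len(n) - cx, dim = dims)
    gy <- array(rep(seq_len(n) - cx, each = n), dim = dims)
    gz <- array(rep(seq_len(nz) - cz, each = n * n), dim = dims)
    rho <- sqrt(gx^2 + gy^2)
    grid <- array(0L, dims)
    grid[(rho - R)^2 + gz^2 <= r^2] <- 1L
    truth <- list(volume_voxels = 2 * pi^2 * R * r^2,
                  surface_voxels2 = 4 * pi^2 * R * r,
                  euler = 0L, major = R, minor = r)
  } else if (kind == "slab") {
    side <- p$side %||% 50
    th <- p$thickness %||% 15
    m <- p$margin %||% 4
    dims <- c(side + 2L * m, side + 2L * m, th + 2L * m)
    grid <- array(0L, dims)
    grid[m + seq_len(side), m + seq_len(side), m + seq_len(th)] <- 1L
    truth <- list(thickness_voxels = th, side = side)
  } else if (kind == "cylinder") {
    r <- p$radius %||% 6
    len <- p$length %||% 40
    m <- p$margin %||% 4
    n <- 2L * ceiling(r + m) + 1L
    dims <- c(n, n, len + 2L * m)
    cx <- (n + 1) / 2
    gx <- array(seq_len(n) - cx, dim = dims)
    gy <- array(rep(seq_len(n) - cx, each = n), dim = dims)
    disk <- gx^2 + gy^2 <= r^2
    grid <- array(0L, dims)
    sel <- disk
    sel[, , c(seq_len(m), m + len + seq_len(m))] <- FALSE
    grid[sel] <- 1L
    truth <- list(diameter_voxels = 2 * r, length = len)
  } else if (kind == "straight_channel") {
    n <- p$n %||% 32
    w <- p$width %||% 4
    k <- p$n_channels %||% 2
    dims <- c(n, n, n)
    grid <- array(0L, dims)
    pos <- round(seq(2, n - w - 1, length.out = k))
    if (any(pos < 1) || any(pos + w - 1 > n))
      stop("channels exceed grid bounds")
    for (x0 in pos)
      grid[x0:(x0 + w - 1), x0:(x0 + w - 1), ] <- 1L
    truth <- list(volume_fraction = 100 * k * w^2 / (n * n),
                  tortuosity = 1, n_channels = k)
  } else if (kind == "serpentine_channel") {
    n <- p$n %||% 40
    w <- p$width %||% 4
    dims <- c(n, n, n)
    grid <- array(0L, dims)
    xlo <- 3L; xhi <- n - w - 2L
    z1 <- round(n * 0.35); z2 <- round(n * 0.7)
    put_box <- function(x0, x1, z0, z1l) {
      y0 <- round(n / 2 - w / 2)
      grid[x0:(x1 + w - 1L), y0:(y0 + w - 1L), z0:z1l] <<- 1L
    }
    # up, across, up, back, up (an S in the x-z plane)
    put_box(xlo, xlo, 1L, z1)
    put_box(xlo, xhi, z1, z1 + w - 1L)
    put_box(xhi, xhi, z1, z2)
    put_box(xlo, xhi, z2, z2 + w - 1L)
    put_box(xlo, xlo, z2, n)
    L_e <- n + 2 * (xhi - xlo)
    truth <- list(centreline_length = L_e, gap = n,
                  tortuosity_estimate = (L_e / n)^2, width = w)
  } else if (kind == "disjoint_blobs") {
    k <- p$k %||% 7
    r <- p$radius %||% 4
    gap <- 2L * ceiling(r) + 5L
    per_row <- ceiling(sqrt(k))
    nx <- per_row * gap + gap
    dims <- c(nx, nx, 2L * ceiling(r) + 9L)
    grid <- array(0L, dims)
    ctrs <- list()
    for (i in seq_len(k)) {
      row <- (i - 1) %/% per_row
      col <- (i - 1) %% per_row
      ctrs[[i]] <- c(gap * (col + 1), gap * (row + 1), (dims[3] + 1) / 2)
    }
    if (any(vapply(ctrs, function(cc) any(cc + r + 1 > dims) ||
                     any(cc - r < 1), logical(1))))
      stop("blobs exceed grid bounds")
    for (cc in ctrs) grid[ball_mask(dims, cc, r)] <- 1L
    truth <- list(n_objects = k, euler = k, radius = r)
  }
  out <- voxel_volume(grid, voxel_size_um, kind = "binary")
  attr(out, "analytic_truth") <- truth
  attr(out, "phantom_kind") <- kind
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
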