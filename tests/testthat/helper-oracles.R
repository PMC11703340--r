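# Shared fixtures and independent oracles used across test files.

sls_material <- function(noise_sd = 0) {
  prony_material(20e3, data.frame(modulus = 40e3, tau = 10),
                 noise_sd = noise_sd)
}

# seeded grid of one/two-arm Prony materials spanning the cartilage-construct
# stiffness range, with stress noise at 0.5% of the peak preconditioning
# stress
material_grid <- function(n = 20, seed = 42, noise = TRUE) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      E0 <- stats::runif(1, 10e3, 30e3)
      nar <- sample(1:2, 1)
      arms <- data.frame(modulus = stats::runif(nar, 15e3, 50e3),
                         tau = stats::runif(nar, 8, 20))
      sd <- if (noise) 0.005 * 0.14 * (E0 + sum(arms$modulus)) else 0
      prony_material(E0, arms, noise_sd = sd)
    })
  })
}

# brute-force 26-connected component count by breadth-first flood fill
# (pure R; small grids only)
flood_fill_count <- function(grid) {
  d <- dim(grid)
  seen <- array(FALSE, d)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  count <- 0L
  fg <- which(grid != 0, arr.ind = TRUE)
  for (r in seq_len(nrow(fg))) {
    if (seen[fg[r, 1], fg[r, 2], fg[r, 3]]) next
    count <- count + 1L
    queue <- list(fg[r, ])
    seen[fg[r, 1], fg[r, 2], fg[r, 3]] <- TRUE
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (grid[nb[1], nb[2], nb[3]] != 0 &&
            !seen[nb[1], nb[2], nb[3]]) {
          seen[nb[1], nb[2], nb[3]] <- TRUE
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  count
}

# analytic ellipse loop: strain/stress sinusoids with a phase lag, starting
# at the strain minimum so the loop splits cleanly into arcs
ellipse_cycle <- function(eps0 = 0.07, sig0 = 4000, delta = 0.2,
                          samples_per_cycle = 200, f = 0.5) {
  tt <- seq(-0.25 / f, 0.75 / f, length.out = samples_per_cycle + 1)
  tt <- tt[-length(tt)]
  w <- 2 * pi * f
  list(time = tt - tt[1],
       strain = eps0 + eps0 * sin(w * tt),
       stress = 2 * sig0 + sig0 * sin(w * tt + delta))
}

make_torus_grid <- function(R, r, dims, ctr) {
  gx <- array(seq_len(dims[1]) - ctr[1], dim = dims)
  gy <- array(rep(seq_len(dims[2]) - ctr[2], each = dims[1]), dim = dims)
  gz <- array(rep(seq_len(dims[3]) - ctr[3], each = dims[1] * dims[2]),
              dim = dims)
  rho <- sqrt(gx^2 + gy^2)
  out <- array(0L, dims)
  out[(rho - R)^2 + gz^2 <= r^2] <- 1L
  out
}

# chain of k tori fused pairwise at single tangency regions: a genus-k
# handlebody, Euler characteristic 1 - k
handle_chain <- function(k, R = 10, r = 3) {
  nx <- 2 * (R + r + 4) + 2 * R * (k - 1) + 1
  ny <- 2 * (R + r + 4) + 1
  nz <- 2 * (r + 4) + 1
  dims <- c(nx, ny, nz)
  grid <- array(0L, dims)
  cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  for (i in seq_len(k)) {
    cx <- R + r + 4 + 1 + 2 * R * (i - 1)
    grid <- pmax(grid, make_torus_grid(R, r, dims, c(cx, cy, cz)))
  }
  grid
}
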