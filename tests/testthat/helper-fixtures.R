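# Shared fixtures and independent oracles, built in code at test time.

# single z-aligned cylinder at the phantom centre, simulated end to end
make_single_cylinder_image <- function(cyl, voxel_size = 4.42,
                                       supersample = 4L,
                                       system = system_model(60, psf_fwhm = 20),
                                       nuclide = i131(), duration_s = 1800,
                                       seed = NULL, noise = "poisson",
                                       padding = 30) {
  lay <- phantom_layout(data.frame(id = cyl$id, x = 0, y = 0))
  av <- voxelize_layout(lay, stats::setNames(list(cyl), cyl$id),
                        voxel_size = voxel_size, supersample = supersample,
                        padding = padding)
  simulate_count_image(av, system, nuclide, duration_s, seed = seed,
                       noise = noise)
}

paper_cylinders <- function() list(
  C1 = cylinder_spec("C1", 7.5, 38, activity_kBq = 300),
  C2 = cylinder_spec("C2", 15, 38, activity_kBq = 1200),
  C3 = cylinder_spec("C3", 30, 38, activity_kBq = 4900),
  C4 = cylinder_spec("C4", 60, 38, activity_kBq = 19000))

# --- independent oracles -------------------------------------------------

# top-k voxel selection: descending count, ascending linear index
topk_oracle <- function(counts, k, idx = seq_along(counts)) {
  vals <- counts[idx]
  ord <- order(-vals, idx)
  sort(idx[ord[seq_len(k)]])
}

# ordinary least squares through explicit normal equations
ols_oracle <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  res <- y - X %*% beta
  n <- length(y)
  s2 <- sum(res^2) / (n - 2)
  covb <- s2 * solve(t(X) %*% X)
  list(offset = beta[1], slope = beta[2],
       offset_se = sqrt(covb[1, 1]), slope_se = sqrt(covb[2, 2]))
}

# exact two-sided signed-rank p by enumerating all 2^n sign patterns
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  venum <- as.vector(signs %*% rk)
  mu <- n * (n + 1) / 4
  p <- if (v < mu) mean(venum <= v) else mean(venum >= v)
  list(statistic = v, p.value = min(1, 2 * p))
}

# brute-force 3D spill-out: fine-grid voxelization, dense separable
# convolution written from scratch with stats::convolve
spillout_3d_oracle <- function(cyl, fwhm, step = 1) {
  sig <- fwhm / (2 * sqrt(2 * log(2)))
  r <- cyl$diameter / 2
  half_xy <- r + 4 * sig + step
  nxy <- ceiling(2 * half_xy / step)
  xs <- (seq_len(nxy) - (nxy + 1) / 2) * step
  nz <- ceiling((cyl$height + 2 * (4 * sig + step)) / step)
  zs <- -(4 * sig + step) + (seq_len(nz) - 0.5) * step
  # occupancy: supersampled disc x analytic z overlap
  occ2 <- matrix(0, nxy, nxy)
  off <- ((1:4 - 0.5) / 4 - 0.5) * step
  for (ox in off) for (oy in off)
    occ2 <- occ2 + (outer((xs + ox)^2, (xs + oy)^2, `+`) <= r^2)
  occ2 <- occ2 / 16
  zfrac <- pmax(0, pmin(zs + step / 2, cyl$height) -
                   pmax(zs - step / 2, 0)) / step
  occ3 <- array(outer(as.vector(occ2), zfrac), dim = c(nxy, nxy, nz))
  kr <- ceiling(4 * sig / step)
  k <- dnorm(seq(-kr, kr) * step, sd = sig)
  k <- k / sum(k)
  conv_dim <- function(A, d) {
    dd <- dim(A)
    perm <- c(d, setdiff(1:3, d))
    M <- matrix(aperm(A, perm), nrow = dd[d])
    out <- apply(M, 2, function(col) {
      full <- convolve(col, rev(k), type = "open")
      full[(kr + 1):(kr + length(col))]
    })
    aperm(array(out, dim = dd[perm]), order(perm))
  }
  bl <- conv_dim(conv_dim(conv_dim(occ3, 1), 2), 3)
  1 - sum(bl * occ3) / sum(occ3)
}

# supersampled-occupancy mask oracle for the nominal-geometry VOI
occupancy_mask_oracle <- function(image, cyl, position = c(0, 0),
                                  supersample = 8L) {
  vox <- image$voxel_size
  occ <- matrix(0, length(image$xs), length(image$ys))
  off <- ((seq_len(supersample) - 0.5) / supersample - 0.5) * vox
  for (ox in off) for (oy in off)
    occ <- occ + (outer((image$xs + ox - position[1])^2,
                        (image$ys + oy - position[2])^2, `+`) <=
                    (cyl$diameter / 2)^2)
  occ <- occ / supersample^2
  zin <- image$zs >= 0 & image$zs <= cyl$height
  mask <- array(FALSE, dim = dim(image$counts))
  mask[, , zin] <- occ >= 0.5
  mask
}

# coarse grid search over (v0, b) with the plateau profiled analytically
recovery_grid_oracle <- function(volumes, values) {
  best <- list(sse = Inf)
  for (v0 in exp(seq(log(0.2), log(200), length.out = 120))) {
    for (b in seq(0.3, 3, by = 0.05)) {
      s <- 1 - exp(-(volumes / v0)^b)
      plateau <- sum(values * s) / sum(s^2)
      sse <- sum((values - plateau * s)^2)
      if (sse < best$sse)
        best <- list(sse = sse, plateau = plateau, v0 = v0, b = b)
    }
  }
  best
}
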