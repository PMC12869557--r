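# Independent reference computations used as oracles. These are written
# longhand (loops, dense linear algebra, closed forms) on purpose: they
# must not share code paths with the package internals they check.

erfc_ <- function(z) 2 * pnorm(-z * sqrt(2))
erfcinv_ <- function(p) qnorm(1 - p / 2) / sqrt(2)

# Half-space diffusion with a fixed boundary concentration.
halfspace_profile <- function(x, t, c0, D_apparent) {
  c0 * erfc_(x / (2 * sqrt(D_apparent * t)))
}

# Transient slab with ends fixed at (c0, 0), zero initial condition.
slab_series_profile <- function(x, t, c0, D_apparent, L, n_modes = 200) {
  n <- seq_len(n_modes)
  steady <- c0 * (1 - x / L)
  modes <- vapply(x, function(xx) {
    sum(2 * c0 / (n * pi) * sin(n * pi * xx / L) *
          exp(-n^2 * pi^2 * D_apparent * t / L^2))
  }, numeric(1))
  steady - modes
}

# Finite-difference Poisson solve of laminar duct flow on the cross-section:
# -eta * (u_yy + u_zz) = dp/L with u = 0 on the walls. Dense grid, sparse LU.
fd_duct_max_velocity <- function(width_um, depth_um, length_mm, dp, eta,
                                 nn = 81) {
  w <- width_um * 1e-6; h <- depth_um * 1e-6; L <- length_mm * 1e-3
  hy <- w / (nn - 1); hz <- h / (nn - 1)
  ni <- nn - 2                      # interior nodes per direction
  ey <- rep(1, ni)
  T1 <- Matrix::bandSparse(ni, ni, k = c(-1, 0, 1),
                           diagonals = list(ey[-1], -2 * ey, ey[-1]))
  Iy <- Matrix::Diagonal(ni)
  A <- Matrix::kronecker(Iy, T1) / hy^2 + Matrix::kronecker(T1, Iy) / hz^2
  b <- rep(-dp / (L * eta), ni * ni)
  u <- Matrix::solve(A, b)
  max(as.numeric(u)) * 1e6          # um/s
}

# Explicit RK4 brute-force integration of the same finite-volume
# semi-discretisation, written as plain loops over faces.
explicit_rk4_reference <- function(faces, eps_cells, D_of_t, cb_left,
                                   cb_right, t_end, dt, c0 = NULL) {
  n <- length(faces) - 1
  centers <- (faces[-1] + faces[-(n + 1)]) / 2
  V <- diff(faces)
  cc <- if (is.null(c0)) rep(0, n) else c0
  rate <- function(t, c) {
    D <- D_of_t(t)
    FF <- numeric(n + 1)
    FF[1] <- -D[1] * (c[1] - cb_left) / (centers[1] - faces[1])
    for (f in 2:n) {
      d1 <- faces[f] - centers[f - 1]
      d2 <- centers[f] - faces[f]
      Df <- (d1 + d2) / (d1 / D[f - 1] + d2 / D[f])
      FF[f] <- -Df * (c[f] - c[f - 1]) / (centers[f] - centers[f - 1])
    }
    FF[n + 1] <- -D[n] * (cb_right - c[n]) / (faces[n + 1] - centers[n])
    (FF[1:n] - FF[2:(n + 1)]) / (eps_cells * V)
  }
  nsteps <- ceiling(t_end / dt)
  dt <- t_end / nsteps
  t <- 0
  for (k in seq_len(nsteps)) {
    k1 <- rate(t, cc)
    k2 <- rate(t + dt / 2, cc + dt / 2 * k1)
    k3 <- rate(t + dt / 2, cc + dt / 2 * k2)
    k4 <- rate(t + dt, cc + dt * k3)
    cc <- cc + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + dt
  }
  list(centers = centers, c = cc)
}

# Two-region steady spherical solution: interior held at c_m by the source
# shell (no interior flux path), harmonic 1/r decay from the shell radius
# to a zero sink at the outer radius.
spherical_steady_profile <- function(r, r_shell, r_outer, c_m) {
  out <- ifelse(r <= r_shell, c_m,
                c_m * (1 / r - 1 / r_outer) / (1 / r_shell - 1 / r_outer))
  pmax(out, 0)
}

# A homogeneous "slab" phantom grid whose single material still carries the
# membrane label, so the saturation law can be exercised on a uniform slab.
uniform_membrane_slab <- function(length_mm = 5, dx = 100) {
  g <- build_phantom_grid(phantom_domain(length_mm = length_mm,
                                         membrane = NULL), dx_max = dx)
  g$material_labels <- c("membrane", "membrane")
  g
}
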