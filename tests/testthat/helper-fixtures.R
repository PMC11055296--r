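# fixtures built in code: tiny analytic meshes and pose scrambling

# unit tetrahedron (closed, 4 vertices / 4 faces)
tetra_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4))
  surface_mesh(v, f, "tetra")
}

# axis-aligned unit cube surface (12 triangles)
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  dimnames(v) <- NULL
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),      # z = 0
    c(5, 6, 7), c(6, 8, 7),      # z = 1
    c(1, 2, 5), c(2, 6, 5),      # y = 0
    c(3, 7, 4), c(4, 7, 8),      # y = 1
    c(1, 5, 3), c(3, 5, 7),      # x = 0
    c(2, 4, 6), c(4, 8, 6))      # x = 1
  surface_mesh(v, f, "cube")
}

# apply a deterministic random rigid motion to a mesh + landmark pair
scramble_pose <- function(mesh, landmarks, seed = 1) {
  set.seed(seed)
  R <- trochlea:::rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
  tr <- stats::runif(3, -50, 50)
  list(mesh = transform_mesh(mesh, R, tr),
       landmarks = trochlea:::matrix_landmarks(
         sweep(trochlea:::landmark_matrix(landmarks) %*% t(R), 2, -tr)))
}

# uniformly scale a mesh + landmark pair
scale_pair <- function(mesh, landmarks, k) {
  list(mesh = surface_mesh(mesh$vertices * k, mesh$faces, mesh$specimen_id),
       landmarks = trochlea:::matrix_landmarks(
         trochlea:::landmark_matrix(landmarks) * k))
}

# points sampled exactly on a cylinder of given radius/axis (for fit oracles)
cylinder_points <- function(n, radius, axis = c(1, 0, 0), center = c(0, 0, 0),
                            length = 40, span = 2 * pi, seed = 1) {
  set.seed(seed)
  a <- axis / sqrt(sum(axis^2))
  e1 <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * a) * a; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  t <- stats::runif(n, -length / 2, length / 2)
  th <- stats::runif(n, -span / 2, span / 2)
  P <- outer(t, a) + radius * (outer(cos(th), e1) + outer(sin(th), e2))
  sweep(P, 2, -center)
}

# independent oracle for cylinder fitting: exhaustive grid over axis
# directions with a closed-form (Kasa) algebraic circle fit of the projected
# points per direction, followed by one local grid refinement around the
# best coarse direction (still a pure grid search, no gradient steps)
grid_cylinder_oracle <- function(P, n_dir = 30) {
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  eval_dir <- function(th, ph) {
    a <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    e1 <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- e1 - sum(e1 * a) * a; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
            a[1] * e1[2] - a[2] * e1[1])
    u <- Q %*% e1; v <- Q %*% e2
    # Kasa fit: minimize ||u^2+v^2 - 2au - 2bv - c||
    A <- cbind(2 * u, 2 * v, 1)
    sol <- qr.solve(A, u^2 + v^2)
    r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
    d <- sqrt((u - sol[1])^2 + (v - sol[2])^2)
    list(sse = sum((d - r)^2), radius = r, axis = a, th = th, ph = ph)
  }
  sweep_grid <- function(ths, phs) {
    best <- list(sse = Inf)
    for (th in ths) for (ph in phs) {
      cand <- eval_dir(th, ph)
      if (cand$sse < best$sse) best <- cand
    }
    best
  }
  best <- sweep_grid(seq(0, pi / 2, length.out = n_dir),
                     seq(0, pi, length.out = n_dir))
  step <- pi / (n_dir - 1)
  sweep_grid(seq(best$th - step, best$th + step, length.out = 21),
             seq(best$ph - step, best$ph + step, length.out = 21))
}
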