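# independent brute-force oracles, implemented apart from the package's
# compiled code paths

# distance from one point to one triangle via closed-form projection onto
# the triangle plane followed by edge clamping
pt_tri_dist_oracle <- function(p, a, b, c) {
  # dense parameter scan + local refinement over barycentric coordinates
  uu <- seq(0, 1, length.out = 21)
  best <- Inf
  for (u in uu) for (v in seq(0, 1 - u, length.out = 21)) {
    q <- a + u * (b - a) + v * (c - a)
    best <- min(best, sum((p - q)^2))
  }
  # refine around the best on a finer lattice
  sqrt(refine_tri(p, a, b, c, best))
}

refine_tri <- function(p, a, b, c, best) {
  uu <- seq(0, 1, length.out = 81)
  for (u in uu) {
    vv <- seq(0, 1 - u, length.out = 81)
    q0 <- a + u * (b - a)
    for (v in vv) {
      q <- q0 + v * (c - a)
      d2 <- sum((p - q)^2)
      if (d2 < best) best <- d2
    }
  }
  best
}

# unsigned distance from grid nodes to a whole mesh: all-pairs brute force,
# vectorized over triangles (exact point-triangle distance per pair)
brute_mesh_distance <- function(pts, mesh) {
  V <- mesh$vertices
  Fc <- mesh$faces
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  AB <- B - A
  AC <- C - A
  out <- numeric(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    AP <- sweep(-A, 2, p, "+")
    d1 <- rowSums(AB * AP)
    d2 <- rowSums(AC * AP)
    a11 <- rowSums(AB * AB)
    a12 <- rowSums(AB * AC)
    a22 <- rowSums(AC * AC)
    det <- pmax(a11 * a22 - a12^2, 1e-300)
    u <- (a22 * d1 - a12 * d2) / det
    v <- (a11 * d2 - a12 * d1) / det
    # clamp barycentric coordinates to the triangle
    u <- pmin(pmax(u, 0), 1)
    v <- pmin(pmax(v, 0), 1)
    s <- u + v
    scale_idx <- s > 1
    u[scale_idx] <- u[scale_idx] / s[scale_idx]
    v[scale_idx] <- v[scale_idx] / s[scale_idx]
    # clamping interior projection is not exact for edge regions; refine by
    # also projecting onto the three edges
    d2_face <- rowSums((AP - u * AB - v * AC)^2)
    t1 <- pmin(pmax(d1 / pmax(a11, 1e-300), 0), 1)
    d2_e1 <- rowSums((AP - t1 * AB)^2)
    t2 <- pmin(pmax(d2 / pmax(a22, 1e-300), 0), 1)
    d2_e2 <- rowSums((AP - t2 * AC)^2)
    BP <- AP - AB
    BC <- C - B
    t3 <- pmin(pmax(rowSums(BC * BP) / pmax(rowSums(BC * BC), 1e-300), 0), 1)
    d2_e3 <- rowSums((BP - t3 * BC)^2)
    out[q] <- sqrt(min(pmin(d2_face, d2_e1, d2_e2, d2_e3)))
  }
  out
}

# inside test by ray parity along +x, independent implementation
brute_inside <- function(pts, mesh) {
  V <- mesh$vertices
  Fc <- mesh$faces
  A <- V[Fc[, 1], , drop = FALSE]
  B <- V[Fc[, 2], , drop = FALSE]
  C <- V[Fc[, 3], , drop = FALSE]
  out <- logical(nrow(pts))
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ] + c(0, 3.1e-7, 7.3e-7)
    s1 <- (A[, 2] - p[2]) * (B[, 3] - p[3]) - (A[, 3] - p[3]) * (B[, 2] - p[2])
    s2 <- (B[, 2] - p[2]) * (C[, 3] - p[3]) - (B[, 3] - p[3]) * (C[, 2] - p[2])
    s3 <- (C[, 2] - p[2]) * (A[, 3] - p[3]) - (C[, 3] - p[3]) * (A[, 2] - p[2])
    tot <- s1 + s2 + s3
    ok <- abs(tot) > 1e-300 &
      (s1 / tot) >= 0 & (s2 / tot) >= 0 & (s3 / tot) >= 0
    if (!any(ok)) {
      out[q] <- FALSE
      next
    }
    w1 <- (s2 / tot)[ok]
    w2 <- (s3 / tot)[ok]
    w3 <- (s1 / tot)[ok]
    xhit <- w1 * A[ok, 1] + w2 * B[ok, 1] + w3 * C[ok, 1]
    out[q] <- sum(xhit > p[1]) %% 2 == 1
  }
  out
}

# closed-form evaluation of the hyperelastic density, written independently
Wbar_oracle <- function(a, d, mu = 1, lam = 1)
  mu / 2 * a^2 + lam / 4 * d^2 - (mu + lam / 2) * log(d) - 3 * mu / 2 - lam / 4

rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
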