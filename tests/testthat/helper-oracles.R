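# Independent oracles used across the suite. These deliberately re-derive
# quantities from first principles (brute-force enumeration, closed forms,
# reference library calls) rather than reusing package internals.

# 10-state partition function of the concerted 2-conformation, 4-site model:
# open states weighted L * C(4,n) (D x)^n, closed states C(4,n) x^n.
oracle_mwc <- function(conc, L, KA, D) {
  x <- KA * conc
  n <- 0:4
  w_open <- L * choose(4, n) * (D * x)^n
  w_closed <- choose(4, n) * x^n
  Z <- sum(w_open) + sum(w_closed)
  occ <- sum((w_open + w_closed) * n / 4) / Z
  cur <- (sum(w_open) / Z) / (L / (1 + L))
  c(occupancy = occ, current = cur)
}

# stationary distribution of the 2-state chain from its transition matrix
# (left eigenvector, computed numerically)
oracle_stationary_p1 <- function(p11, p22) {
  P <- matrix(c(p11, 1 - p11, 1 - p22, p22), 2, 2, byrow = TRUE)
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  (v / sum(v))[1]
}

# brute-force minimum pairwise distance between two coordinate sets
oracle_min_dist <- function(A, B) {
  best <- Inf
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
  best
}

# brute-force H-bond count for one frame: all (donor, hydrogen, acceptor)
# triplets checked against the geometric criterion
oracle_hbond_count <- function(xyz, donors, hydrogens, acceptors,
                               dist_cutoff = 3.5, angle_cutoff = 30) {
  count <- 0L
  for (d in donors) for (h in hydrogens) for (a in acceptors) {
    v_da <- xyz[a, ] - xyz[d, ]
    v_dh <- xyz[h, ] - xyz[d, ]
    dda <- sqrt(sum(v_da^2))
    if (dda == 0 || dda > dist_cutoff) next
    ang <- acos(max(-1, min(1, sum(v_dh * v_da) /
                              (sqrt(sum(v_dh^2)) * dda)))) * 180 / pi
    if (ang <= angle_cutoff) count <- count + 1L
  }
  count
}

# reference superposed RMSD via bio3d's least-squares fit (independent
# Kabsch implementation); RMSD computed from the superposed coordinates to
# avoid bio3d::rmsd's 3-digit rounding
oracle_rmsd_bio3d <- function(A, B) {
  a <- as.vector(t(A)); b <- as.vector(t(B))
  bfit <- bio3d::fit.xyz(fixed = a, mobile = matrix(b, nrow = 1),
                         fixed.inds = seq_along(a),
                         mobile.inds = seq_along(b))
  d <- matrix(a - as.vector(bfit), ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums(d^2)))
}

# effective autocorrelation-time-corrected SE of the occupancy of a 2-state
# Markov chain: var = p(1-p)/n * (1+rho)/(1-rho), rho = p11 + p22 - 1
oracle_markov_se <- function(p11, p22, n) {
  p <- oracle_stationary_p1(p11, p22)
  rho <- p11 + p22 - 1
  sqrt(p * (1 - p) / n * (1 + rho) / (1 - rho))
}

# small deterministic trajectory builder for geometry tests
make_toy_traj <- function(coords_list, elements = NULL, chain = "A",
                          resno = NULL, role = NULL, dt = 1) {
  na <- nrow(coords_list[[1]])
  atoms <- data.frame(
    eleno = seq_len(na),
    elety = paste0("C", seq_len(na)),
    element = if (is.null(elements)) rep("C", na) else elements,
    resno = if (is.null(resno)) seq_len(na) else resno,
    resid = "GLY",
    chain = if (length(chain) == 1) rep(chain, na) else chain,
    role = if (is.null(role)) rep("protein", na) else role,
    stringsAsFactors = FALSE)
  xyz <- array(NA_real_, c(length(coords_list), na, 3))
  for (f in seq_along(coords_list)) xyz[f, , ] <- coords_list[[f]]
  trajectory_ensemble(atoms, xyz, times = dt * seq_along(coords_list))
}

# random rigid motion applied to an n x 3 coordinate matrix
apply_rigid <- function(M, angles = c(0.3, -0.7, 1.2), shift = c(5, -3, 8)) {
  Rx <- matrix(c(1, 0, 0, 0, cos(angles[1]), -sin(angles[1]),
                 0, sin(angles[1]), cos(angles[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(angles[2]), 0, sin(angles[2]), 0, 1, 0,
                 -sin(angles[2]), 0, cos(angles[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(angles[3]), -sin(angles[3]), 0,
                 sin(angles[3]), cos(angles[3]), 0, 0, 0, 1), 3, 3,
               byrow = TRUE)
  sweep(M %*% t(Rz %*% Ry %*% Rx), 2, shift, `+`)
}
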