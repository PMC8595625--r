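# Shared fixtures and independent oracles.

toy_pdb_path <- function() {
  system.file("extdata", "toy_tripeptide.pdb", package = "helixnet",
              mustWork = TRUE)
}

# independent Kabsch superposition (SVD), used as oracle against
# align_to_reference (which goes through bio3d::fit.xyz)
kabsch_rmsd <- function(mobile, fixed) {
  cm <- colMeans(mobile); cf <- colMeans(fixed)
  A <- sweep(mobile, 2, cm); B <- sweep(fixed, 2, cf)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- A %*% t(R)
  sqrt(mean(rowSums((fit - B)^2)))
}

# scalar whole-system potential: Coulomb + LJ over atom pairs, GB double sum
# with atomic self terms; written as plain loops, independent of the
# vectorized implementation
direct_system_energy <- function(st, ap, radii, opt) {
  n <- nrow(st$atoms)
  co <- st$coords
  kc <- 332.0636
  tau <- function(f) 1 / opt$epsilon_in - exp(-opt$kappa * f) / opt$epsilon_out
  e <- 0
  for (i in seq_len(n)) {
    e <- e - 0.5 * kc * tau(radii[i]) * ap$charge[i]^2 / radii[i]
    if (i == n) next
    for (j in seq((i + 1), n)) {
      r <- sqrt(sum((co[i, ] - co[j, ])^2))
      e <- e + kc * ap$charge[i] * ap$charge[j] / (opt$epsilon_in * r)
      rmin <- ap$lj_rmin_half[i] + ap$lj_rmin_half[j]
      epsm <- sqrt(ap$lj_epsilon[i] * ap$lj_epsilon[j])
      e <- e + epsm * ((rmin / r)^12 - 2 * (rmin / r)^6)
      bb <- radii[i] * radii[j]
      f <- sqrt(r^2 + bb * exp(-r^2 / (4 * bb)))
      e <- e - kc * tau(f) * ap$charge[i] * ap$charge[j] / f
    }
  }
  e
}

# scalar HCT/OBC-II effective radii, plain loops
direct_born_radii <- function(st, ap, opt) {
  n <- nrow(st$atoms)
  co <- st$coords
  rho <- ap$gb_radius - opt$offset
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (i == j) next
      r <- sqrt(sum((co[i, ] - co[j, ])^2))
      s <- ap$gb_scale[j] * rho[j]
      if (r + s <= rho[i]) next
      U <- r + s
      L <- max(rho[i], abs(r - s))
      term <- 0.5 * (1 / L - 1 / U + 0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
                     0.5 * log(L / U) / r)
      if (s > r + rho[i]) term <- term + (1 / rho[i] - 1 / L)
      acc <- acc + term
    }
    psi <- rho[i] * acc
    arg <- opt$alpha * psi - opt$beta * psi^2 + opt$gamma * psi^3
    out[i] <- 1 / (1 / rho[i] - tanh(arg) / ap$gb_radius[i])
  }
  out
}

# tiny charged cluster with wildcard-covered atom names
cluster_structure <- function(n = 10, seed = 42, spread = 3) {
  set.seed(seed)
  nm <- rep(c("N", "CA", "C", "O", "CB"), length.out = n)
  atoms <- data.frame(atom_name = nm,
                      residue_number = rep(seq_len(ceiling(n / 5)), each = 5)[seq_len(n)],
                      residue_name = "ALA", chain_id = "A",
                      element = substr(nm, 1, 1), stringsAsFactors = FALSE)
  repeat {
    co <- matrix(stats::runif(3 * n, -spread, spread), ncol = 3)
    if (min(dist(co)) > 1.0) break
  }
  new_structure(atoms, co, label = "cluster")
}
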