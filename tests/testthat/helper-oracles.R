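# Shared oracles and fixture builders for the test suite.

# Central finite-difference gradient of a scalar or component function of
# a 3-vector.
fd_grad <- function(f, r, h = 1e-5) {
  sapply(1:3, function(a) {
    e <- numeric(3); e[a] <- h
    (f(r + e) - f(r - e)) / (2 * h)
  })
}

# Random traceless symmetric quadrupole.
rand_quad <- function(scale = 0.5) {
  m <- matrix(stats::rnorm(9), 3); m <- (m + t(m)) / 2 * scale
  m - diag(sum(diag(m)) / 3, 3)
}

# Point-charge realization of a (q, mu, theta) multipole site: monopole,
# three dipole pairs, and a linear charge triplet per quadrupole
# eigenvector.  Exact multipoles up to the realization spacing delta.
point_charges <- function(q, mu, theta, center, delta) {
  pts <- list(list(q = q, x = center))
  for (a in 1:3) {
    e <- numeric(3); e[a] <- delta / 2
    pts <- c(pts, list(list(q = mu[a] / delta, x = center + e),
                       list(q = -mu[a] / delta, x = center - e)))
  }
  ev <- eigen(theta, symmetric = TRUE)
  for (k in 1:3) {
    c_k <- ev$values[k] / (3 * delta^2)
    v <- ev$vectors[, k]
    pts <- c(pts, list(list(q = c_k, x = center + delta * v),
                       list(q = c_k, x = center - delta * v),
                       list(q = -2 * c_k, x = center)))
  }
  pts
}

coulomb_sum <- function(pa, pb) {
  e <- 0
  for (i in pa) for (j in pb) e <- e + i$q * j$q / sqrt(sum((i$x - j$x)^2))
  e
}

# Richardson-extrapolated point-charge interaction energy between two
# multipole sites (independent oracle for the tensor contractions).
multipole_energy_oracle <- function(qi, mui, thi, qj, muj, thj, R) {
  e1 <- coulomb_sum(point_charges(qi, mui, thi, c(0, 0, 0), 4e-2),
                    point_charges(qj, muj, thj, R, 4e-2))
  e2 <- coulomb_sum(point_charges(qi, mui, thi, c(0, 0, 0), 2e-2),
                    point_charges(qj, muj, thj, R, 2e-2))
  (4 * e2 - e1) / 3
}

# A small fixture dimer with deterministic synthetic properties.
fixture_dimer <- function(names = c("methanol", "formaldehyde"), seed = 7,
                          n_orientations = 1) {
  lib <- monomer_library()[names]
  spec <- synthetic_spec(monomers = names, n_orientations = n_orientations,
                         seed = seed)
  dimers <- sample_dimer_configurations(lib, spec)
  props <- lapply(lib, synth_atomic_properties, seed = seed)
  list(dimers = dimers, props = props,
       params = ground_truth_parameters(seed))
}

# Properties aligned with one sampled dimer.
fixture_props <- function(dim, props) saptfit:::dimer_props(dim, props)

# Rigidly rotate+translate a whole dimer and its properties.
rotate_fixture <- function(dim, pr, R, shift) {
  move <- function(m) {
    m$xyz <- m$xyz %*% t(R) + rep(1, nrow(m$xyz)) %o% shift
    m
  }
  list(dimer = build_dimer(move(dim$monomer_a), move(dim$monomer_b), dim$id),
       props = list(a = rotate_properties(pr$a, R),
                    b = rotate_properties(pr$b, R)))
}
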