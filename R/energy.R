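# The four SAPT-component energy models, evaluated over intermolecular
# atom pairs in atomic units and reported in kcal/mol.

# Normalise the `props` argument: accept a single atomic_properties for
# the whole dimer (A atoms then B atoms) or list(a = ..., b = ...).
split_props <- function(dim, props) {
  na <- length(dim$monomer_a$element)
  nb <- length(dim$monomer_b$element)
  if (inherits(props, "atomic_properties")) {
    if (length(props$element) != na + nb) {
      stop(sprintf("property records (%d) do not match dimer atoms (%d)",
                   length(props$element), na + nb))
    }
    list(a = subset_properties(props, seq_len(na)),
         b = subset_properties(props, na + seq_len(nb)))
  } else if (is.list(props) && !is.null(props$a) && !is.null(props$b)) {
    if (length(props$a$element) != na || length(props$b$element) != nb) {
      stop("per-monomer property records do not match dimer atoms")
    }
    props
  } else {
    stop("props must be atomic_properties or list(a=, b=)")
  }
}

# Pair geometry for a dimer: distances and separation vectors in bohr.
pair_geometry <- function(dim) {
  b2a <- sapt_units[["bohr_per_angstrom"]]
  xa <- dim$monomer_a$xyz * b2a
  xb <- dim$monomer_b$xyz * b2a
  na <- nrow(xa); nb <- nrow(xb)
  ij <- expand.grid(i = seq_len(na), j = seq_len(nb))
  rvec <- xb[ij$j, , drop = FALSE] - xa[ij$i, , drop = FALSE]
  list(i = ij$i, j = ij$j, rvec = rvec, r = sqrt(rowSums(rvec^2)),
       xa = xa, xb = xb)
}

#' Electrostatic component energy
#'
#' Damped multipole electrostatics: over intermolecular pairs,
#' Z_i Z_j / r (bare nuclear term) plus f1-damped nucleus-multipole and
#' f2-damped multipole-multipole contractions, with multipoles truncated
#' at quadrupole.  The f1 damping takes K_elst of the multipole-bearing
#' atom; f2 takes both atoms' K_elst.
#'
#' @param dim A typed `dimer`.
#' @param props `atomic_properties` for the dimer (A atoms then B) or
#'   `list(a=, b=)`.
#' @param params `global_parameters` with K_elst set for all species
#'   present.
#' @return Scalar energy, kcal/mol.
#' @export
elst_energy <- function(dim, props, params) {
  des <- elst_design(dim, split_props(dim, props))
  ke_i <- param_lookup(params, des$si, "K_elst")
  ke_j <- param_lookup(params, des$sj, "K_elst")
  e_h <- sum(des$nuc) +
    sum(damping_f1(ke_j, des$r) * des$zi_mj) +
    sum(damping_f1(ke_i, des$r) * des$mi_zj) +
    sum(damping_f2(ke_i, ke_j, des$r) * des$mi_mj)
  e_h * sapt_units[["kcal_per_hartree"]]
}

# Parameter-independent electrostatic pair contractions (hartree).
elst_design <- function(dim, pr) {
  g <- pair_geometry(dim)
  np <- length(g$r)
  nuc <- zi_mj <- mi_zj <- mi_mj <- numeric(np)
  pa <- pr$a; pb <- pr$b
  for (k in seq_len(np)) {
    i <- g$i[k]; j <- g$j[k]
    tt <- interaction_tensors(g$rvec[k, ], max_rank = 4)
    nuc[k] <- pa$Z[i] * pb$Z[j] / g$r[k]
    zi_mj[k] <- pa$Z[i] *
      contract_charge_multipole(tt, pb$q[j], pb$mu[j, ], pb$theta[, , j], "left")
    mi_zj[k] <- pb$Z[j] *
      contract_charge_multipole(tt, pa$q[i], pa$mu[i, ], pa$theta[, , i], "right")
    mi_mj[k] <- contract_multipole_multipole(
      tt, pa$q[i], pa$mu[i, ], pa$theta[, , i],
      pb$q[j], pb$mu[j, ], pb$theta[, , j])
  }
  list(si = dim$monomer_a$species[g$i], sj = dim$monomer_b$species[g$j],
       r = g$r, nuc = nuc, zi_mj = zi_mj, mi_zj = mi_zj, mi_mj = mi_mj)
}

#' Exchange-repulsion component energy
#'
#' E = sum over intermolecular pairs of K_ij^exch S_ij, with
#' K_ij = sqrt(K_i K_j) and S the density-overlap function of the atomic
#' widths.
#'
#' @inheritParams elst_energy
#' @return Scalar energy, kcal/mol (>= 0 for positive parameters).
#' @export
exch_energy <- function(dim, props, params) {
  pr <- split_props(dim, props)
  g <- pair_geometry(dim)
  s <- overlap_s(pr$a$sigma[g$i], pr$b$sigma[g$j], g$r)
  kij <- combine_pair_k(
    param_lookup(params, dim$monomer_a$species[g$i], "K_exch"),
    param_lookup(params, dim$monomer_b$species[g$j], "K_exch"))
  sum(kij * s) * sapt_units[["kcal_per_hartree"]]
}

#' Dispersion component energy
#'
#' Tang-Toennies damped multipole dispersion:
#' E = sum C6_ij/r^6 f6 + K_ij^disp (C8_ij/r^8 f8 + C10_ij/r^10 f10),
#' with C6 from Hirshfeld-scaled free-atom coefficients, C8/C10 from the
#' effective-charge rules, and K_ij = sqrt(K_i K_j).
#'
#' @inheritParams elst_energy
#' @return Scalar energy, kcal/mol (< 0 for valid inputs).
#' @export
disp_energy <- function(dim, props, params) {
  des <- disp_design(dim, split_props(dim, props))
  kij <- combine_pair_k(param_lookup(params, des$si, "K_disp"),
                        param_lookup(params, des$sj, "K_disp"))
  (sum(des$e6) + sum(kij * des$e810)) * sapt_units[["kcal_per_hartree"]]
}

# Parameter-independent dispersion pair terms (hartree): the damped C6
# sum and the damped C8+C10 sum awaiting its K_disp prefactor.
disp_design <- function(dim, pr) {
  g <- pair_geometry(dim)
  fa <- free_atom_constants(pr$a$element)
  fb <- free_atom_constants(pr$b$element)
  sa <- scale_dispersion_inputs(fa$c6_free, fa$alpha_free, pr$a$h)
  sb <- scale_dispersion_inputs(fb$c6_free, fb$alpha_free, pr$b$h)
  qa <- effective_q(fa$z_nuc, fa$r2, fa$r4)
  qb <- effective_q(fb$z_nuc, fb$r2, fb$r4)

  i <- g$i; j <- g$j; r <- g$r
  c6 <- combine_c6(sa$c6[i], sb$c6[j], sa$alpha[i], sb$alpha[j])
  c810 <- compute_c8_c10(c6, qa[i], qb[j])
  B <- pair_b(pr$a$sigma[i], pr$b$sigma[j])
  x <- tt_x(B, r)
  e6 <- c6 / r^6 * tt_f_of_x(6, x)
  e810 <- c810$c8 / r^8 * tt_f_of_x(8, x) +
    c810$c10 / r^10 * tt_f_of_x(10, x)
  list(si = dim$monomer_a$species[i], sj = dim$monomer_b$species[j],
       r = r, e6 = e6, e810 = e810)
}

#' Converged Thole induced dipoles
#'
#' Induced dipoles on every atom of the dimer from the Thole smeared-dipole
#' model: the zeroth-order dipole is alpha_i times the damped field of the
#' other monomer's permanent multipoles; mutual dipole-dipole coupling over
#' all atoms is converged by successive substitution with mixing factor
#' omega.
#'
#' @param dim A typed `dimer`.
#' @param props Properties for the dimer (see [elst_energy()]).
#' @param constants A `model_constants` object (omega, a_thole, tolerance,
#'   iteration cap).
#' @return n x 3 matrix of induced dipoles (e bohr) with attributes
#'   `iterations`, `residual` and `mu0`.
#' @export
induced_dipoles <- function(dim, props, constants = model_constants()) {
  pr <- split_props(dim, props)
  p <- c_properties(pr$a, pr$b)
  na <- length(pr$a$element)
  n <- length(p$element)
  b2a <- sapt_units[["bohr_per_angstrom"]]
  xyz <- rbind(dim$monomer_a$xyz, dim$monomer_b$xyz) * b2a
  in_a <- seq_len(n) <= na

  fac <- free_atom_constants(p$element)
  alpha <- scale_dispersion_inputs(fac$c6_free, fac$alpha_free, p$h)$alpha
  a_th <- constants$a_thole

  # zeroth-order: damped permanent field from the other monomer.  The
  # monopole source is the net atomic charge Z + q (nucleus plus
  # electrons); the electronic monopole alone would leave every atom
  # polarized by a near-nuclear charge even at long range.
  mu0 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    other <- which(in_a != in_a[i])
    f <- c(0, 0, 0)
    for (j in other) {
      f <- f + thole_field(xyz[i, ] - xyz[j, ], p$Z[j] + p$q[j], p$mu[j, ],
                           p$theta[, , j], alpha[i], alpha[j], a_th)
    }
    mu0[i, ] <- alpha[i] * f
  }

  # mutual dipole-dipole coupling matrix D[ik] = alpha_i * T2_thole(i,k)
  D <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (k == i) next
      tt <- thole_tensors(xyz[i, ] - xyz[k, ], alpha[i], alpha[k], a_th,
                          max_rank = 2)
      D[(3 * i - 2):(3 * i), (3 * k - 2):(3 * k)] <- alpha[i] * tt$T2
    }
  }

  mu <- as.vector(t(mu0))
  mu0v <- mu
  omega <- constants$omega
  res <- Inf
  it <- 0L
  while (it < constants$pol_max_iter) {
    it <- it + 1L
    mu_new <- (1 - omega) * mu + omega * (mu0v + D %*% mu)
    res <- max(abs(mu_new - mu))
    mu <- as.vector(mu_new)
    if (res < constants$pol_tol) break
  }
  if (res >= constants$pol_tol) {
    stop(sprintf("induced dipoles did not converge in %d iterations (residual %.3g a.u.)",
                 constants$pol_max_iter, res))
  }
  out <- matrix(mu, n, 3, byrow = TRUE)
  attr(out, "iterations") <- it
  attr(out, "residual") <- res
  attr(out, "mu0") <- mu0
  attr(out, "alpha") <- alpha
  out
}

# Direct dense linear solve of the coupled polarization equations;
# independent of the fixed-point path (test oracle and internal check).
induced_dipoles_direct <- function(dim, props, constants = model_constants()) {
  pr <- split_props(dim, props)
  p <- c_properties(pr$a, pr$b)
  na <- length(pr$a$element)
  n <- length(p$element)
  b2a <- sapt_units[["bohr_per_angstrom"]]
  xyz <- rbind(dim$monomer_a$xyz, dim$monomer_b$xyz) * b2a
  in_a <- seq_len(n) <= na
  fac <- free_atom_constants(p$element)
  alpha <- scale_dispersion_inputs(fac$c6_free, fac$alpha_free, p$h)$alpha
  a_th <- constants$a_thole

  mu0 <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    for (j in which(in_a != in_a[i])) {
      mu0[i, ] <- mu0[i, ] + alpha[i] *
        thole_field(xyz[i, ] - xyz[j, ], p$Z[j] + p$q[j], p$mu[j, ],
                    p$theta[, , j], alpha[i], alpha[j], a_th)
    }
  }
  A <- diag(3 * n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (k == i) next
    tt <- thole_tensors(xyz[i, ] - xyz[k, ], alpha[i], alpha[k], a_th, 2)
    A[(3 * i - 2):(3 * i), (3 * k - 2):(3 * k)] <- -alpha[i] * tt$T2
  }
  matrix(solve(A, as.vector(t(mu0))), n, 3, byrow = TRUE)
}

#' Induction component energy
#'
#' Polarization energy of the converged Thole induced dipoles in the
#' damped permanent field of the opposite monomer (both polarization
#' directions summed), plus the short-range overlap term
#' K_ij^indu S_ij with K_ij = sqrt(K_i K_j).
#'
#' @inheritParams induced_dipoles
#' @param params `global_parameters` with K_indu set for all species
#'   present.
#' @return Scalar energy, kcal/mol.
#' @export
indu_energy <- function(dim, props, params, constants = model_constants()) {
  pr <- split_props(dim, props)
  e_pol <- polarization_energy(dim, pr, constants)
  g <- pair_geometry(dim)
  s <- overlap_s(pr$a$sigma[g$i], pr$b$sigma[g$j], g$r)
  kij <- combine_pair_k(
    param_lookup(params, dim$monomer_a$species[g$i], "K_indu"),
    param_lookup(params, dim$monomer_b$species[g$j], "K_indu"))
  (e_pol + sum(kij * s)) * sapt_units[["kcal_per_hartree"]]
}

# Parameter-free polarization part of the induction energy (hartree):
# E = - sum_i mu'_i . F_i with F_i the damped permanent field of the
# other monomer (mu0_i / alpha_i).
polarization_energy <- function(dim, pr, constants = model_constants()) {
  mu <- induced_dipoles(dim, pr, constants)
  mu0 <- attr(mu, "mu0")
  alpha <- attr(mu, "alpha")
  -sum(mu * (mu0 / alpha))
}

#' A SAPT component-energy record
#'
#' @param elst,exch,indu,disp Component energies, kcal/mol.
#' @return Object of class `sapt_record` with the total enforced as the
#'   component sum.
#' @export
sapt_record <- function(elst, exch, indu, disp) {
  v <- c(elst = as.numeric(elst), exch = as.numeric(exch),
         indu = as.numeric(indu), disp = as.numeric(disp))
  if (!all(is.finite(v))) stop("non-finite component energy")
  structure(as.list(c(v, total = sum(v))), class = "sapt_record")
}

#' @export
print.sapt_record <- function(x, ...) {
  cat(sprintf("Elst %9.4f  Exch %9.4f  Indu %9.4f  Disp %9.4f  Total %9.4f kcal/mol\n",
              x$elst, x$exch, x$indu, x$disp, x$total))
  invisible(x)
}

#' Total interaction energy with SAPT decomposition
#'
#' Evaluates all four component models and returns them with their sum.
#'
#' @inheritParams indu_energy
#' @return A `sapt_record` (kcal/mol).
#' @export
total_energy <- function(dim, props, params, constants = model_constants()) {
  pr <- split_props(dim, props)
  sapt_record(
    elst = elst_energy(dim, pr, params),
    exch = exch_energy(dim, pr, params),
    indu = indu_energy(dim, pr, params, constants),
    disp = disp_energy(dim, pr, params)
  )
}
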