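# Cartesian multipole interaction tensors: successive gradients of 1/r.
# All conventions follow the standard T-tensor formulation of
# intermolecular electrostatics with Buckingham traceless quadrupoles
# (1/3 and 1/9 contraction factors).

#' Cartesian interaction tensors up to quadrupole rank
#'
#' Returns the derivative tensors of 1/r evaluated at the separation
#' vector: T0 = 1/r, T1_a = d_a(1/r) = -r_a/r^3,
#' T2_ab = (3 r_a r_b - r^2 d_ab)/r^5, and the rank-3 and rank-4
#' gradients needed for dipole-quadrupole and quadrupole-quadrupole
#' interactions.  Units: bohr in, inverse-bohr powers out.
#'
#' @param r_vec Separation 3-vector (bohr), from site i to site j.
#' @param max_rank Highest tensor rank to build (0..4; default 4).
#' @return List with elements `T0` (scalar), `T1` (3-vector), `T2`
#'   (3 x 3), `T3` (3 x 3 x 3), `T4` (3 x 3 x 3 x 3), up to `max_rank`.
#' @export
interaction_tensors <- function(r_vec, max_rank = 4) {
  r_vec <- as.numeric(r_vec)
  r2 <- sum(r_vec^2)
  if (r2 <= 0) stop("zero separation: interaction tensors undefined")
  if (max_rank < 0 || max_rank > 4) stop("max_rank must be in 0..4")
  r <- sqrt(r2)
  out <- list(T0 = 1 / r)
  if (max_rank >= 1) out$T1 <- -r_vec / r^3
  d <- diag(3)
  if (max_rank >= 2) {
    out$T2 <- (3 * outer(r_vec, r_vec) - r2 * d) / r^5
  }
  if (max_rank >= 3) {
    T3 <- array(0, c(3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (g in 1:3) {
      T3[a, b, g] <- -(15 * r_vec[a] * r_vec[b] * r_vec[g] -
                         3 * r2 * (r_vec[a] * d[b, g] +
                                   r_vec[b] * d[a, g] +
                                   r_vec[g] * d[a, b])) / r^7
    }
    out$T3 <- T3
  }
  if (max_rank >= 4) {
    T4 <- array(0, c(3, 3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (g in 1:3) for (e in 1:3) {
      T4[a, b, g, e] <-
        (105 * r_vec[a] * r_vec[b] * r_vec[g] * r_vec[e] -
           15 * r2 * (r_vec[a] * r_vec[b] * d[g, e] +
                      r_vec[a] * r_vec[g] * d[b, e] +
                      r_vec[a] * r_vec[e] * d[b, g] +
                      r_vec[b] * r_vec[g] * d[a, e] +
                      r_vec[b] * r_vec[e] * d[a, g] +
                      r_vec[g] * r_vec[e] * d[a, b]) +
           3 * r2^2 * (d[a, b] * d[g, e] + d[a, g] * d[b, e] +
                       d[a, e] * d[b, g])) / r^9
    }
    out$T4 <- T4
  }
  out
}

# Bilinear multipole-multipole interaction energy pieces, split by which
# side carries the multipoles.  R points from site i to site j.
#
# charge (c) at i against full multipoles M_j:
#   E = c * (T0 q_j + T1 . mu_j + (1/3) T2 : theta_j)
# and symmetrically for M_i against charge at j (T1 flips sign via the
# parity of the odd-rank tensors).
contract_charge_multipole <- function(tt, q, mu, theta, side = c("left", "right")) {
  side <- match.arg(side)
  s1 <- if (side == "left") 1 else -1   # odd-rank parity under i<->j
  tt$T0 * q + s1 * sum(tt$T1 * mu) + sum(tt$T2 * theta) / 3
}

# Full multipole-multipole energy (both sites carry q, mu, theta).
contract_multipole_multipole <- function(tt, qi, mui, thi, qj, muj, thj) {
  e <- qi * qj * tt$T0
  e <- e + sum(tt$T1 * (qi * muj - qj * mui))
  e <- e + sum(tt$T2 * (qi * thj + qj * thi)) / 3
  e <- e - as.numeric(mui %*% tt$T2 %*% muj)
  # dipole-quadrupole: (1/3)(theta_i : T3 . mu_j - mu_i . T3 : theta_j)
  t3_mu_j <- apply(tt$T3, 1, function(m) sum(m * thj))  # contract last two idx
  mu_t3_i <- apply(tt$T3, 3, function(m) sum(m * thi))  # contract first two idx
  e <- e - sum(mui * t3_mu_j) / 3 + sum(mu_t3_i * muj) / 3
  # quadrupole-quadrupole: (1/9) theta_i : T4 : theta_j
  t4m <- matrix(tt$T4, 9, 9)
  e + as.numeric(t(as.vector(thi)) %*% t4m %*% as.vector(thj)) / 9
}

#' Thole-damped interaction tensors
#'
#' Damped T1/T2/T3 tensors for smeared (Thole exponential model) charge
#' distributions, with dimensionless separation u = r/(alpha_i alpha_j)^(1/6)
#' and smearing coefficient a (default 0.39).  The damping factors are
#' lambda3 = 1 - exp(-a u^3), lambda5 = 1 - (1 + a u^3) exp(-a u^3),
#' lambda7 = 1 - (1 + a u^3 + 3/5 a^2 u^6) exp(-a u^3); each multiplies the
#' corresponding radial structure of the bare tensor, and the damped set is
#' derivative-consistent (damped T2 is the gradient of damped T1).
#'
#' @param r_vec Separation 3-vector (bohr).
#' @param alpha_i,alpha_j Atomic polarizabilities (bohr^3), > 0.
#' @param a_thole Smearing coefficient; default 0.39.
#' @param max_rank Highest rank (1..3; default 2).
#' @return List with `T1`, `T2`, `T3` (up to `max_rank`), plus `u`,
#'   `lambda3`, `lambda5`, `lambda7`.
#' @export
thole_tensors <- function(r_vec, alpha_i, alpha_j, a_thole = 0.39,
                          max_rank = 2) {
  if (alpha_i <= 0 || alpha_j <= 0) stop("polarizabilities must be > 0")
  if (a_thole <= 0) stop("a_thole must be > 0")
  r_vec <- as.numeric(r_vec)
  r2 <- sum(r_vec^2)
  if (r2 <= 0) stop("zero separation: Thole tensors undefined")
  r <- sqrt(r2)
  u <- r / (alpha_i * alpha_j)^(1 / 6)
  au3 <- a_thole * u^3
  ex <- exp(-au3)
  l3 <- 1 - ex
  l5 <- 1 - (1 + au3) * ex
  l7 <- 1 - (1 + au3 + 0.6 * au3^2) * ex
  d <- diag(3)
  out <- list(u = u, lambda3 = l3, lambda5 = l5, lambda7 = l7)
  out$T1 <- -l3 * r_vec / r^3
  if (max_rank >= 2) {
    out$T2 <- (l5 * 3 * outer(r_vec, r_vec) - l3 * r2 * d) / r^5
  }
  if (max_rank >= 3) {
    T3 <- array(0, c(3, 3, 3))
    for (a in 1:3) for (b in 1:3) for (g in 1:3) {
      T3[a, b, g] <- -(l7 * 15 * r_vec[a] * r_vec[b] * r_vec[g] -
                         l5 * 3 * r2 * (r_vec[a] * d[b, g] +
                                        r_vec[b] * d[a, g] +
                                        r_vec[g] * d[a, b])) / r^7
    }
    out$T3 <- T3
  }
  out
}

# Thole-damped electric field at a site from permanent multipoles
# (q, mu, theta) at separation R = r_site - r_source (bohr).
# F_a = -T1_a q + T2_ab mu_b - (1/3) T3_abg theta_bg, with damped tensors.
thole_field <- function(R, q, mu, theta, alpha_i, alpha_j, a_thole = 0.39) {
  tt <- thole_tensors(R, alpha_i, alpha_j, a_thole, max_rank = 3)
  f <- -tt$T1 * q
  f <- f + as.numeric(tt$T2 %*% mu)
  f - apply(tt$T3, 1, function(m) sum(m * theta)) / 3
}
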