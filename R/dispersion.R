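# Dispersion-coefficient combination rules.

#' Combine atomic C6 coefficients into a pair coefficient
#'
#' C6_ij = -2 C6_i C6_j / ((alpha_j/alpha_i) C6_i + (alpha_i/alpha_j) C6_j),
#' the polarizability-weighted combination; negative by the model's sign
#' convention (attractive), symmetric, and |C6_ii| = C6_i for identical
#' atoms.
#'
#' @param c6_i,c6_j Atomic C6 coefficients (hartree bohr^6), > 0
#'   (vectorized).
#' @param alpha_i,alpha_j Atomic polarizabilities (bohr^3), > 0.
#' @return Pair coefficient C6_ij (< 0).
#' @export
combine_c6 <- function(c6_i, c6_j, alpha_i, alpha_j) {
  if (any(c6_i <= 0) || any(c6_j <= 0)) stop("atomic C6 must be > 0")
  if (any(alpha_i <= 0) || any(alpha_j <= 0)) stop("polarizabilities must be > 0")
  -2 * c6_i * c6_j / ((alpha_j / alpha_i) * c6_i + (alpha_i / alpha_j) * c6_j)
}

#' Higher dispersion coefficients C8 and C10
#'
#' C8_ij = 3 C6_ij sqrt(Q_i Q_j) and C10_ij = (49/40) C8_ij^2 / C6_ij,
#' with Q the effective dispersion charge from free-atom density moments
#' (see [effective_q()]).  Both inherit the sign of C6_ij, and the
#' identity C10 C6 / C8^2 = 49/40 holds exactly.
#'
#' @param c6_ij Pair C6 coefficient, non-zero (vectorized).
#' @param q_i,q_j Effective dispersion charges (bohr^2), > 0.
#' @return List with components `c8` and `c10`.
#' @export
compute_c8_c10 <- function(c6_ij, q_i, q_j) {
  if (any(c6_ij == 0)) stop("C6_ij must be non-zero (C10 undefined)")
  if (any(q_i <= 0) || any(q_j <= 0)) stop("effective charges Q must be > 0")
  c8 <- 3 * c6_ij * sqrt(q_i * q_j)
  list(c8 = c8, c10 = (49 / 40) * c8^2 / c6_ij)
}
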