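# Short-range damping functions for the electrostatic, exchange and
# dispersion models.  All arguments in atomic units.

#' One-sided charge-penetration damping f1
#'
#' f1(r) = 1 - exp(-K r).  Multiplies the nucleus-multipole contractions
#' of the electrostatic model.
#'
#' @param K Species damping parameter (1/bohr), > 0 (vectorized).
#' @param r Separation (bohr), >= 0 (vectorized).
#' @return Value in [0, 1).
#' @export
damping_f1 <- function(K, r) {
  if (any(K <= 0)) stop("damping parameter K must be > 0")
  if (any(r < 0)) stop("separation r must be >= 0")
  1 - exp(-K * r)
}

#' Two-sided charge-penetration damping f2
#'
#' f2(r) = 1 - Ki^2/(Ki^2 - Kj^2) exp(-Ki r) - Kj^2/(Kj^2 - Ki^2) exp(-Kj r),
#' symmetric in (Ki, Kj); multiplies the multipole-multipole contractions.
#' When |Ki - Kj| < 1e-6 max(Ki, Kj) the analytic equal-K limit
#' 1 - exp(-K r)(1 - K r / 2) is used.  Note the two-exponential form
#' approaches 1 from above at long range when Ki != Kj.
#'
#' @param K_i,K_j Species damping parameters (1/bohr), > 0 (vectorized).
#' @param r Separation (bohr), >= 0 (vectorized).
#' @return f2 value; 0 at r = 0, tending to 1 as r grows.
#' @export
damping_f2 <- function(K_i, K_j, r) {
  if (any(K_i <= 0) || any(K_j <= 0)) stop("damping parameters must be > 0")
  if (any(r < 0)) stop("separation r must be >= 0")
  n <- max(length(K_i), length(K_j), length(r))
  K_i <- rep_len(K_i, n); K_j <- rep_len(K_j, n); r <- rep_len(r, n)
  near <- abs(K_i - K_j) < 1e-6 * pmax(K_i, K_j)
  out <- numeric(n)
  if (any(near)) {
    K <- 0.5 * (K_i[near] + K_j[near])
    x <- K * r[near]
    out[near] <- 1 - exp(-x) * (1 - x / 2)
  }
  if (any(!near)) {
    ki <- K_i[!near]; kj <- K_j[!near]; rr <- r[!near]
    den <- ki^2 - kj^2
    out[!near] <- 1 - (ki^2 / den) * exp(-ki * rr) +
      (kj^2 / den) * exp(-kj * rr)
  }
  out
}

#' Density-overlap function S
#'
#' S(r) = (1/3 (B r)^2 + B r + 1) exp(-B r) with inverse width
#' B = (sigma_i sigma_j)^(-1/2); S(0) = 1 and S decreases monotonically.
#' Drives the exchange-repulsion model and the short-range induction term.
#'
#' @param sigma_i,sigma_j Atomic widths (bohr), > 0 (vectorized).
#' @param r Separation (bohr), >= 0 (vectorized).
#' @return Overlap value in (0, 1].
#' @export
overlap_s <- function(sigma_i, sigma_j, r) {
  if (any(sigma_i <= 0) || any(sigma_j <= 0)) stop("atomic widths must be > 0")
  if (any(r < 0)) stop("separation r must be >= 0")
  B <- 1 / sqrt(sigma_i * sigma_j)
  x <- B * r
  (x^2 / 3 + x + 1) * exp(-x)
}

# Inverse-width combination used by both the overlap and the
# Tang-Toennies x argument.
pair_b <- function(sigma_i, sigma_j) 1 / sqrt(sigma_i * sigma_j)

#' Tang-Toennies dispersion damping
#'
#' f_n(r) = 1 - exp(-x) sum_{k=0}^{n} x^k / k!, with
#' x = B r + r (2 B^2 + 3 B) / ((B r)^2 + 3 B r + 3) and B the pair
#' inverse width.  Removes the short-range divergence of the r^-n
#' dispersion terms.
#'
#' @param n Damping order, one of 6, 8, 10.
#' @param B_ij Pair inverse width (1/bohr), > 0 (scalar).
#' @param r Separation (bohr), >= 0 (vectorized).
#' @return f_n in [0, 1]; 0 at r = 0, 1 at large r.
#' @export
tt_damping <- function(n, B_ij, r) {
  if (!n %in% c(6, 8, 10)) stop("Tang-Toennies order n must be 6, 8 or 10")
  if (any(B_ij <= 0)) stop("pair inverse width B must be > 0")
  if (any(r < 0)) stop("separation r must be >= 0")
  x <- tt_x(B_ij, r)
  tt_f_of_x(n, x)
}

# The Tang-Toennies x(r) argument.
tt_x <- function(B, r) {
  B * r + r * (2 * B^2 + 3 * B) / ((B * r)^2 + 3 * B * r + 3)
}

# f_n as a function of x: 1 - exp(-x) * sum_{k=0}^n x^k/k!.
tt_f_of_x <- function(n, x) {
  s <- rep(1, length(x))
  term <- rep(1, length(x))
  for (k in seq_len(n)) {
    term <- term * x / k
    s <- s + term
  }
  pmin(pmax(1 - exp(-x) * s, 0), 1)
}
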