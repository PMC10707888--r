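#' Global per-species parameters
#'
#' One positive scalar per species and component: K_elst (electrostatic
#' damping, 1/bohr), K_exch, K_indu (overlap prefactors, hartree) and
#' K_disp (dimensionless C8/C10 scale).  Species that never occurred in a
#' training set stay unset (NA), mirroring the blank cells of a fitted
#' parameter table.
#'
#' @param species Character vector of species labels (subset of
#'   [species_vocabulary()]); defaults to the full vocabulary.
#' @param K_elst,K_exch,K_indu,K_disp Numeric vectors aligned with
#'   `species`; NA = unset, set values must be > 0.
#' @return Object of class `global_parameters`: a data.frame with row per
#'   species.
#' @export
global_parameters <- function(species = species_vocabulary(),
                              K_elst = NA_real_, K_exch = NA_real_,
                              K_indu = NA_real_, K_disp = NA_real_) {
  bad <- setdiff(species, species_vocabulary())
  if (length(bad) > 0) {
    stop("unknown species label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(species)) stop("duplicated species labels")
  df <- data.frame(
    species = as.character(species),
    K_elst = rep_len(as.numeric(K_elst), length(species)),
    K_exch = rep_len(as.numeric(K_exch), length(species)),
    K_indu = rep_len(as.numeric(K_indu), length(species)),
    K_disp = rep_len(as.numeric(K_disp), length(species)),
    stringsAsFactors = FALSE
  )
  for (col in c("K_elst", "K_exch", "K_indu", "K_disp")) {
    v <- df[[col]]
    if (any(!is.na(v) & v <= 0)) stop(col, " values must be > 0 where set")
  }
  class(df) <- c("global_parameters", "data.frame")
  df
}

#' Look up per-species parameter values
#'
#' @param params A `global_parameters` object.
#' @param species Character vector of species labels.
#' @param component One of "K_elst", "K_exch", "K_indu", "K_disp".
#' @return Numeric vector of values; error naming the species if any
#'   requested value is unset or the species is absent.
#' @export
param_lookup <- function(params, species, component) {
  component <- match.arg(component, c("K_elst", "K_exch", "K_indu", "K_disp"))
  idx <- match(species, params$species)
  if (anyNA(idx)) {
    stop("no parameter row for species: ",
         paste(unique(species[is.na(idx)]), collapse = ", "))
  }
  v <- params[[component]][idx]
  if (anyNA(v)) {
    stop(component, " unset for species: ",
         paste(unique(species[is.na(v)]), collapse = ", "))
  }
  v
}

#' Pair parameter combination rule
#'
#' K_ij = sqrt(K_i K_j): symmetric, positivity-preserving, and reduces to
#' K_i for homoatomic pairs, which makes the per-species scalars
#' identifiable from homodimer data.  Used for the exchange, induction and
#' dispersion prefactors.
#'
#' @param K_i,K_j Per-species values, > 0 (vectorized).
#' @return Geometric-mean pair values.
#' @export
combine_pair_k <- function(K_i, K_j) {
  if (any(K_i <= 0) || any(K_j <= 0)) stop("pair parameters must be > 0")
  sqrt(K_i * K_j)
}

#' Write a parameter table to CSV
#'
#' Layout: one row per species, columns Kelst/Kexch/Kindu/Kdisp; unset
#' values are written as empty cells (blanks).
#'
#' @param params A `global_parameters` object.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_parameters <- function(params, file) {
  out <- data.frame(
    species = params$species,
    Kelst = ifelse(is.na(params$K_elst), "", sprintf("%.10g", params$K_elst)),
    Kexch = ifelse(is.na(params$K_exch), "", sprintf("%.10g", params$K_exch)),
    Kindu = ifelse(is.na(params$K_indu), "", sprintf("%.10g", params$K_indu)),
    Kdisp = ifelse(is.na(params$K_disp), "", sprintf("%.10g", params$K_disp)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a parameter table from CSV
#'
#' @param file Path to a CSV written by [write_parameters()] (blank cells
#'   = unset species).
#' @return A `global_parameters` object.
#' @export
read_parameters <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE,
                        colClasses = c("character", rep("character", 4)))
  num <- function(x) suppressWarnings(ifelse(nzchar(trimws(x)), as.numeric(x), NA_real_))
  global_parameters(
    species = df$species,
    K_elst = num(df$Kelst), K_exch = num(df$Kexch),
    K_indu = num(df$Kindu), K_disp = num(df$Kdisp)
  )
}

#' Model constants for the induction solver
#'
#' @param omega Self-consistency mixing factor (0 < omega <= 1); default
#'   0.7.
#' @param a_thole Thole smearing coefficient; default 0.39.
#' @param pol_tol Convergence tolerance for induced dipoles (a.u.);
#'   default 1e-8.
#' @param pol_max_iter Iteration cap; default 500.
#' @return List of class `model_constants`.
#' @export
model_constants <- function(omega = 0.7, a_thole = 0.39,
                            pol_tol = 1e-8, pol_max_iter = 500) {
  if (omega <= 0 || omega > 1) stop("omega must be in (0, 1]")
  if (a_thole <= 0) stop("a_thole must be > 0")
  structure(list(omega = omega, a_thole = a_thole,
                 pol_tol = pol_tol, pol_max_iter = pol_max_iter),
            class = "model_constants")
}
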