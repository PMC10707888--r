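# Seeded synthetic-data generator: idealized monomer library, dimer
# configuration sampling, plausible atomic properties, ground-truth
# parameters and forward-model reference energies.  The model itself is
# the ground truth (a well-specified recovery problem); realism enters
# through the geometry and property ranges only.

# Run code with a private RNG stream, restoring global state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic small-integer hash of a monomer's content, mixed with a
# user seed (keeps identical monomers' properties identical).
monomer_hash <- function(mon, seed) {
  s <- paste(mon$element, apply(round(mon$xyz, 6), 1, paste, collapse = ","),
             collapse = ";")
  codes <- utf8ToInt(s)
  h <- sum(codes * (seq_along(codes) %% 97 + 1)) %% 1048573
  as.integer((h * 31 + (as.numeric(seed) %% 65521) * 7919) %% 2147483629)
}

# Idealized tetrahedral methyl hydrogens attached to heavy atom at
# `center` with the substituent along +x.
methyl_h <- function(center, d = 1.09) {
  rad <- sqrt(8) / 3             # tetrahedral: direction (-1/3, rad cos, rad sin)
  t(vapply(0:2, function(k) {
    phi <- 2 * pi * k / 3
    center + d * c(-1 / 3, rad * cos(phi), rad * sin(phi))
  }, numeric(3)))
}

#' Idealized small-molecule monomer library
#'
#' Thirteen small organics with idealized equilibrium-like geometries
#' whose union of atom species covers the full 17-label vocabulary, each
#' typed and tagged with a functional-group class.
#'
#' @return Named list of typed `monomer` objects.
#' @export
monomer_library <- function() {
  mk <- function(name, cls, el, xyz) {
    m <- monomer(el, xyz, class_label = cls, name = name)
    assign_atom_types(perceive_bonds(m))
  }
  lib <- list()

  td <- 1.09 / sqrt(3)
  lib$methane <- mk("methane", "Alkane",
    c("C", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(td, td, td), c(td, -td, -td),
          c(-td, td, -td), c(-td, -td, td)))

  ch <- 1.09; s1 <- sin(58.7 * pi / 180); c1 <- cos(58.7 * pi / 180)
  lib$ethylene <- mk("ethylene", "Alkene",
    c("C", "C", "H", "H", "H", "H"),
    rbind(c(-0.6665, 0, 0), c(0.6665, 0, 0),
          c(-0.6665 - ch * c1,  ch * s1, 0), c(-0.6665 - ch * c1, -ch * s1, 0),
          c(0.6665 + ch * c1,  ch * s1, 0), c(0.6665 + ch * c1, -ch * s1, 0)))

  lib$ethyne <- mk("ethyne", "Alkyne",
    c("C", "C", "H", "H"),
    rbind(c(-0.60, 0, 0), c(0.60, 0, 0), c(-1.66, 0, 0), c(1.66, 0, 0)))

  lib$methanol <- mk("methanol", "Alcohol",
    c("C", "O", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.43, 0, 0),
          c(1.43, 0, 0) + 0.96 * c(cos(71.5 * pi / 180), sin(71.5 * pi / 180), 0),
          methyl_h(c(0, 0, 0))))

  lib$formaldehyde <- mk("formaldehyde", "Aldehyde",
    c("C", "O", "H", "H"),
    rbind(c(0, 0, 0), c(1.21, 0, 0),
          c(-1.09 * cos(58 * pi / 180),  1.09 * sin(58 * pi / 180), 0),
          c(-1.09 * cos(58 * pi / 180), -1.09 * sin(58 * pi / 180), 0)))

  nh <- 1.01; a71 <- 71 * pi / 180
  lib$methylamine <- mk("methylamine", "Amine",
    c("C", "N", "H", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.47, 0, 0),
          c(1.47, 0, 0) + nh * c(cos(a71), sin(a71) * cos(pi / 3),
                                 sin(a71) * sin(pi / 3)),
          c(1.47, 0, 0) + nh * c(cos(a71), sin(a71) * cos(pi / 3),
                                 -sin(a71) * sin(pi / 3)),
          methyl_h(c(0, 0, 0))))

  lib$methanimine <- mk("methanimine", "Imine",
    c("C", "N", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.28, 0, 0),
          c(1.28, 0, 0) + 1.01 * c(cos(70 * pi / 180), sin(70 * pi / 180), 0),
          c(-1.09 * cos(60 * pi / 180),  1.09 * sin(60 * pi / 180), 0),
          c(-1.09 * cos(60 * pi / 180), -1.09 * sin(60 * pi / 180), 0)))

  lib$hydrogen_cyanide <- mk("hydrogen_cyanide", "Nitrile",
    c("C", "N", "H"),
    rbind(c(0, 0, 0), c(1.16, 0, 0), c(-1.07, 0, 0)))

  a84 <- 84 * pi / 180
  lib$methanethiol <- mk("methanethiol", "Thiol",
    c("C", "S", "H", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.82, 0, 0),
          c(1.82, 0, 0) + 1.34 * c(cos(a84), sin(a84), 0),
          methyl_h(c(0, 0, 0))))

  lib$thioformaldehyde <- mk("thioformaldehyde", "Thiocarbonyl",
    c("C", "S", "H", "H"),
    rbind(c(0, 0, 0), c(1.61, 0, 0),
          c(-1.09 * cos(60 * pi / 180),  1.09 * sin(60 * pi / 180), 0),
          c(-1.09 * cos(60 * pi / 180), -1.09 * sin(60 * pi / 180), 0)))

  lib$fluoromethane <- mk("fluoromethane", "Haloalkane",
    c("C", "F", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.38, 0, 0), methyl_h(c(0, 0, 0))))
  lib$chloromethane <- mk("chloromethane", "Haloalkane",
    c("C", "Cl", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.78, 0, 0), methyl_h(c(0, 0, 0))))
  lib$bromomethane <- mk("bromomethane", "Haloalkane",
    c("C", "Br", "H", "H", "H"),
    rbind(c(0, 0, 0), c(1.94, 0, 0), methyl_h(c(0, 0, 0))))
  lib
}

#' Synthetic-study specification
#'
#' The generator's study conditions: which library monomers to use, the
#' sampled center-to-center separations (bohr), orientations per monomer
#' pair, per-component reference noise, and the mandatory seed.
#'
#' @param monomers Character vector of [monomer_library()] names (default
#'   all 13, covering the 17 species).
#' @param separations Length-2 window, in bohr within [3, 30], for the
#'   closest intermolecular contact distance of a sampled configuration;
#'   default c(4.5, 6.5), spanning hydrogen-bond-like to loose van der
#'   Waals contacts (about 2.4-3.4 Angstrom) as an equilibrium dimer set
#'   does.
#' @param n_orientations Configurations sampled per monomer pair;
#'   default 4.
#' @param noise_sd Per-component Gaussian noise on reference energies,
#'   kcal/mol; default 0.
#' @param seed Integer seed (mandatory).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(monomers = names(monomer_library()),
                           separations = c(4.5, 6.5), n_orientations = 4,
                           noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (length(separations) != 2 || separations[1] > separations[2] ||
      separations[1] < 3 || separations[2] > 30) {
    stop("separations must be an increasing range within [3, 30] bohr")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(monomers = monomers, separations = separations,
                 n_orientations = n_orientations, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Centre a monomer at the origin, rotate by R, then translate by shift
# (Angstrom).
transform_monomer <- function(mon, R = diag(3), shift = c(0, 0, 0)) {
  out <- mon
  ctr <- colMeans(mon$xyz)
  out$xyz <- sweep(sweep(mon$xyz, 2, ctr) %*% t(R), 2, shift, `+`)
  out
}

#' Rotate tensor atomic properties
#'
#' Co-rotates dipoles (mu' = R mu) and quadrupoles (theta' = R theta R^T)
#' with a rigid rotation of the parent monomer; scalar properties are
#' unchanged.
#'
#' @param props An `atomic_properties` object.
#' @param R 3 x 3 rotation matrix.
#' @return Rotated `atomic_properties`.
#' @export
rotate_properties <- function(props, R) {
  n <- length(props$element)
  mu <- props$mu %*% t(R)
  theta <- props$theta
  for (i in seq_len(n)) theta[, , i] <- R %*% theta[, , i] %*% t(R)
  atomic_properties(props$element, props$q, mu, theta, props$Z,
                    props$sigma, props$h)
}

#' Sample dimer configurations
#'
#' Homodimers (X, X) and/or heterodimers (X, Y) of library monomers at
#' seeded random orientations.  Monomer A keeps its reference
#' orientation at the origin; monomer B is randomly rotated and slid
#' along a random direction until the closest intermolecular contact
#' equals a distance drawn from the spec's separation window, emulating
#' equilibrium-state dimers.  Configurations with any intermolecular
#' contact closer than 1.5 bohr are rejected and resampled (up to 100
#' attempts).
#'
#' @param monomers Named list of typed monomers (see [monomer_library()]).
#' @param spec A `synthetic_spec`.
#' @param which One of "both", "homo", "hetero".
#' @return List of `dimer` objects; each monomer carries `lib_name` and
#'   `rotation` fields for property alignment, and each dimer a
#'   `pairing` field ("homo"/"hetero").
#' @export
sample_dimer_configurations <- function(monomers, spec, which = "both") {
  which <- match.arg(which, c("both", "homo", "hetero"))
  nm <- names(monomers)
  pairs <- list()
  if (which %in% c("both", "homo")) {
    for (a in nm) pairs[[length(pairs) + 1]] <- c(a, a)
  }
  if (which %in% c("both", "hetero")) {
    if (length(nm) > 1) {
      for (u in seq_along(nm)) for (v in seq_along(nm)) {
        if (u < v) pairs[[length(pairs) + 1]] <- c(nm[u], nm[v])
      }
    }
  }
  a2b <- sapt_units[["angstrom_per_bohr"]]
  with_seed(spec$seed, {
    out <- list()
    for (p in pairs) {
      ma0 <- monomers[[p[1]]]
      mb0 <- monomers[[p[2]]]
      for (k in seq_len(spec$n_orientations)) {
        placed <- NULL
        for (attempt in 1:100) {
          gap_bohr <- stats::runif(1, spec$separations[1], spec$separations[2])
          u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
          Rb <- random_rotation()
          ma <- transform_monomer(ma0, diag(3), c(0, 0, 0))
          # slide B along u until min contact equals the drawn gap
          contact_at <- function(d) {
            mbd <- transform_monomer(mb0, Rb, u * d * a2b)
            min(intermolecular_distances(ma$xyz, mbd$xyz)) *
              sapt_units[["bohr_per_angstrom"]]
          }
          lo <- 0; hi <- 60
          for (bis in 1:50) {
            mid <- (lo + hi) / 2
            if (contact_at(mid) < gap_bohr) lo <- mid else hi <- mid
          }
          mb <- transform_monomer(mb0, Rb, u * hi * a2b)
          if (min(intermolecular_distances(ma$xyz, mb$xyz)) *
              sapt_units[["bohr_per_angstrom"]] >= 1.5) {
            ma$lib_name <- p[1]; ma$rotation <- diag(3)
            mb$lib_name <- p[2]; mb$rotation <- Rb
            placed <- build_dimer(ma, mb,
              id = sprintf("%s|%s#%d", p[1], p[2], k))
            placed$pairing <- if (p[1] == p[2]) "homo" else "hetero"
            break
          }
        }
        if (is.null(placed)) {
          stop(sprintf("could not place %s|%s without clash in 100 attempts",
                       p[1], p[2]))
        }
        out[[length(out) + 1]] <- placed
      }
    }
    out
  })
}

# Species-typical net atomic charges (e) before the neutrality shift.
SPECIES_NET_Q <- c(
  C4 = -0.10, C3 = 0.10, C2 = 0.05,
  N3 = -0.80, N2 = -0.50, N1 = -0.35,
  O2 = -0.55, O1 = -0.45, S2 = -0.20, S1 = -0.20,
  HC = 0.05, HN = 0.33, HO = 0.42, HS = 0.12,
  F = -0.25, Cl = -0.15, Br = -0.10
)

# Effective nuclear charges (valence electron counts) used in the
# electrostatic nuclear terms.
ELEMENT_Z_EFF <- c(C = 4, H = 1, N = 5, O = 6, S = 6, F = 7, Cl = 7, Br = 7)

# Element-typical atomic width ranges (bohr).
SIGMA_RANGE <- list(
  H = c(0.50, 0.62), C = c(0.75, 0.95), N = c(0.72, 0.90),
  O = c(0.68, 0.85), S = c(0.90, 1.10), F = c(0.62, 0.78),
  Cl = c(0.85, 1.05), Br = c(0.95, 1.20)
)

#' Synthesize plausible atomic properties for a monomer
#'
#' Deterministic per (monomer content, seed): species-typical net charges
#' jittered and shifted to exact monomer neutrality, small random dipoles
#' and traceless quadrupoles, element-typical widths in [0.5, 1.2] bohr,
#' Hirshfeld ratios in [0.7, 1.25].  The multipole monopole is stored as
#' net charge minus the effective nuclear charge Z, so the electrostatic
#' charge terms reduce to net-charge Coulomb at long range.
#'
#' @param mon A typed `monomer`.
#' @param seed Integer seed.
#' @return An `atomic_properties` object (reference orientation of the
#'   monomer).
#' @export
synth_atomic_properties <- function(mon, seed) {
  if (is.null(mon$species)) stop("monomer must be typed")
  n <- length(mon$element)
  with_seed(monomer_hash(mon, seed), {
    qnet <- SPECIES_NET_Q[mon$species] + stats::rnorm(n, sd = 0.03)
    qnet <- qnet - mean(qnet)                      # exact neutrality
    Z <- unname(ELEMENT_Z_EFF[mon$element])
    mu <- matrix(stats::rnorm(3 * n, sd = 0.06), n, 3)
    theta <- array(0, c(3, 3, n))
    for (i in seq_len(n)) {
      m <- matrix(stats::rnorm(9, sd = 0.08), 3, 3)
      m <- (m + t(m)) / 2
      theta[, , i] <- m - diag(sum(diag(m)) / 3, 3)
    }
    sigma <- vapply(mon$element, function(el) {
      rg <- SIGMA_RANGE[[el]]; stats::runif(1, rg[1], rg[2])
    }, numeric(1))
    h <- stats::runif(n, 0.7, 1.25)
    atomic_properties(mon$element, q = unname(qnet) - Z, mu = mu,
                      theta = theta, Z = Z, sigma = unname(sigma), h = h)
  })
}

#' Draw ground-truth global parameters
#'
#' All 17 species set, drawn uniformly from ranges bracketing typical
#' fitted magnitudes: K_elst in [2.5, 5.5] 1/bohr, K_exch in [0.5, 7],
#' K_indu in [0.1, 2.5], K_disp in [0.1, 1].
#'
#' @param seed Integer seed.
#' @return A fully populated `global_parameters` object.
#' @export
ground_truth_parameters <- function(seed) {
  sp <- species_vocabulary()
  with_seed(as.integer(seed) + 104729L, {
    global_parameters(
      species = sp,
      K_elst = stats::runif(17, 2.5, 5.5),
      K_exch = stats::runif(17, 0.5, 7.0),
      K_indu = stats::runif(17, 0.1, 2.5),
      K_disp = stats::runif(17, 0.1, 1.0)
    )
  })
}

# Properties for one sampled dimer: look up the library properties of
# each monomer and co-rotate them with the monomer's stored rotation.
dimer_props <- function(dim, props_by_name) {
  pa <- props_by_name[[dim$monomer_a$lib_name]]
  pb <- props_by_name[[dim$monomer_b$lib_name]]
  if (is.null(pa) || is.null(pb)) stop("missing library properties for dimer")
  list(a = rotate_properties(pa, dim$monomer_a$rotation),
       b = rotate_properties(pb, dim$monomer_b$rotation))
}

#' Forward-model reference dataset
#'
#' Evaluates the model under the ground-truth parameters for every dimer
#' and stores the component energies, plus independent per-component
#' Gaussian noise, as the reference data; the reference total is
#' recomputed as the component sum after noising.
#'
#' @param dimers List of sampled dimers (see
#'   [sample_dimer_configurations()]).
#' @param props_by_name Named list of library `atomic_properties`.
#' @param params Ground-truth `global_parameters`.
#' @param noise_sd Per-component Gaussian noise sd, kcal/mol.
#' @param seed Integer seed for the noise stream.
#' @param constants `model_constants` for the induction solver.
#' @return A `sapt_dataset` whose records carry reference energies and
#'   homo/hetero split tags.
#' @export
generate_reference_dataset <- function(dimers, props_by_name, params,
                                       noise_sd = 0, seed = 1L,
                                       constants = model_constants()) {
  records <- lapply(dimers, function(d) {
    dimer_record(d, dimer_props(d, props_by_name),
                 class_label = d$monomer_a$class_label,
                 split = d$pairing)
  })
  ds <- sapt_dataset(records)
  sp <- dataset_species(ds)
  des <- build_design(ds, sp, constants)
  pred <- eval_design(des,
                      param_lookup(params, sp, "K_elst"),
                      param_lookup(params, sp, "K_exch"),
                      param_lookup(params, sp, "K_indu"),
                      param_lookup(params, sp, "K_disp"))
  with_seed(as.integer(seed) + 7919L, {
    for (m in seq_along(records)) {
      e <- pred[m, 1:4]
      if (noise_sd > 0) e <- e + stats::rnorm(4, sd = noise_sd)
      records[[m]]$ref <- sapt_record(e[1], e[2], e[3], e[4])
    }
  })
  sapt_dataset(records)
}

#' Split records into homodimer train / heterodimer test sets
#'
#' @param dataset A `sapt_dataset` whose records carry "homo"/"hetero"
#'   split tags.
#' @return List with `train` (homodimers) and `test` (heterodimers)
#'   datasets; errors if either side is empty.
#' @export
split_train_test <- function(dataset) {
  tags <- vapply(dataset$records, function(r) as.character(r$split), character(1))
  if (!all(tags %in% c("homo", "hetero"))) {
    stop("records must be tagged homo/hetero")
  }
  tr <- dataset$records[tags == "homo"]
  te <- dataset$records[tags == "hetero"]
  if (length(tr) == 0) stop("no homodimer (training) records")
  if (length(te) == 0) stop("no heterodimer (test) records")
  tr <- lapply(tr, function(r) { r$split <- "train"; r })
  te <- lapply(te, function(r) { r$split <- "test"; r })
  list(train = sapt_dataset(tr), test = sapt_dataset(te))
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: monomer library subset, homodimer + heterodimer
#' configurations, per-monomer properties, ground-truth parameters and
#' noised forward-model references, split into homodimer-train /
#' heterodimer-test datasets.
#'
#' @param spec A `synthetic_spec`.
#' @param constants `model_constants`.
#' @return List with `train`, `test` (`sapt_dataset`), `truth`
#'   (`global_parameters`), `monomers`, `props_by_name`.
#' @export
generate_synthetic_study <- function(spec, constants = model_constants()) {
  lib <- monomer_library()[spec$monomers]
  if (any(vapply(lib, is.null, TRUE))) stop("unknown monomer name in spec")
  dimers <- sample_dimer_configurations(lib, spec, which = "both")
  props <- lapply(lib, synth_atomic_properties, seed = spec$seed)
  truth <- ground_truth_parameters(spec$seed)
  ds <- generate_reference_dataset(dimers, props, truth,
                                   noise_sd = spec$noise_sd,
                                   seed = spec$seed, constants = constants)
  c(split_train_test(ds),
    list(truth = truth, monomers = lib, props_by_name = props))
}
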