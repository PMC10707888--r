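# Precomputed per-record design structures.  All parameter-independent
# quantities (multipole contractions, overlaps, damped dispersion sums,
# the polarization energy) are evaluated once per dimer; afterwards every
# component energy is a short vectorized expression in the per-species
# parameters, which is what makes repeated loss evaluation inside BFGS
# cheap.

#' Assemble a training/test record
#'
#' @param dim A typed `dimer`.
#' @param props Properties for the dimer (whole-dimer
#'   `atomic_properties` or `list(a=, b=)`).
#' @param ref Optional reference `sapt_record` (kcal/mol).
#' @param class_label Optional functional-group class.
#' @param split Optional split tag ("train"/"test").
#' @return Object of class `sapt_dimer_record`.
#' @export
dimer_record <- function(dim, props, ref = NULL, class_label = NA_character_,
                         split = NA_character_) {
  pr <- split_props(dim, props)
  if (!is.null(ref)) {
    stopifnot(inherits(ref, "sapt_record"))
    if (abs(ref$total - (ref$elst + ref$exch + ref$indu + ref$disp)) > 1e-6) {
      stop("reference total does not equal component sum")
    }
  }
  structure(list(id = dim$id, dimer = dim, props = pr, ref = ref,
                 class_label = class_label, split = split),
            class = "sapt_dimer_record")
}

#' Bundle records into a dataset
#'
#' @param records List of `sapt_dimer_record` objects.
#' @return Object of class `sapt_dataset`.
#' @export
sapt_dataset <- function(records) {
  if (length(records) == 0) stop("empty dataset")
  stopifnot(all(vapply(records, inherits, TRUE, "sapt_dimer_record")))
  structure(list(records = records), class = "sapt_dataset")
}

#' @export
print.sapt_dataset <- function(x, ...) {
  spl <- vapply(x$records, function(r) as.character(r$split), character(1))
  cat(sprintf("sapt_dataset: %d records (%s)\n", length(x$records),
              paste(names(table(spl, useNA = "ifany")),
                    table(spl, useNA = "ifany"), sep = "=", collapse = ", ")))
  invisible(x)
}

#' Species present in a dataset
#' @param dataset A `sapt_dataset`.
#' @return Sorted character vector of species labels occurring in any
#'   record.
#' @export
dataset_species <- function(dataset) {
  sp <- unlist(lapply(dataset$records, function(r) {
    c(r$dimer$monomer_a$species, r$dimer$monomer_b$species)
  }))
  intersect(species_vocabulary(), unique(sp))
}

# Build the flattened design for a set of records against a fixed species
# list.  Returns parameter-independent pair data concatenated over
# records plus per-record constants and the reference matrix.
build_design <- function(dataset, species, constants = model_constants()) {
  stopifnot(inherits(dataset, "sapt_dataset"))
  nrec <- length(dataset$records)
  pair_rec <- pair_si <- pair_sj <- integer(0)
  pair_r <- pair_nuc <- pair_zi_mj <- pair_mi_zj <- pair_mi_mj <-
    pair_w <- pair_e810 <- numeric(0)
  const_elst <- const_disp <- const_pol <- numeric(nrec)
  ref <- matrix(NA_real_, nrec, 5,
                dimnames = list(NULL, c("elst", "exch", "indu", "disp", "total")))
  ids <- character(nrec)

  for (m in seq_len(nrec)) {
    rec <- dataset$records[[m]]
    ids[m] <- rec$id
    ed <- elst_design(rec$dimer, rec$props)
    dd <- disp_design(rec$dimer, rec$props)
    g <- pair_geometry(rec$dimer)
    w <- overlap_s(rec$props$a$sigma[g$i], rec$props$b$sigma[g$j], g$r)

    si <- match(ed$si, species)
    sj <- match(ed$sj, species)
    if (anyNA(si) || anyNA(sj)) {
      miss <- unique(c(ed$si[is.na(si)], ed$sj[is.na(sj)]))
      stop("species not covered by parameter set: ",
           paste(miss, collapse = ", "))
    }
    np <- length(ed$r)
    pair_rec <- c(pair_rec, rep.int(m, np))
    pair_si <- c(pair_si, si)
    pair_sj <- c(pair_sj, sj)
    pair_r <- c(pair_r, ed$r)
    pair_zi_mj <- c(pair_zi_mj, ed$zi_mj)
    pair_mi_zj <- c(pair_mi_zj, ed$mi_zj)
    pair_mi_mj <- c(pair_mi_mj, ed$mi_mj)
    pair_w <- c(pair_w, w)
    pair_e810 <- c(pair_e810, dd$e810)
    const_elst[m] <- sum(ed$nuc)
    const_disp[m] <- sum(dd$e6)
    const_pol[m] <- polarization_energy(rec$dimer, rec$props, constants)
    if (!is.null(rec$ref)) {
      ref[m, ] <- c(rec$ref$elst, rec$ref$exch, rec$ref$indu, rec$ref$disp,
                    rec$ref$total)
    }
  }
  list(species = species, n_records = nrec, ids = ids,
       rec = pair_rec, si = pair_si, sj = pair_sj, r = pair_r,
       zi_mj = pair_zi_mj, mi_zj = pair_mi_zj, mi_mj = pair_mi_mj,
       w = pair_w, e810 = pair_e810,
       const_elst = const_elst, const_disp = const_disp,
       const_pol = const_pol, ref = ref)
}

# Evaluate all component energies (kcal/mol) for every record of a design
# at the given per-species parameter vectors (aligned with
# design$species).  Returns an n_records x 5 matrix.
eval_design <- function(des, kelst, kexch, kindu, kdisp) {
  h2k <- sapt_units[["kcal_per_hartree"]]
  ke_i <- kelst[des$si]; ke_j <- kelst[des$sj]
  rsum <- function(x) {
    out <- numeric(des$n_records)
    s <- rowsum(x, des$rec)
    out[as.integer(rownames(s))] <- s
    out
  }
  elst <- (des$const_elst +
             rsum(damping_f1(ke_j, des$r) * des$zi_mj +
                    damping_f1(ke_i, des$r) * des$mi_zj +
                    damping_f2(ke_i, ke_j, des$r) * des$mi_mj)) * h2k
  exch <- rsum(sqrt(kexch[des$si] * kexch[des$sj]) * des$w) * h2k
  indu <- (des$const_pol + rsum(sqrt(kindu[des$si] * kindu[des$sj]) * des$w)) * h2k
  disp <- (des$const_disp + rsum(sqrt(kdisp[des$si] * kdisp[des$sj]) * des$e810)) * h2k
  cbind(elst = elst, exch = exch, indu = indu, disp = disp,
        total = elst + exch + indu + disp)
}
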