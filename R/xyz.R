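#' Construct a monomer
#'
#' A monomer is an ordered set of atoms with Cartesian coordinates in
#' Angstrom, an optional bond list (perceived, not input) and optional
#' atom-species labels.
#'
#' @param element Character vector of element symbols (C,H,N,O,S,F,Cl,Br).
#' @param xyz Numeric n x 3 matrix of coordinates, Angstrom.
#' @param class_label Optional functional-group class tag.
#' @param name Optional monomer name.
#' @return Object of class `monomer`.
#' @export
monomer <- function(element, xyz, class_label = NA_character_,
                    name = NA_character_) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(element) != nrow(xyz)) {
    stop("element / coordinate count mismatch")
  }
  bad <- setdiff(unique(element), SUPPORTED_ELEMENTS)
  if (length(bad) > 0) {
    stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
  }
  if (!all(is.finite(xyz))) stop("non-finite coordinate")
  structure(
    list(element = as.character(element), xyz = xyz,
         bonds = NULL, species = NULL,
         class_label = class_label, name = name),
    class = "monomer"
  )
}

#' @export
print.monomer <- function(x, ...) {
  cat(sprintf("monomer: %d atoms (%s)%s\n",
              length(x$element),
              paste(x$element, collapse = " "),
              if (!is.na(x$class_label)) paste0(" class=", x$class_label) else ""))
  if (!is.null(x$species)) cat("species:", paste(x$species, collapse = " "), "\n")
  if (!is.null(x$bonds)) cat(sprintf("bonds: %d\n", nrow(x$bonds)))
  invisible(x)
}

#' Parse XYZ-format text into a monomer
#'
#' Standard XYZ: first line atom count, second line comment, then one
#' "Element x y z" line per atom, coordinates in Angstrom.  A
#' `class=<label>` token in the comment line is picked up as the monomer's
#' functional-group class.
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @return A `monomer` (bonds and species unassigned).
#' @export
parse_xyz <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 1L) stop("empty XYZ input")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L) stop("XYZ line 1: invalid atom count")
  if (length(lines) < n + 2L) {
    stop(sprintf("XYZ: count says %d atoms but only %d atom lines present",
                 n, max(0L, length(lines) - 2L)))
  }
  comment <- if (length(lines) >= 2L) lines[2] else ""
  cls <- NA_character_
  m <- regmatches(comment, regexpr("class=\\S+", comment))
  if (length(m) == 1L && nzchar(m)) cls <- sub("^class=", "", m)

  el <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- trimws(lines[i + 2L])
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 4L) stop(sprintf("XYZ line %d: expected 'El x y z'", i + 2L))
    co <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(co)) stop(sprintf("XYZ line %d: non-numeric coordinate", i + 2L))
    el[i] <- tok[1]
    xyz[i, ] <- co
  }
  monomer(el, xyz, class_label = cls)
}

#' Read a monomer from an XYZ file
#' @param file Path to an XYZ file.
#' @return A `monomer`.
#' @export
read_xyz <- function(file) {
  parse_xyz(readLines(file, warn = FALSE))
}

#' Write a monomer (or dimer) to an XYZ file
#'
#' Dimers are written as a single XYZ file whose comment line carries
#' `natoms_A=<k>` marking the monomer split.
#'
#' @param x A `monomer` or `dimer`.
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_xyz <- function(x, file) {
  if (inherits(x, "dimer")) {
    el <- c(x$monomer_a$element, x$monomer_b$element)
    xyz <- rbind(x$monomer_a$xyz, x$monomer_b$xyz)
    comment <- sprintf("natoms_A=%d id=%s", length(x$monomer_a$element), x$id)
  } else {
    el <- x$element
    xyz <- x$xyz
    comment <- if (!is.na(x$class_label)) paste0("class=", x$class_label) else ""
  }
  lines <- c(
    as.character(length(el)), comment,
    sprintf("%-2s %18.10f %18.10f %18.10f", el, xyz[, 1], xyz[, 2], xyz[, 3])
  )
  writeLines(lines, file)
  invisible(file)
}

#' Read a dimer from disk
#'
#' Either two XYZ files (one per monomer) or one XYZ file whose comment
#' line contains `natoms_A=<k>` splitting the atom list.
#'
#' @param file Path to the (first) XYZ file.
#' @param file_b Optional path to the second monomer's XYZ file.
#' @param id Dimer identifier; defaults to the file name.
#' @param type Logical: perceive bonds and assign species on read.
#' @return A `dimer`.
#' @export
read_dimer_xyz <- function(file, file_b = NULL, id = NULL, type = TRUE) {
  if (is.null(id)) id <- sub("\\.xyz$", "", basename(file))
  if (!is.null(file_b)) {
    a <- read_xyz(file)
    b <- read_xyz(file_b)
  } else {
    lines <- readLines(file, warn = FALSE)
    comment <- if (length(lines) >= 2L) lines[2] else ""
    m <- regmatches(comment, regexpr("natoms_A=\\d+", comment))
    if (length(m) != 1L || !nzchar(m)) {
      stop("single-file dimer needs 'natoms_A=<k>' in the XYZ comment line")
    }
    k <- as.integer(sub("natoms_A=", "", m))
    full <- parse_xyz(lines)
    n <- length(full$element)
    if (k < 1L || k >= n) stop("natoms_A out of range")
    a <- monomer(full$element[1:k], full$xyz[1:k, , drop = FALSE])
    b <- monomer(full$element[(k + 1):n], full$xyz[(k + 1):n, , drop = FALSE])
  }
  if (type) {
    a <- assign_atom_types(perceive_bonds(a))
    b <- assign_atom_types(perceive_bonds(b))
  }
  build_dimer(a, b, id = id)
}
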