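# Element property tables. Van der Waals radii follow Bondi's compilation
# (values in Angstrom); masses are standard atomic weights (u). Elements not
# listed fall back to carbon-like defaults.
VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
               FE = 2.00, ZN = 1.39, MG = 1.73, CA = 2.31, `NA` = 2.27,
               K = 2.75, MN = 2.00)
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
                   P = 30.974, F = 18.998, CL = 35.45, BR = 79.904,
                   I = 126.904, SE = 78.971, FE = 55.845, ZN = 65.38,
                   MG = 24.305, CA = 40.078, `NA` = 22.990, K = 39.098,
                   MN = 54.938)
# Polarity partition for solvent-accessible surface splitting: carbon and
# sulfur count as hydrophobic, nitrogen/oxygen/phosphorus (and polar H,
# when present) as hydrophilic.
HYDROPHOBIC_ELEMENTS <- c("C", "S")

element_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- 1.70
  unname(r)
}
element_mass <- function(element) {
  m <- ATOMIC_MASSES[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Atomic structure model
#'
#' A light container for an atomic structure: a data frame of atoms with
#' element, residue bookkeeping, Cartesian coordinates (Angstrom), van der
#' Waals radius (Angstrom), atomic mass (u) and a polarity class used to
#' split solvent-accessible surface into hydrophobic (C, S) and hydrophilic
#' (N, O, P, polar H) contributions.
#'
#' @param atoms Data frame with at least `element`, `x`, `y`, `z`; optional
#'   `name`, `resid`, `resname`, `radius`, `mass`, `polarity`.
#' @param radius,mass Optional overrides (scalar or per atom); derived from
#'   the element tables when absent.
#' @return An object of class `structure_model` (a data frame).
#' @export
structure_model <- function(atoms, radius = NULL, mass = NULL) {
  if (nrow(atoms) < 1) abort("structure needs >= 1 atom", "protomer_domain_error")
  need <- c("element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    abort("atoms must have element, x, y, z columns", "protomer_domain_error")
  if (anyNA(atoms[need]) || any(!is.finite(as.matrix(atoms[c("x", "y", "z")]))))
    abort("coordinates must be finite", "protomer_domain_error")
  if (is.null(atoms$name)) atoms$name <- atoms$element
  if (is.null(atoms$resid)) atoms$resid <- seq_len(nrow(atoms))
  if (is.null(atoms$resname)) atoms$resname <- "UNK"
  atoms$radius <- if (!is.null(radius)) rep_len(radius, nrow(atoms))
                  else if (!is.null(atoms$radius)) atoms$radius
                  else element_radius(atoms$element)
  atoms$mass <- if (!is.null(mass)) rep_len(mass, nrow(atoms))
                else if (!is.null(atoms$mass)) atoms$mass
                else element_mass(atoms$element)
  if (any(atoms$radius <= 0)) abort("radii must be > 0", "protomer_domain_error")
  if (is.null(atoms$polarity))
    atoms$polarity <- ifelse(toupper(atoms$element) %in% HYDROPHOBIC_ELEMENTS,
                             "hydrophobic", "hydrophilic")
  structure(atoms, class = c("structure_model", "data.frame"))
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues, mass %.1f u\n",
              nrow(x), length(unique(x$resid)), sum(x$mass)))
  invisible(x)
}

coords <- function(structure) as.matrix(structure[, c("x", "y", "z")])

#' Read a structure from a PDB file
#'
#' Minimal reader for standard PDB `ATOM`/`HETATM` records (fixed-width
#' columns). Only the first model of a multi-model file is read (see
#' [read_pdb_trajectory()] for all models). Hydrogens and heteroatoms
#' (ions, ligands, water) are excluded by default, giving united-atom
#' surface areas.
#'
#' @param path PDB file path.
#' @param keep_hetatm Keep `HETATM` records? Default `FALSE`.
#' @param keep_hydrogens Keep hydrogen atoms? Default `FALSE`.
#' @return A [structure_model()].
#' @export
read_pdb <- function(path, keep_hetatm = FALSE, keep_hydrogens = FALSE) {
  lines <- readLines(path)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  atoms <- parse_pdb_atoms(lines, keep_hetatm, keep_hydrogens)
  if (nrow(atoms) == 0) abort("no atoms found in PDB file", "protomer_domain_error")
  structure_model(atoms)
}

parse_pdb_atoms <- function(lines, keep_hetatm = FALSE, keep_hydrogens = FALSE) {
  rec <- substr(lines, 1, 6)
  keep <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(element = character(), name = character(),
                      resid = integer(), resname = character(),
                      x = numeric(), y = numeric(), z = numeric()))
  name <- trimws(substr(lines, 13, 16))
  elem <- trimws(substr(lines, 77, 78))
  # fall back to first alphabetic character of the atom name
  miss <- elem == ""
  elem[miss] <- sub("^[0-9]*", "", name[miss])
  elem[miss] <- substr(elem[miss], 1, 1)
  d <- data.frame(
    element = toupper(elem),
    name = name,
    resid = as.integer(substr(lines, 23, 26)),
    resname = trimws(substr(lines, 18, 20)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)))
  if (!keep_hydrogens) d <- d[d$element != "H" & d$element != "D", , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write a structure (or trajectory) to a PDB file
#'
#' @param x A [structure_model()] or [trajectory()] (written as a
#'   multi-model PDB).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "trajectory")) {
    for (f in seq_len(dim(x$frames)[3])) {
      writeLines(sprintf("MODEL     %4d", f), con)
      write_pdb_atoms(x$atoms, x$frames[, , f], con)
      writeLines("ENDMDL", con)
    }
  } else {
    write_pdb_atoms(x, coords(x), con)
  }
  writeLines("END", con)
  invisible(path)
}

write_pdb_atoms <- function(atoms, xyz, con) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(atoms)), substr(atoms$name, 1, 4),
    substr(atoms$resname, 1, 3), atoms$resid %% 10000,
    xyz[, 1], xyz[, 2], xyz[, 3], toupper(substr(atoms$element, 1, 2)))
  writeLines(lines, con)
}
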