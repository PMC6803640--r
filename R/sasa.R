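#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes the per-atom solvent-accessible surface area by the
#' Shrake-Rupley method: a quasi-uniform set of test points (a deterministic
#' golden-spiral lattice) is placed on each atom's solvent-expanded sphere
#' (van der Waals radius + probe radius) and the accessible fraction is the
#' share of points falling outside every neighbouring expanded sphere.
#' Totals are split by the polarity class of the atoms (hydrophobic: C, S;
#' hydrophilic: N, O, P) and reported in nm^2; per-atom areas stay in
#' Angstrom^2 as is conventional.
#'
#' An isolated atom gets exactly its analytic area
#' `4 * pi * (r + probe)^2`; coincident duplicate atoms are handled
#' gracefully (the duplicate contributes zero marginal area).
#'
#' @param structure A [structure_model()].
#' @param probe_radius Probe (solvent) radius in Angstrom; 1.4 by default
#'   (water).
#' @param n_sphere_points Number of test points per atom (>= 100);
#'   960 by default.
#' @return An object of class `sasa_result`: list with `per_atom`
#'   (Angstrom^2), and `hydrophobic`, `hydrophilic`, `total` (nm^2).
#' @examples
#' s <- toy_structures("dumbbell", d = 100, atom_radius = 1.9)
#' sasa(s)$total * 100  # Angstrom^2: twice the isolated-sphere area
#' @export
sasa <- function(structure, probe_radius = 1.4, n_sphere_points = 960) {
  if (!inherits(structure, "structure_model"))
    abort("need a structure_model", "protomer_domain_error")
  if (probe_radius <= 0) abort("probe radius must be > 0", "protomer_domain_error")
  if (n_sphere_points < 100) abort("need >= 100 sphere points", "protomer_domain_error")

  xyz <- coords(structure)
  n <- nrow(xyz)
  rext <- structure$radius + probe_radius
  pts <- golden_spiral_points(n_sphere_points)

  per_atom <- numeric(n)
  maxr <- max(rext)
  for (i in seq_len(n)) {
    # neighbours whose expanded sphere can intersect atom i's expanded sphere
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
          (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rext[i] + rext)^2 & seq_len(n) != i)
    # coincident duplicates: a strictly larger sphere (or, for ties, the
    # later atom) takes the area, the other contributes zero marginal area
    coinc <- nb[d2[nb] == 0]
    if (any(rext[coinc] > rext[i] | (rext[coinc] == rext[i] & coinc > i))) {
      per_atom[i] <- 0
      next
    }
    nb <- setdiff(nb, coinc)   # remaining coincident spheres cannot occlude
    test <- pts * rext[i]
    test <- sweep(test, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (test[acc, 1] - xyz[j, 1])^2 + (test[acc, 2] - xyz[j, 2])^2 +
             (test[acc, 3] - xyz[j, 3])^2
      acc[acc] <- dj2 >= rext[j]^2
    }
    per_atom[i] <- 4 * pi * rext[i]^2 * sum(acc) / n_sphere_points
  }

  hydro <- sum(per_atom[structure$polarity == "hydrophobic"]) / 100
  phil <- sum(per_atom[structure$polarity == "hydrophilic"]) / 100
  structure(list(per_atom = per_atom, hydrophobic = hydro,
                 hydrophilic = phil, total = hydro + phil,
                 probe_radius = probe_radius,
                 n_sphere_points = n_sphere_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf(paste0("Solvent-accessible surface (probe %.2f A, %d pts): ",
                     "total %.2f nm^2 (hydrophobic %.2f, hydrophilic %.2f)\n"),
              x$probe_radius, x$n_sphere_points, x$total, x$hydrophobic,
              x$hydrophilic))
  invisible(x)
}

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(theta), r * sin(theta), z)
}
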