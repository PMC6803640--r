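#' Coordinate trajectory
#'
#' An ordered set of coordinate frames (Angstrom) over a fixed atom list.
#'
#' @param frames Numeric array `n_atoms x 3 x n_frames` (or a list of
#'   `n_atoms x 3` matrices).
#' @param atoms Data frame of atom metadata with at least `resid`; optional
#'   `name`, `element`, `calpha` (logical flag marking C-alpha atoms —
#'   derived from `name == "CA"` when absent).
#' @param reference Optional reference coordinate set (`n_atoms x 3`), e.g.
#'   the equilibrated structure; defaults to the first frame in analyses.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, atoms, reference = NULL) {
  if (is.list(frames) && !is.array(frames))
    frames <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  if (length(dim(frames)) != 3 || dim(frames)[2] != 3)
    abort("frames must be an n_atoms x 3 x n_frames array", "protomer_domain_error")
  if (dim(frames)[3] < 2) abort("need >= 2 frames", "protomer_domain_error")
  if (nrow(atoms) != dim(frames)[1])
    abort("atom metadata does not match frame atom count", "protomer_domain_error")
  if (is.null(atoms$calpha))
    atoms$calpha <- if (!is.null(atoms$name)) atoms$name == "CA"
                    else rep(TRUE, nrow(atoms))
  if (!is.null(reference) && !all(dim(reference) == dim(frames)[1:2]))
    abort("reference does not match frame dimensions", "protomer_domain_error")
  structure(list(frames = frames, atoms = atoms, reference = reference),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms (%d C-alpha)\n",
              dim(x$frames)[3], dim(x$frames)[1], sum(x$atoms$calpha)))
  invisible(x)
}

#' Read a multi-model PDB file as a trajectory
#'
#' @inheritParams read_pdb
#' @return A [trajectory()] whose atom metadata comes from the first model.
#' @export
read_pdb_trajectory <- function(path, keep_hetatm = FALSE,
                                keep_hydrogens = FALSE) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) < 2 || length(starts) != length(ends))
    abort("not a multi-model PDB file", "protomer_domain_error")
  models <- lapply(seq_along(starts), function(i)
    parse_pdb_atoms(lines[starts[i]:ends[i]], keep_hetatm, keep_hydrogens))
  n <- nrow(models[[1]])
  if (any(vapply(models, nrow, 1L) != n))
    abort("models have inconsistent atom counts", "protomer_domain_error")
  frames <- array(0, dim = c(n, 3, length(models)))
  for (i in seq_along(models))
    frames[, , i] <- as.matrix(models[[i]][, c("x", "y", "z")])
  trajectory(frames, models[[1]][, c("element", "name", "resid", "resname")])
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares rigid superposition of a mobile coordinate set onto a
#' reference via singular value decomposition of the cross-covariance
#' matrix, with the usual determinant correction to exclude reflections.
#'
#' @param mobile,reference `n x 3` coordinate matrices (Angstrom), `n >= 3`
#'   non-collinear points.
#' @param selection Optional index vector: the atoms used to determine the
#'   transform (all atoms are transformed).
#' @return List with `rotation` (3x3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `rmsd` (Angstrom,
#'   post-fit over the selection) and `transformed` (the transformed mobile
#'   set).
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3)
    abort("mobile and reference must be matching n x 3 matrices",
          "protomer_domain_error")
  sel <- if (is.null(selection)) seq_len(nrow(mobile)) else selection
  if (length(sel) < 3)
    abort("need >= 3 selected atoms for superposition", "protomer_domain_error")
  ms <- mobile[sel, , drop = FALSE]; rs <- reference[sel, , drop = FALSE]
  mc <- colMeans(ms); rc <- colMeans(rs)
  A <- sweep(ms, 2, mc)
  B <- sweep(rs, 2, rc)
  sv <- svd(crossprod(A, B))     # t(A) %*% B
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    abort("degenerate (collinear) geometry: rotation is not determined",
          "protomer_domain_error")
  sgn <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, sgn))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- rc - as.numeric(R %*% mc)
  transformed <- mobile %*% t(R) + matrix(translation, nrow(mobile), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((transformed[sel, , drop = FALSE] - rs)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd,
       transformed = transformed)
}

#' Per-residue C-alpha root-mean-square fluctuation
#'
#' For each C-alpha atom, the RMSF over the trajectory relative to a
#' reference structure,
#' \deqn{RMSF_i = \sqrt{\langle |r_i(t) - r_{i,ref}|^2 \rangle_t},}
#' after (by default) least-squares superposition of every frame onto the
#' reference on the C-alpha selection. With `reference = "mean"` the
#' deviations are measured about the time-averaged structure instead, which
#' by variance decomposition can only lower the profile.
#'
#' @param traj A [trajectory()].
#' @param reference `"first"` (default: first frame, or the trajectory's
#'   stored reference if present), `"mean"`, or an explicit `n x 3`
#'   coordinate matrix / [structure_model()] (the equilibrated structure).
#' @param fit Superpose each frame onto the reference before measuring
#'   fluctuations (default `TRUE`).
#' @return An object of class `rmsf_profile`: data frame with `resid` and
#'   `rmsf` (nm).
#' @export
rmsf_per_residue <- function(traj, reference = "first", fit = TRUE) {
  if (!inherits(traj, "trajectory"))
    abort("need a trajectory", "protomer_domain_error")
  frames <- traj$frames
  nf <- dim(frames)[3]
  ca <- which(traj$atoms$calpha)
  if (!length(ca)) abort("trajectory has no C-alpha atoms", "protomer_domain_error")

  ref <- if (is.character(reference) && reference[1] %in% c("first", "mean")) {
    if (!is.null(traj$reference)) traj$reference else frames[, , 1]
  } else if (inherits(reference, "structure_model")) coords(reference)
  else as.matrix(reference)
  if (!all(dim(ref) == dim(frames)[1:2]))
    abort("reference is not atom-compatible with the trajectory",
          "protomer_domain_error")

  fitted <- array(0, dim = dim(frames))
  for (f in seq_len(nf)) {
    fr <- frames[, , f]
    if (fit) fr <- kabsch_superpose(fr, ref, selection = ca)$transformed
    fitted[, , f] <- fr
  }
  target <- if (is.character(reference) && reference[1] == "mean")
    apply(fitted, c(1, 2), mean) else ref

  d2 <- matrix(0, length(ca), nf)
  for (f in seq_len(nf))
    d2[, f] <- rowSums((fitted[ca, , f] - target[ca, , drop = FALSE])^2)
  rmsf_A <- sqrt(rowMeans(d2))
  structure(data.frame(resid = traj$atoms$resid[ca], rmsf = rmsf_A / 10),
            class = c("rmsf_profile", "data.frame"))
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile: %d residues, mean %.3f nm, max %.3f nm (residue %d)\n",
              nrow(x), mean(x$rmsf), max(x$rmsf), x$resid[which.max(x$rmsf)]))
  invisible(x)
}

#' @export
plot.rmsf_profile <- function(x, ...) {
  plot(x$resid, x$rmsf, type = "l", xlab = "Residue",
       ylab = "RMSF (nm)", ...)
  invisible(x)
}
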