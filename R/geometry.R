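## geometry: optimal rigid-body superposition and stability observables.

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the mass-unweighted
#' squared deviation between `mobile` and `reference` over a selection, via
#' singular value decomposition of the covariance of the centred coordinate
#' sets. The reflection case is handled by flipping the sign of the smallest
#' singular direction, guaranteeing a proper rotation (det = +1).
#'
#' @param mobile `n_atoms x 3` coordinate matrix to transform (angstrom).
#' @param reference `n_atoms x 3` coordinate matrix to fit onto.
#' @param selection Optional [select_atoms()] result or index vector; the fit
#'   and the reported RMSD use only these atoms. Default: all atoms.
#' @return List of class `superposition` with `rotation` (3x3, det +1),
#'   `translation` (length-3, angstrom) and `rmsd` (angstrom, over the
#'   selection). The transform maps mobile coordinates as
#'   `x %*% rotation + translation` (row vectors).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(30), ncol = 3)
#' kabsch_superpose(x, x)$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference, selection = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    stop("kabsch_superpose: coordinate sets differ in size")
  idx <- resolve_selection(selection, nrow(mobile))
  if (length(idx) < 3)
    stop("kabsch_superpose: need at least 3 selected atoms")
  A <- mobile[idx, , drop = FALSE]
  B <- reference[idx, , drop = FALSE]
  ## collinearity check: rank of centred reference must exceed 1
  Bc <- sweep(B, 2, colMeans(B))
  if (sum(svd(Bc)$d > 1e-8 * max(1, max(abs(Bc)))) < 2)
    stop("kabsch_superpose: selected atoms are collinear (degenerate geometry)")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  H <- crossprod(Ac, Bc)            # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)       # rotation applied as x %*% R
  t_vec <- cb - as.numeric(ca %*% R)
  fitted <- sweep(Ac %*% R, 2, cb, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  structure(list(rotation = R, translation = t_vec, rmsd = rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#'
#' @param coords `n x 3` coordinate matrix.
#' @param sp A `superposition` from [kabsch_superpose()].
#' @return Transformed `n x 3` matrix.
#' @export
apply_superposition <- function(coords, sp) {
  stopifnot(inherits(sp, "superposition"))
  sweep(as.matrix(coords) %*% sp$rotation, 2, sp$translation, `+`)
}

#' Per-frame RMSD series against a reference frame
#'
#' Each frame is independently superposed (Kabsch, over the selection) onto
#' the reference frame before the deviation is computed, so the value at the
#' reference frame is exactly zero and rigid motions contribute nothing.
#'
#' @param traj A [trajectory].
#' @param reference_frame Index of the reference frame (default 1).
#' @param selection Optional selection; both the fit and the RMSD use it.
#' @return Numeric vector of per-frame RMSD (angstrom) of class
#'   `rmsd_series`, with attributes `mean` and `sd`.
#' @export
rmsd_series <- function(traj, reference_frame = 1, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (reference_frame < 1 || reference_frame > nf)
    stop("rmsd_series: reference frame out of range")
  idx <- resolve_selection(selection, n_atoms(traj))
  if (length(idx) == 0) stop("rmsd_series: empty selection")
  ref <- frame_coords(traj, reference_frame)
  out <- vapply(seq_len(nf), function(i) {
    kabsch_superpose(frame_coords(traj, i), ref, idx)$rmsd
  }, numeric(1))
  structure(out, mean = mean(out), sd = stats::sd(out),
            class = "rmsd_series")
}

#' @export
print.rmsd_series <- function(x, ...) {
  cat(sprintf("<rmsd_series> %d frames, mean %.3f +/- %.3f A\n",
              length(x), attr(x, "mean"), attr(x, "sd")))
  invisible(x)
}

## Superpose every frame of traj onto `ref` over `idx`; returns the
## transformed coordinate array.
superpose_all <- function(traj, ref, idx) {
  coords <- traj$coords
  out <- coords
  for (i in seq_len(dim(coords)[1])) {
    fr <- matrix(coords[i, , ], ncol = 3)
    sp <- kabsch_superpose(fr, ref, idx)
    out[i, , ] <- apply_superposition(fr, sp)
  }
  out
}

#' Per-residue root-mean-square fluctuation profile
#'
#' All frames are superposed onto the mean structure using a two-pass
#' scheme: align every frame to the first, compute the mean structure, then
#' re-align to that mean. Per-atom RMSF is the square root of the time-mean
#' squared displacement from the mean position; the residue value is the
#' mean over its selected atoms.
#'
#' @param traj A [trajectory] with at least 2 frames.
#' @param topology Matching [topology] (residue labels).
#' @param selection Optional selection restricting the atoms profiled.
#' @param fit_selection Optional selection used for the superposition fit;
#'   defaults to `selection`. Fitting on a stable subset (e.g. the scaffold
#'   backbone) while profiling everything prevents a mobile region from
#'   dragging the alignment.
#' @return data.frame of class `rmsf_profile` with columns `chain`, `resid`,
#'   `resname`, `rmsf` (angstrom).
#' @export
rmsf_profile <- function(traj, topology, selection = NULL,
                         fit_selection = selection) {
  stopifnot(inherits(traj, "trajectory"), inherits(topology, "topology"))
  if (n_frames(traj) < 2)
    stop("rmsf_profile: fluctuation undefined for a single frame")
  idx <- resolve_selection(selection, n_atoms(traj))
  fit_idx <- resolve_selection(fit_selection, n_atoms(traj))
  if (length(idx) < 1) stop("rmsf_profile: empty selection")
  if (length(fit_idx) < 3)
    stop("rmsf_profile: need at least 3 atoms in the fit selection")
  ref1 <- frame_coords(traj, 1)
  pass1 <- superpose_all(traj, ref1, fit_idx)
  mean1 <- apply(pass1, c(2, 3), mean)
  pass2 <- superpose_all(trajectory(pass1), mean1, fit_idx)
  mean2 <- apply(pass2, c(2, 3), mean)
  ## per-atom mean squared displacement about the mean position
  disp2 <- rowMeans(apply(pass2, 1, function(fr) {
    rowSums((matrix(fr, ncol = 3) - mean2)^2)
  }))
  atom_rmsf <- sqrt(disp2)
  at <- topology$atoms[idx, , drop = FALSE]
  key <- paste(at$chain, at$resid, sep = ":")
  agg <- tapply(atom_rmsf[idx], key, mean)
  ## preserve topology order of residues
  ord <- unique(key)
  out <- data.frame(
    chain = sub(":.*$", "", ord),
    resid = as.integer(sub("^.*:", "", ord)),
    resname = at$resname[match(ord, key)],
    rmsf = as.numeric(agg[ord]),
    stringsAsFactors = FALSE)
  class(out) <- c("rmsf_profile", class(out))
  out
}

#' Atom-pair distance series
#'
#' Euclidean distance between two atoms in every frame, e.g. for monitoring
#' disulfide-bridge S-S separations.
#'
#' @param traj A [trajectory].
#' @param atom_i,atom_j Distinct atom indices (1-based).
#' @return Numeric vector (angstrom) with attributes `mean` and `sd`.
#' @export
pair_distance_series <- function(traj, atom_i, atom_j) {
  stopifnot(inherits(traj, "trajectory"))
  na <- n_atoms(traj)
  if (atom_i < 1 || atom_i > na || atom_j < 1 || atom_j > na)
    stop("pair_distance_series: atom index out of range")
  if (atom_i == atom_j)
    stop("pair_distance_series: atom indices must be distinct")
  d <- sqrt(rowSums((traj$coords[, atom_i, , drop = FALSE] -
                     traj$coords[, atom_j, , drop = FALSE])^2))
  d <- as.numeric(d)
  structure(d, mean = mean(d), sd = stats::sd(d))
}
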