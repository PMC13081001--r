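## sie_scoring: solvated interaction energy (SIE) end-point binding
## free-energy model.
##
## dG = alpha * (E_vdw + E_coul + E_rf + E_cav) + C
##
## E_vdw, E_coul: intermolecular Lennard-Jones and Coulomb energies;
## E_rf: generalized-Born reaction-field (electrostatic desolvation) change
## on binding; E_cav: gamma-scaled change in solvent-accessible surface
## area (nonpolar desolvation). All energies in kcal/mol.

#' SIE model coefficients
#'
#' Defaults: `alpha = 0.1048` (global scaling; recovered by least squares
#' from published component/affinity tables), `C = -2.89` kcal/mol,
#' `gamma = 0.0129` kcal/mol/A^2 (used only when computing the cavity term
#' from surface areas), interior dielectric `eps_in = 2.25`, solvent
#' dielectric `eps_out = 78.5`.
#'
#' @param alpha Unitless global scaling, > 0.
#' @param C Constant offset, kcal/mol.
#' @param gamma Cavity coefficient, kcal/mol/A^2.
#' @param eps_in,eps_out Interior and solvent dielectric constants;
#'   `eps_out > eps_in >= 1`.
#' @return Named list of class `sie_coefficients`.
#' @export
sie_coefficients <- function(alpha = 0.1048, C = -2.89, gamma = 0.0129,
                             eps_in = 2.25, eps_out = 78.5) {
  if (alpha <= 0) stop("sie_coefficients: alpha must be positive")
  if (!(eps_out > eps_in && eps_in >= 1))
    stop("sie_coefficients: need eps_out > eps_in >= 1")
  structure(list(alpha = alpha, C = C, gamma = gamma,
                 eps_in = eps_in, eps_out = eps_out),
            class = "sie_coefficients")
}

#' SIE binding free energy from components
#'
#' `dG = alpha * (E_vdw + E_coul + E_rf + E_cav) + C`. Accepts a single
#' component set (named list or vector) or an energy table (one dG per row).
#'
#' @param components Named list/vector with `E_vdw`, `E_coul`, `E_rf`,
#'   `E_cav` (kcal/mol), or a data.frame with those columns.
#' @param coeffs [sie_coefficients()].
#' @return Numeric dG (kcal/mol), one value per component row.
#' @examples
#' sie_score(c(E_vdw = 0, E_coul = 0, E_rf = 0, E_cav = 0))  # the constant
#' @export
sie_score <- function(components, coeffs = sie_coefficients()) {
  comp_names <- c("E_vdw", "E_coul", "E_rf", "E_cav")
  if (is.data.frame(components)) {
    missing_cols <- setdiff(comp_names, names(components))
    if (length(missing_cols) > 0)
      stop("sie_score: missing component column(s): ",
           paste(missing_cols, collapse = ", "))
    s <- rowSums(as.matrix(components[, comp_names]))
  } else {
    components <- unlist(components)
    if (!all(comp_names %in% names(components)))
      stop("sie_score: components must be named E_vdw, E_coul, E_rf, E_cav")
    s <- sum(components[comp_names])
  }
  if (any(!is.finite(s))) stop("sie_score: non-finite components")
  coeffs$alpha * s + coeffs$C
}

#' Calibrate SIE coefficients from a component table with reference dG
#'
#' Least-squares fit of `(alpha, C)` in `dG ~ alpha * sum(components) + C`.
#' Because a single grossly inconsistent row can drag an ordinary
#' least-squares line towards itself (it has high leverage when its
#' component sum is extreme), rows are first screened with a robust
#' Theil-Sen line (median of pairwise slopes): rows whose residual under
#' that line exceeds `outlier_threshold` are flagged as inconsistent, the
#' coefficients are then refit by least squares on the unflagged rows, and
#' the reported residuals are taken under that refit. Flagged rows are
#' never silently corrected or dropped from the output.
#'
#' @param table data.frame with component columns `E_vdw`, `E_coul`, `E_rf`,
#'   `E_cav` and a reference column `dG` (kcal/mol).
#' @param outlier_threshold Absolute residual under the robust screen above
#'   which a row is flagged as inconsistent, kcal/mol (default 1.0).
#' @param fix_C Optional known constant offset (kcal/mol). When given, only
#'   `alpha` is estimated, by least squares of `dG - fix_C` on the component
#'   sums through the origin.
#' @return List of class `sie_calibration`: `coefficients`
#'   ([sie_coefficients()] with the fitted alpha and C), `residuals` (per
#'   row, under the final fit), `outliers` (logical per row), `fit` (the
#'   underlying [stats::lm()]).
#' @export
sie_calibrate <- function(table, outlier_threshold = 1.0, fix_C = NULL) {
  comp_names <- c("E_vdw", "E_coul", "E_rf", "E_cav")
  missing_cols <- setdiff(c(comp_names, "dG"), names(table))
  if (length(missing_cols) > 0)
    stop("sie_calibrate: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(table)
  if (n < 2) stop("sie_calibrate: need at least 2 rows")
  s <- rowSums(as.matrix(table[, comp_names]))
  dg <- table$dG
  if (max(s) - min(s) < 1e-10)
    stop("sie_calibrate: rank-deficient design (all component sums equal)")
  outliers <- rep(FALSE, n)
  if (n >= 3) {
    ## Theil-Sen screen: median pairwise slope and matching intercept
    pairs <- utils::combn(n, 2)
    ds <- s[pairs[2, ]] - s[pairs[1, ]]
    ok <- abs(ds) > 1e-10
    slope <- stats::median((dg[pairs[2, ]] - dg[pairs[1, ]])[ok] / ds[ok])
    icept <- stats::median(dg - slope * s)
    outliers <- abs(dg - (slope * s + icept)) > outlier_threshold
    if (sum(!outliers) < 2) outliers <- rep(FALSE, n)  # refuse to drop all
  }
  keep <- !outliers
  if (is.null(fix_C)) {
    fit <- stats::lm(dg[keep] ~ s[keep])
    alpha <- unname(stats::coef(fit)[2])
    C <- unname(stats::coef(fit)[1])
  } else {
    y <- dg[keep] - fix_C
    fit <- stats::lm(y ~ 0 + s[keep])
    alpha <- unname(stats::coef(fit)[1])
    C <- fix_C
  }
  resid <- dg - (alpha * s + C)
  out <- list(coefficients = sie_coefficients(alpha = alpha, C = C),
              residuals = resid,
              outliers = outliers,
              fit = fit)
  class(out) <- "sie_calibration"
  out
}

#' @export
print.sie_calibration <- function(x, ...) {
  cat(sprintf(
    "<sie_calibration> alpha = %.4f, C = %.2f kcal/mol; max |residual| %.3f; %d outlier(s)\n",
    x$coefficients$alpha, x$coefficients$C, max(abs(x$residuals)),
    sum(x$outliers)))
  invisible(x)
}

#' Intermolecular Lennard-Jones and Coulomb energies
#'
#' Sums over all protein-ligand atom pairs, with no cutoff: LJ 12-6 using
#' Lorentz-Berthelot combination (arithmetic rmin, geometric epsilon) and
#' Coulomb `ke * qi * qj / (eps_in * rij)` with
#' `ke = 332.0636 kcal A / (mol e^2)`.
#'
#' @param coords `n_atoms x 3` coordinates of the complex (angstrom).
#' @param topology [topology] carrying `charges` and `lj` for every atom.
#' @param ligand_selection Selection (or indices) of ligand atoms; the rest
#'   is the protein.
#' @param eps_in Interior dielectric (default 1).
#' @return Named numeric vector `c(E_vdw = ..., E_coul = ...)` in kcal/mol.
#' @export
lj_coulomb_interaction <- function(coords, topology, ligand_selection,
                                   eps_in = 1) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.null(topology$charges) || is.null(topology$lj))
    stop("lj_coulomb_interaction: topology lacks charges and/or LJ parameters")
  bad <- which(is.na(topology$charges) | is.na(topology$lj$epsilon) |
               is.na(topology$lj$rmin_half))
  if (length(bad) > 0)
    stop("lj_coulomb_interaction: missing parameters for atom(s) ",
         paste(utils::head(bad, 10), collapse = ", "))
  lig <- resolve_selection(ligand_selection, n)
  prot <- setdiff(seq_len(n), lig)
  if (length(prot) == 0) stop("lj_coulomb_interaction: empty protein selection")
  A <- coords[prot, , drop = FALSE]
  B <- coords[lig, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  r <- sqrt(pmax(d2, 0))
  if (any(r < 1e-6))
    stop("lj_coulomb_interaction: overlapping protein/ligand atoms")
  eps_pair <- sqrt(outer(topology$lj$epsilon[prot],
                         topology$lj$epsilon[lig]))
  rmin_pair <- outer(topology$lj$rmin_half[prot],
                     topology$lj$rmin_half[lig], `+`)
  sr6 <- (rmin_pair / r)^6
  e_vdw <- sum(eps_pair * (sr6^2 - 2 * sr6))
  q_pair <- outer(topology$charges[prot], topology$charges[lig])
  e_coul <- .ke * sum(q_pair / r) / eps_in
  c(E_vdw = e_vdw, E_coul = e_coul)
}

## Generalized-Born solvation energy of one set of atoms:
## G = -1/2 * ke * (1/eps_in - 1/eps_out) * sum_ij qi qj / f_ij,
## f_ij = sqrt(r^2 + ai*aj*exp(-r^2 / (4 ai aj))), including i = j.
gb_energy <- function(coords, charges, born, eps_in, eps_out) {
  n <- length(charges)
  pref <- -0.5 * .ke * (1 / eps_in - 1 / eps_out)
  if (n == 1) return(pref * charges^2 / born)
  d2 <- as.matrix(stats::dist(coords))^2
  aa <- outer(born, born)
  f <- sqrt(d2 + aa * exp(-d2 / (4 * aa)))
  qq <- outer(charges, charges)
  pref * sum(qq / f)
}

#' Generalized-Born reaction-field change on binding
#'
#' Pairwise generalized-Born energy with
#' `f_ij = sqrt(r_ij^2 + a_i a_j exp(-r_ij^2 / (4 a_i a_j)))` (self terms
#' included). The reaction-field component is the rigid decomposition
#' `E_rf = G(complex) - G(protein) - G(ligand)` with identical atom
#' positions in all three states, so self terms cancel and only cross
#' protein-ligand terms survive.
#'
#' @param coords `n_atoms x 3` complex coordinates (angstrom).
#' @param charges Per-atom partial charges (e).
#' @param born_radii Per-atom Born radii (angstrom), all positive.
#' @param eps_in,eps_out Interior and solvent dielectrics.
#' @param ligand_selection Selection (or indices) of ligand atoms.
#' @return `E_rf` in kcal/mol.
#' @export
gb_reaction_field <- function(coords, charges, born_radii, eps_in = 2.25,
                              eps_out = 78.5, ligand_selection) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(charges) != n || length(born_radii) != n)
    stop("gb_reaction_field: charges/born_radii must match atom count")
  if (any(born_radii <= 0))
    stop("gb_reaction_field: Born radii must be positive")
  lig <- resolve_selection(ligand_selection, n)
  prot <- setdiff(seq_len(n), lig)
  g_complex <- gb_energy(coords, charges, born_radii, eps_in, eps_out)
  g_prot <- gb_energy(coords[prot, , drop = FALSE], charges[prot],
                      born_radii[prot], eps_in, eps_out)
  g_lig <- gb_energy(coords[lig, , drop = FALSE], charges[lig],
                     born_radii[lig], eps_in, eps_out)
  unname(g_complex - g_prot - g_lig)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Places `n_sphere_points` points on each atom's probe-inflated sphere via
#' a deterministic golden-spiral construction and counts the fraction not
#' buried inside any neighbour's inflated sphere.
#'
#' @param coords `n_atoms x 3` coordinates (angstrom).
#' @param radii Per-atom intrinsic radii (angstrom).
#' @param probe_radius Probe radius, >= 0 (default 1.4).
#' @param n_sphere_points Points per atom (default 960).
#' @return Numeric vector of per-atom accessible areas (angstrom^2); sum it
#'   for the total SASA.
#' @export
sasa_shrake_rupley <- function(coords, radii, probe_radius = 1.4,
                               n_sphere_points = 960) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (length(radii) != n) stop("sasa_shrake_rupley: radii must match atoms")
  if (probe_radius < 0) stop("sasa_shrake_rupley: probe must be >= 0")
  ## golden-spiral unit sphere points (deterministic)
  k <- seq_len(n_sphere_points)
  z <- (2 * k - 1) / n_sphere_points - 1
  theta <- k * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  unit <- cbind(rho * cos(theta), rho * sin(theta), z)
  inflated <- radii + probe_radius
  areas <- numeric(n)
  for (i in seq_len(n)) {
    ri <- inflated[i]
    pts <- sweep(unit * ri, 2, coords[i, ], `+`)
    nb <- which(seq_len(n) != i &
                sqrt(rowSums(sweep(coords, 2, coords[i, ])^2)) <
                  ri + inflated)
    exposed <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      if (!any(exposed)) break
      d2 <- rowSums(sweep(pts[exposed, , drop = FALSE], 2,
                          coords[j, ])^2)
      exposed[exposed] <- d2 > inflated[j]^2
    }
    areas[i] <- 4 * pi * ri^2 * sum(exposed) / n_sphere_points
  }
  areas
}

#' Cavity (nonpolar desolvation) term from surface areas
#'
#' `E_cav = gamma * (SASA_complex - SASA_protein - SASA_ligand)`; negative
#' when surface is buried on binding.
#'
#' @param sasa_complex,sasa_protein,sasa_ligand Total accessible areas
#'   (angstrom^2), all >= 0.
#' @param gamma Surface coefficient, kcal/mol/A^2 (default 0.0129).
#' @return `E_cav` in kcal/mol.
#' @export
cavity_term <- function(sasa_complex, sasa_protein, sasa_ligand,
                        gamma = 0.0129) {
  if (any(c(sasa_complex, sasa_protein, sasa_ligand) < 0))
    stop("cavity_term: areas must be >= 0")
  gamma * (sasa_complex - sasa_protein - sasa_ligand)
}

#' SIE binding free energy from a trajectory
#'
#' Evaluates the four components for every frame inside a time window
#' (rigid decomposition: complex, protein and ligand share coordinates),
#' averages them per replicate, and reports component means and standard
#' deviations across replicate means. The final dG applies [sie_score()] to
#' the pooled mean components.
#'
#' @param traj A [trajectory].
#' @param topology Matching [topology] with `charges` and `lj`; Born radii
#'   are taken from `born_radii` if given, else from [atom_radii()].
#' @param ligand_selection Selection (or indices) of ligand atoms.
#' @param window Optional `c(start_ns, end_ns)`; requires frame times.
#'   Default: all frames.
#' @param replicate_bounds Integer vector of replicate start frames
#'   (default one replicate).
#' @param coeffs [sie_coefficients()].
#' @param born_radii Optional per-atom Born radii (angstrom).
#' @param probe_radius,n_sphere_points SASA settings (see
#'   [sasa_shrake_rupley()]).
#' @return Object of class `sie_result`: `dG`, `component_means`,
#'   `component_sds`, `n_replicates`, `n_frames`, `per_frame` (data.frame
#'   of per-frame components and dG).
#' @export
sie_from_trajectory <- function(traj, topology, ligand_selection,
                                window = NULL, replicate_bounds = 1L,
                                coeffs = sie_coefficients(),
                                born_radii = NULL, probe_radius = 1.4,
                                n_sphere_points = 240) {
  stopifnot(inherits(traj, "trajectory"), inherits(topology, "topology"))
  nf <- n_frames(traj)
  frames <- seq_len(nf)
  if (!is.null(window)) {
    if (is.null(traj$times))
      stop("sie_from_trajectory: window requires frame times")
    frames <- which(traj$times >= window[1] - 1e-9 &
                    traj$times <= window[2] + 1e-9)
    if (length(frames) == 0) stop("sie_from_trajectory: empty window")
  }
  lig <- resolve_selection(ligand_selection, n_atoms(traj))
  prot <- setdiff(seq_len(n_atoms(traj)), lig)
  radii <- atom_radii(topology)
  if (is.null(born_radii)) born_radii <- radii
  rep_id <- findInterval(frames, replicate_bounds)
  per <- t(vapply(frames, function(i) {
    fr <- frame_coords(traj, i)
    e_pair <- lj_coulomb_interaction(fr, topology, lig,
                                     eps_in = coeffs$eps_in)
    e_rf <- gb_reaction_field(fr, topology$charges, born_radii,
                              coeffs$eps_in, coeffs$eps_out, lig)
    sasa_c <- sum(sasa_shrake_rupley(fr, radii, probe_radius,
                                     n_sphere_points))
    sasa_p <- sum(sasa_shrake_rupley(fr[prot, , drop = FALSE], radii[prot],
                                     probe_radius, n_sphere_points))
    sasa_l <- sum(sasa_shrake_rupley(fr[lig, , drop = FALSE], radii[lig],
                                     probe_radius, n_sphere_points))
    e_cav <- cavity_term(sasa_c, sasa_p, sasa_l, coeffs$gamma)
    c(e_pair["E_vdw"], e_pair["E_coul"], E_rf = e_rf, E_cav = e_cav)
  }, numeric(4)))
  colnames(per) <- c("E_vdw", "E_coul", "E_rf", "E_cav")
  per <- as.data.frame(per)
  per$dG <- sie_score(per, coeffs)
  rep_means <- do.call(rbind, lapply(split(per, rep_id), function(b)
    colMeans(b[, 1:4])))
  comp_mean <- colMeans(rep_means)
  comp_sd <- if (nrow(rep_means) > 1) apply(rep_means, 2, stats::sd)
             else stats::setNames(rep(0, 4), colnames(rep_means))
  structure(list(dG = unname(sie_score(as.list(comp_mean), coeffs)),
                 component_means = comp_mean, component_sds = comp_sd,
                 n_replicates = nrow(rep_means), n_frames = length(frames),
                 per_frame = per),
            class = "sie_result")
}

#' @export
print.sie_result <- function(x, ...) {
  cat(sprintf(
    "<sie_result> dG = %.2f kcal/mol over %d frame(s), %d replicate(s)\n",
    x$dG, x$n_frames, x$n_replicates))
  m <- x$component_means; s <- x$component_sds
  for (k in names(m))
    cat(sprintf("  %-7s %8.2f +/- %.2f kcal/mol\n", k, m[k], s[k]))
  invisible(x)
}
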