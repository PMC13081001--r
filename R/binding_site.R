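## binding_site: pocket volume by grid flood fill, geometric hydrogen bonds,
## residue-level interaction fingerprints.
##
## Default geometric criteria: hydrogen bond = donor-acceptor heavy-atom
## distance <= 3.5 A and (when a hydrogen is available) D-H...A angle
## >= 130 degrees; hydrophobic contact = carbon/sulfur pair <= 4.5 A;
## van der Waals contact = heavy-atom pair <= 4.0 A.

#' Estimate the volume of an enclosed binding pocket
#'
#' Lays a cubic grid of pitch `grid_spacing` over a sphere of radius
#' `search_radius` around `seed_center`. A grid point is open when its
#' distance to every atom centre exceeds that atom's radius plus
#' `probe_radius`. The pocket is the set of open points 6-connected (flood
#' fill) to the grid point nearest the seed; points on the search-sphere
#' boundary layer are excluded, and a fill that touches the boundary is
#' reported as leaking. Volume = `grid_spacing^3` times the number of pocket
#' points.
#'
#' @param coords `n_atoms x 3` coordinate matrix (angstrom).
#' @param radii Per-atom intrinsic radii (angstrom); see [atom_radii()].
#' @param seed_center Length-3 point inside the pocket.
#' @param search_radius Radius (angstrom) of the search sphere around the
#'   seed.
#' @param grid_spacing Grid pitch in angstrom (default 0.5).
#' @param probe_radius Solvent probe radius in angstrom (default 1.4).
#' @return Object of class `pocket_result`: `volume` (angstrom^3),
#'   `n_points`, `grid_spacing`, `probe_radius`, `seed_center`, and flags
#'   `seed_blocked` (seed point not open: zero volume) and `leak` (fill
#'   reached the search boundary).
#' @export
pocket_volume <- function(coords, radii, seed_center, search_radius = 10,
                          grid_spacing = 0.5, probe_radius = 1.4) {
  coords <- as.matrix(coords)
  if (length(radii) != nrow(coords))
    stop("pocket_volume: radii must match atom count")
  if (probe_radius < 0) stop("pocket_volume: probe radius must be >= 0")
  seed_center <- as.numeric(seed_center)
  ## grid axes centred on the seed
  half <- ceiling(search_radius / grid_spacing)
  ax <- seed_center[1] + grid_spacing * (-half:half)
  ay <- seed_center[2] + grid_spacing * (-half:half)
  az <- seed_center[3] + grid_spacing * (-half:half)
  ng <- length(ax)
  gx <- rep(ax, times = ng * ng)
  gy <- rep(rep(ay, each = ng), times = ng)
  gz <- rep(az, each = ng * ng)
  d2_seed <- (gx - seed_center[1])^2 + (gy - seed_center[2])^2 +
    (gz - seed_center[3])^2
  in_sphere <- d2_seed <= search_radius^2
  ## boundary layer: inside the sphere but within one grid pitch of it
  boundary <- in_sphere & d2_seed > (search_radius - grid_spacing)^2
  ## open test: min distance to any inflated atom, accumulated atom by atom
  min_gap <- rep(Inf, length(gx))
  inflate <- radii + probe_radius
  for (a in seq_len(nrow(coords))) {
    d2 <- (gx - coords[a, 1])^2 + (gy - coords[a, 2])^2 +
      (gz - coords[a, 3])^2
    min_gap <- pmin(min_gap, d2 - inflate[a]^2)
  }
  open <- in_sphere & min_gap > 0
  res <- function(n_points, seed_blocked, leak) {
    structure(list(volume = n_points * grid_spacing^3, n_points = n_points,
                   grid_spacing = grid_spacing, probe_radius = probe_radius,
                   seed_center = seed_center, seed_blocked = seed_blocked,
                   leak = leak),
              class = "pocket_result")
  }
  seed_lin <- half + 1 + ng * half + ng * ng * half  # centre point index
  if (!open[seed_lin]) return(res(0L, seed_blocked = TRUE, leak = FALSE))
  ## vectorised 6-connected flood fill on the linear index; +/-1 steps are
  ## masked on the x-index so they never wrap between grid columns
  visited <- logical(length(gx))
  visited[seed_lin] <- TRUE
  frontier <- seed_lin
  ntot <- length(gx)
  xi <- ((seq_len(ntot) - 1L) %% ng) + 1L
  yi <- (((seq_len(ntot) - 1L) %/% ng) %% ng) + 1L
  offs <- c(-1L, +1L, -ng, +ng, -ng * ng, +ng * ng)
  while (length(frontier) > 0) {
    nb_all <- integer(0)
    for (k in seq_along(offs)) {
      f <- frontier
      if (k == 1L) f <- f[xi[f] > 1L]
      if (k == 2L) f <- f[xi[f] < ng]
      if (k == 3L) f <- f[yi[f] > 1L]
      if (k == 4L) f <- f[yi[f] < ng]
      nb <- f + offs[k]
      nb_all <- c(nb_all, nb[nb >= 1L & nb <= ntot])
    }
    nb_all <- unique(nb_all)
    nb_all <- nb_all[!visited[nb_all] & open[nb_all]]
    visited[nb_all] <- TRUE
    frontier <- nb_all
  }
  pocket <- visited & !boundary
  leak <- any(visited & boundary)
  res(as.integer(sum(pocket)), seed_blocked = FALSE, leak = leak)
}

#' @export
print.pocket_result <- function(x, ...) {
  cat(sprintf("<pocket_result> volume %.1f A^3 (%d points at %.2f A)%s%s\n",
              x$volume, x$n_points, x$grid_spacing,
              if (x$seed_blocked) " [seed blocked]" else "",
              if (x$leak) " [leaks to boundary]" else ""))
  invisible(x)
}

#' Default hydrogen-bond and contact criteria
#'
#' @param hbond_dist Donor-acceptor heavy-atom cutoff, angstrom (3.5).
#' @param hbond_angle Minimum D-H...A angle in degrees (130), applied only
#'   when a hydrogen position is available.
#' @param hydrophobic_dist Carbon/sulfur pair cutoff, angstrom (4.5).
#' @param vdw_dist Heavy-atom pair cutoff, angstrom (4.0).
#' @return Named list of criteria.
#' @export
interaction_criteria <- function(hbond_dist = 3.5, hbond_angle = 130,
                                 hydrophobic_dist = 4.5, vdw_dist = 4.0) {
  list(hbond_dist = hbond_dist, hbond_angle = hbond_angle,
       hydrophobic_dist = hydrophobic_dist, vdw_dist = vdw_dist)
}

#' Detect hydrogen bonds in a single frame
#'
#' A donor-acceptor pair is emitted when the heavy-atom distance is at most
#' `dist_cutoff` and, if a hydrogen position is supplied for the donor, the
#' D-H...A angle is at least `angle_min` degrees. Without hydrogens (e.g. a
#' heavy-atom-only topology) the distance criterion alone applies. Events
#' are ordered by (donor, acceptor).
#'
#' @param coords `n_atoms x 3` frame coordinates (angstrom).
#' @param donors data.frame with column `donor` (atom index) and optional
#'   column `hydrogen` (atom index or NA); or a plain index vector.
#' @param acceptors Vector of acceptor atom indices.
#' @param dist_cutoff Heavy-atom distance cutoff, angstrom (default 3.5).
#' @param angle_min Minimum D-H...A angle, degrees (default 130).
#' @return data.frame with columns `donor`, `hydrogen`, `acceptor`,
#'   `distance`, `angle` (NA without hydrogen).
#' @export
detect_hbonds <- function(coords, donors, acceptors, dist_cutoff = 3.5,
                          angle_min = 130) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (is.atomic(donors)) donors <- data.frame(donor = as.integer(donors),
                                              hydrogen = NA_integer_)
  if (is.null(donors$hydrogen)) donors$hydrogen <- NA_integer_
  all_idx <- c(donors$donor, donors$hydrogen[!is.na(donors$hydrogen)],
               acceptors)
  if (any(all_idx < 1 | all_idx > n))
    stop("detect_hbonds: atom index out of range")
  out <- list()
  for (r in seq_len(nrow(donors))) {
    d <- donors$donor[r]; h <- donors$hydrogen[r]
    for (a in acceptors) {
      if (a == d) next
      dist <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dist > dist_cutoff) next
      ang <- NA_real_
      if (!is.na(h)) {
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[a, ] - coords[h, ]
        cs <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cs, -1), 1)) * 180 / pi
        if (ang < angle_min) next
      }
      out[[length(out) + 1L]] <- data.frame(
        donor = d, hydrogen = if (is.na(h)) NA_integer_ else h,
        acceptor = a, distance = dist, angle = ang)
    }
  }
  if (length(out) == 0)
    return(data.frame(donor = integer(), hydrogen = integer(),
                      acceptor = integer(), distance = numeric(),
                      angle = numeric()))
  ev <- do.call(rbind, out)
  ev[order(ev$donor, ev$acceptor), , drop = FALSE]
}

## Partition the polar heavy atoms (N, O) of a selection into hydrogen-bond
## donors and acceptors. With hydrogens in the topology, donors are the
## polar atoms carrying an attached hydrogen (nearest H within 1.25 A in
## the frame) and every polar atom can accept. Without hydrogens the
## convention is element-based and unambiguous: N donates, O accepts - so
## the two directional detector calls can never double-count a pair.
hbond_partners <- function(topology, indices, coords) {
  el <- toupper(topology$atoms$element)
  polar <- indices[el[indices] %in% c("N", "O")]
  h_all <- which(el == "H")
  if (length(h_all) > 0) {
    hyd <- vapply(polar, function(p) {
      d <- sqrt(rowSums((coords[h_all, , drop = FALSE] -
                         matrix(coords[p, ], length(h_all), 3,
                                byrow = TRUE))^2))
      if (min(d) <= 1.25) h_all[which.min(d)] else NA_integer_
    }, integer(1))
    donors <- data.frame(donor = polar[!is.na(hyd)],
                         hydrogen = hyd[!is.na(hyd)])
    acceptors <- polar
  } else {
    don <- polar[el[polar] == "N"]
    donors <- data.frame(donor = don,
                         hydrogen = rep(NA_integer_, length(don)))
    acceptors <- polar[el[polar] == "O"]
  }
  list(donors = donors, acceptors = acceptors)
}

#' Hydrogen-bond occupancy between a residue and a ligand
#'
#' Counts qualifying hydrogen bonds (either direction) between the polar
#' atoms of one protein residue and the ligand in every frame, averages the
#' count per replicate, and reports the mean and standard deviation across
#' replicate means.
#'
#' @param traj A [trajectory].
#' @param topology Matching [topology].
#' @param resid Residue index of the protein residue.
#' @param ligand_selection Selection (or indices) of ligand atoms.
#' @param replicate_bounds Integer vector of replicate start frames
#'   (first element must be 1); e.g. `c(1, 501)` for two 500-frame
#'   replicates of a 1000-frame trajectory.
#' @param criteria Criteria list from [interaction_criteria()].
#' @param chain Optional chain to disambiguate the residue.
#' @return List with `mean`, `sd`, `per_replicate` (mean count per frame in
#'   each replicate), `n_replicates`.
#' @export
hbond_occupancy <- function(traj, topology, resid, ligand_selection,
                            replicate_bounds = 1L,
                            criteria = interaction_criteria(),
                            chain = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(topology, "topology"))
  keep <- topology$atoms$resid == resid
  if (!is.null(chain)) keep <- keep & topology$atoms$chain == chain
  res_idx <- which(keep)
  if (length(res_idx) == 0)
    stop("hbond_occupancy: residue ", resid, " not found in topology")
  lig_idx <- resolve_selection(ligand_selection, n_atoms(traj))
  nf <- n_frames(traj)
  if (replicate_bounds[1] != 1L)
    stop("hbond_occupancy: replicate_bounds must start at frame 1")
  rep_id <- findInterval(seq_len(nf), replicate_bounds)
  counts <- vapply(seq_len(nf), function(i) {
    fr <- frame_coords(traj, i)
    res_p <- hbond_partners(topology, res_idx, fr)
    lig_p <- hbond_partners(topology, lig_idx, fr)
    e1 <- if (nrow(res_p$donors) > 0 && length(lig_p$acceptors) > 0)
      detect_hbonds(fr, res_p$donors, lig_p$acceptors,
                    criteria$hbond_dist, criteria$hbond_angle)
    else NULL
    e2 <- if (nrow(lig_p$donors) > 0 && length(res_p$acceptors) > 0)
      detect_hbonds(fr, lig_p$donors, res_p$acceptors,
                    criteria$hbond_dist, criteria$hbond_angle)
    else NULL
    ## count unique heavy-atom pairs so a bond is never double-counted
    ## across the two directional calls
    pairs <- unique(rbind(
      if (!is.null(e1)) cbind(pmin(e1$donor, e1$acceptor),
                              pmax(e1$donor, e1$acceptor)),
      if (!is.null(e2)) cbind(pmin(e2$donor, e2$acceptor),
                              pmax(e2$donor, e2$acceptor))))
    if (is.null(pairs)) 0L else nrow(pairs)
  }, integer(1))
  per_rep <- tapply(counts, rep_id, mean)
  m <- mean(per_rep)
  s <- if (length(per_rep) > 1) stats::sd(per_rep) else 0
  list(mean = m, sd = s, per_replicate = as.numeric(per_rep),
       n_replicates = length(per_rep))
}

#' Residue-level interaction fingerprint
#'
#' For every protein residue and frame, flags four interaction classes with
#' the ligand: `hydrophobic` (any carbon/sulfur pair within the hydrophobic
#' cutoff), `hbond_donor` (residue donates to a ligand acceptor),
#' `hbond_acceptor` (residue accepts from a ligand donor), and `vdw_contact`
#' (any heavy-atom pair within the van der Waals cutoff). Matrix cells are
#' the fraction of frames with the flag set; residues whose rows are all
#' zero are omitted.
#'
#' @param traj A [trajectory].
#' @param topology Matching [topology].
#' @param ligand_selection Selection (or indices) of ligand atoms; must be
#'   disjoint from the protein.
#' @param criteria Criteria list from [interaction_criteria()].
#' @return data.frame of class `fingerprint_matrix` with columns `chain`,
#'   `resid`, `resname`, `hydrophobic`, `hbond_donor`, `hbond_acceptor`,
#'   `vdw_contact` (occupancies in [0, 1]).
#' @export
interaction_fingerprint <- function(traj, topology, ligand_selection,
                                    criteria = interaction_criteria()) {
  stopifnot(inherits(traj, "trajectory"), inherits(topology, "topology"))
  lig_idx <- resolve_selection(ligand_selection, n_atoms(traj))
  prot_idx <- setdiff(seq_len(n_atoms(traj)), lig_idx)
  if (length(lig_idx) == 0 || length(prot_idx) == 0)
    stop("interaction_fingerprint: ligand selection must be a non-empty ",
         "proper subset of the atoms")
  at <- topology$atoms
  el <- toupper(at$element)
  res_key <- paste(at$chain, at$resid, sep = ":")
  res_levels <- unique(res_key[prot_idx])
  nf <- n_frames(traj)
  classes <- c("hydrophobic", "hbond_donor", "hbond_acceptor", "vdw_contact")
  hits <- array(0L, dim = c(length(res_levels), length(classes)),
                dimnames = list(res_levels, classes))
  lig_apolar <- lig_idx[el[lig_idx] %in% c("C", "S")]
  lig_heavy <- lig_idx[el[lig_idx] != "H"]
  for (i in seq_len(nf)) {
    fr <- frame_coords(traj, i)
    lig_p <- hbond_partners(topology, lig_idx, fr)
    for (rl in res_levels) {
      ridx <- prot_idx[res_key[prot_idx] == rl]
      r_apolar <- ridx[el[ridx] %in% c("C", "S")]
      r_heavy <- ridx[el[ridx] != "H"]
      flags <- c(hydrophobic = FALSE, hbond_donor = FALSE,
                 hbond_acceptor = FALSE, vdw_contact = FALSE)
      if (length(r_apolar) > 0 && length(lig_apolar) > 0) {
        d <- min_pair_dist(fr, r_apolar, lig_apolar)
        flags["hydrophobic"] <- d <= criteria$hydrophobic_dist
      }
      if (length(r_heavy) > 0 && length(lig_heavy) > 0) {
        d <- min_pair_dist(fr, r_heavy, lig_heavy)
        flags["vdw_contact"] <- d <= criteria$vdw_dist
      }
      r_p <- hbond_partners(topology, ridx, fr)
      if (nrow(r_p$donors) > 0 && length(lig_p$acceptors) > 0) {
        don <- detect_hbonds(fr, r_p$donors, lig_p$acceptors,
                             criteria$hbond_dist, criteria$hbond_angle)
        flags["hbond_donor"] <- nrow(don) > 0
      }
      if (nrow(lig_p$donors) > 0 && length(r_p$acceptors) > 0) {
        acc <- detect_hbonds(fr, lig_p$donors, r_p$acceptors,
                             criteria$hbond_dist, criteria$hbond_angle)
        flags["hbond_acceptor"] <- nrow(acc) > 0
      }
      hits[rl, ] <- hits[rl, ] + as.integer(flags)
    }
  }
  occ <- hits / nf
  nonzero <- rowSums(occ) > 0
  kept <- res_levels[nonzero]
  first_at <- match(kept, res_key)
  out <- data.frame(
    chain = at$chain[first_at], resid = at$resid[first_at],
    resname = at$resname[first_at],
    occ[nonzero, , drop = FALSE],
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("fingerprint_matrix", class(out))
  out
}

## minimum pairwise distance between two index sets in one frame
min_pair_dist <- function(coords, idx_a, idx_b) {
  A <- coords[idx_a, , drop = FALSE]
  B <- coords[idx_b, , drop = FALSE]
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}
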