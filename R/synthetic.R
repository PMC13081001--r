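## synthetic_data: generators with recorded ground truth for every pipeline
## stage. Each generator is a pure function of its arguments and seed: the
## caller's RNG state is restored on exit and the same seed reproduces the
## output bit for bit.

## Backbone scaffold: n_res residues x 4 atoms (N, CA, C, O) laid out on a
## helical curve. `residue_spacing` controls the distance between
## consecutive residues along the curve; wide spacing gives residues that
## are spatially isolated, which planted-interaction fixtures rely on.
make_scaffold <- function(n_res = 30, resid = seq_len(n_res),
                          resname = rep("ALA", n_res),
                          chain = "A", residue_spacing = 3.8) {
  stopifnot(length(resid) == n_res, length(resname) == n_res)
  atom_names <- c("N", "CA", "C", "O")
  elements <- c("N", "C", "C", "O")
  ## helix: radius grows with spacing so consecutive residues are
  ## residue_spacing apart along the arc
  turn <- 100 * pi / 180
  radius <- residue_spacing / (2 * sin(turn / 2)) * 0.9
  rise <- residue_spacing * 0.45
  coords <- matrix(NA_real_, n_res * 4, 3)
  offsets <- rbind(c(-0.7, -0.6, -0.4), c(0, 0, 0),
                   c(0.8, 0.5, 0.3), c(1.0, -0.7, 0.9))
  for (r in seq_len(n_res)) {
    ang <- (r - 1) * turn
    ca <- c(radius * cos(ang), radius * sin(ang), (r - 1) * rise)
    for (a in 1:4)
      coords[(r - 1) * 4 + a, ] <- ca + offsets[a, ]
  }
  top <- topology(data.frame(
    serial = seq_len(n_res * 4),
    name = rep(atom_names, n_res),
    element = rep(elements, n_res),
    resname = rep(resname, each = 4),
    resid = rep(as.integer(resid), each = 4),
    chain = chain, stringsAsFactors = FALSE))
  list(topology = top, coords = coords)
}

## Orthonormal 3N directions orthogonal to the 6 rigid-body modes
## (3 translations + 3 infinitesimal rotations) of `base`, so that basin
## displacements survive superposition.
conformational_directions <- function(base, k) {
  n <- nrow(base)
  centred <- sweep(base, 2, colMeans(base))
  rigid <- matrix(0, 3 * n, 6)
  for (ax in 1:3) rigid[seq(ax, 3 * n, by = 3), ax] <- 1  # translations
  ## infinitesimal rotations about x, y, z: dr = e_ax x r
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    cr <- t(apply(centred, 1, function(r)
      c(e[2] * r[3] - e[3] * r[2],
        e[3] * r[1] - e[1] * r[3],
        e[1] * r[2] - e[2] * r[1])))
    rigid[, 3 + ax] <- as.numeric(t(cr))
  }
  Q <- qr.Q(qr(rigid))
  dirs <- matrix(stats::rnorm(3 * n * k), 3 * n, k)
  dirs <- dirs - Q %*% crossprod(Q, dirs)   # project out rigid modes
  qr.Q(qr(dirs))[, seq_len(k), drop = FALSE]
}

#' Generate a multi-basin synthetic trajectory
#'
#' Emulates conformational sampling over a small number of metastable
#' basins: each frame independently samples a basin according to the
#' occupancies, takes that basin's reference conformation, and adds
#' isotropic Gaussian jitter to every coordinate. Basin reference
#' conformations are displaced from a common scaffold along mutually
#' orthogonal directions that are orthogonal to the rigid-body modes, so
#' pairwise backbone RMSD separations equal `separation` and survive
#' superposition.
#'
#' @param n_residues Scaffold size (default 30 residues x 4 backbone atoms).
#' @param occupancies Basin occupancies, at least 2 values summing to 1.
#' @param n_frames Number of frames.
#' @param jitter_sd Isotropic jitter standard deviation per coordinate
#'   (angstrom, default 0.5).
#' @param separation Pairwise basin RMSD separation (angstrom, default 6).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and this seed.
#' @param assign `"random"` (default): basins drawn independently per frame;
#'   `"exact"`: a deterministic interleaved pattern realizing each occupancy
#'   to within one frame (exact when `occupancy * n_frames` is an integer).
#' @param time_span_ns Optional total time span; frames are then stamped
#'   with evenly spaced times from 0 to `time_span_ns`.
#' @return List with `topology`, `trajectory` and `truth`. The truth record
#'   carries `occupancies`, per-frame `assignment`, the basin reference
#'   conformations and displacement `directions`, `separation`, `jitter_sd`,
#'   `seed`, and `jitter_warning` (TRUE when `separation < 3 * jitter_sd`,
#'   i.e. basins overlap substantially).
#' @export
gen_multibasin_trajectory <- function(n_residues = 30,
                                      occupancies = c(0.8, 0.2),
                                      n_frames = 2000, jitter_sd = 0.5,
                                      separation = 6, seed = 1,
                                      assign = c("random", "exact"),
                                      time_span_ns = NULL) {
  assign <- match.arg(assign)
  k <- length(occupancies)
  if (k < 2) stop("gen_multibasin_trajectory: need at least 2 basins")
  if (abs(sum(occupancies) - 1) > 1e-8)
    stop("gen_multibasin_trajectory: occupancies must sum to 1")
  with_seed(seed, {
    sc <- make_scaffold(n_residues)
    n_at <- nrow(sc$coords)
    dirs <- conformational_directions(sc$coords, k)
    ## place basin i at amp * dirs[, i]; orthogonal displacements give
    ## pairwise 3N distance amp * sqrt(2) and RMSD = that / sqrt(n_at)
    amp <- separation * sqrt(n_at) / sqrt(2)
    basin_refs <- lapply(seq_len(k), function(i) {
      sc$coords + matrix(amp * dirs[, i], ncol = 3, byrow = TRUE)
    })
    assignment <- if (assign == "random") {
      sample.int(k, n_frames, replace = TRUE, prob = occupancies)
    } else {
      ## interleaved deterministic pattern: basin i occupies the frames
      ## where its cumulative quota increments
      cum <- c(0, cumsum(occupancies))
      out <- integer(n_frames)
      taken <- logical(n_frames)
      for (i in seq_len(k)) {
        quota <- floor(seq_len(n_frames) * occupancies[i] + 1e-9)
        want <- which(diff(c(0, quota)) == 1L)
        slots <- which(!taken)[seq_along(want)]
        out[slots] <- i; taken[slots] <- TRUE
      }
      out[out == 0L] <- k
      out
    }
    coords <- array(NA_real_, dim = c(n_frames, n_at, 3))
    for (f in seq_len(n_frames)) {
      coords[f, , ] <- basin_refs[[assignment[f]]] +
        matrix(stats::rnorm(3 * n_at, sd = jitter_sd), n_at, 3)
    }
    times <- if (!is.null(time_span_ns))
      seq(0, time_span_ns, length.out = n_frames) else NULL
    truth <- list(occupancies = occupancies, assignment = assignment,
                  basin_refs = basin_refs, directions = dirs,
                  separation = separation, jitter_sd = jitter_sd,
                  seed = seed,
                  jitter_warning = separation < 3 * jitter_sd)
    list(topology = sc$topology,
         trajectory = trajectory(coords, times), truth = truth)
  })
}

## Per-class default contact distances (angstrom) for planted interactions.
.planted_defaults <- c(hydrophobic = 3.8, hbond_donor = 2.9,
                       hbond_acceptor = 2.9, vdw_contact = 3.7)

#' Generate a toy protein-ligand complex with planted interactions
#'
#' Builds a rigid, widely spaced scaffold whose residue labels mirror a
#' serine-hydrolase active site (Thr43, Thr45, Ser120, Gln121, His185 among
#' generic residues) and a short oligomer ligand with one dedicated atom per
#' planted contact. In each frame a contact is either realized at its
#' contact distance from the target residue or parked 12 A away; the on/off
#' pattern is a deterministic interleaving that reproduces the requested
#' occupancy exactly whenever `occupancy * n_frames` is an integer.
#'
#' Contact classes use elements that trigger exactly the intended detector:
#' carbon (hydrophobic), oxygen acceptor for `hbond_donor` (the residue's
#' backbone N donates), nitrogen donor for `hbond_acceptor` (the residue's
#' backbone O accepts), and phosphorus (vdw-only contact; neither apolar
#' nor a hydrogen-bonding element).
#'
#' @param planted_contacts data.frame with columns `resid`, `class`
#'   (hydrophobic, hbond_donor, hbond_acceptor, vdw_contact), `occupancy`
#'   in [0, 1], and optionally `distance` (angstrom). May have zero rows.
#' @param n_frames Number of frames (default 200).
#' @param seed Integer seed.
#' @return List with `topology`, `trajectory`, `ligand_selection`
#'   (atom indices), and `truth` (the planted contact table with realized
#'   per-contact occupancies and the seed).
#' @export
gen_toy_complex <- function(planted_contacts = data.frame(), n_frames = 200,
                            seed = 1) {
  resid <- c(40:47, 116:136, 185L)
  resname <- rep("ALA", 30)
  resname[match(c(43, 45, 120, 121, 185), resid)] <-
    c("THR", "THR", "SER", "GLN", "HIS")
  if (nrow(planted_contacts) > 0) {
    if (!all(c("resid", "class", "occupancy") %in% names(planted_contacts)))
      stop("gen_toy_complex: planted_contacts needs resid, class, occupancy")
    if (any(planted_contacts$occupancy < 0 | planted_contacts$occupancy > 1))
      stop("gen_toy_complex: occupancies must lie in [0, 1]")
    bad <- setdiff(planted_contacts$class, names(.planted_defaults))
    if (length(bad) > 0)
      stop("gen_toy_complex: unknown interaction class: ",
           paste(bad, collapse = ", "))
    if (!all(planted_contacts$resid %in% resid))
      stop("gen_toy_complex: residue(s) not in scaffold: ",
           paste(setdiff(planted_contacts$resid, resid), collapse = ", "))
  }
  with_seed(seed, {
    sc <- make_scaffold(30, resid = resid, resname = resname,
                        residue_spacing = 14)
    prot_at <- sc$topology$atoms
    nc <- nrow(planted_contacts)
    n_lig <- nc + 2L    # one atom per contact plus two far spacer carbons
    lig_el <- c(if (nc > 0) vapply(planted_contacts$class, function(cl)
                  switch(cl, hydrophobic = "C", hbond_donor = "O",
                         hbond_acceptor = "N", vdw_contact = "P"),
                  character(1)),
                "C", "C")
    atoms <- rbind(
      prot_at,
      data.frame(serial = nrow(prot_at) + seq_len(n_lig),
                 name = paste0(lig_el, seq_len(n_lig)),
                 element = lig_el, resname = "LIG", resid = 999L,
                 chain = "L", stringsAsFactors = FALSE))
    top <- topology(atoms)
    lig_idx <- nrow(prot_at) + seq_len(n_lig)
    centroid <- colMeans(sc$coords)
    ## target atom per contact: the residue atom the detector inspects
    target_atom <- if (nc > 0) vapply(seq_len(nc), function(i) {
      r <- planted_contacts$resid[i]
      nm <- switch(planted_contacts$class[i],
                   hbond_donor = "N", hbond_acceptor = "O", "CA")
      which(prot_at$resid == r & prot_at$name == nm)
    }, integer(1)) else integer(0)
    dist_i <- if (nc > 0) {
      d <- planted_contacts$distance
      if (is.null(d)) d <- rep(NA_real_, nc)
      ifelse(is.na(d), .planted_defaults[planted_contacts$class], d)
    } else numeric(0)
    ## outward unit direction per contact (away from the scaffold centroid)
    out_dir <- if (nc > 0) t(vapply(seq_len(nc), function(i) {
      v <- sc$coords[target_atom[i], ] - centroid
      v / sqrt(sum(v^2))
    }, numeric(3))) else matrix(0, 0, 3)
    on_pos <- if (nc > 0) lapply(seq_len(nc), function(i)
      sc$coords[target_atom[i], ] + dist_i[i] * out_dir[i, ]) else list()
    off_pos <- if (nc > 0) lapply(seq_len(nc), function(i)
      sc$coords[target_atom[i], ] + 12 * out_dir[i, ]) else list()
    ## satisfiability: a planted atom must not fall within any class cutoff
    ## (4.5 A) of a residue other than its target
    if (nc > 0) {
      for (i in seq_len(nc)) {
        other <- which(prot_at$resid != planted_contacts$resid[i])
        dmin <- min(sqrt(rowSums(sweep(sc$coords[other, , drop = FALSE], 2,
                                       on_pos[[i]])^2)))
        if (dmin <= 4.5)
          stop("gen_toy_complex: contact ", i,
               " is geometrically unsatisfiable (collides with another residue)")
      }
    }
    far <- centroid + c(0, 0, 200)   # spacer atoms, far from everything
    on_pattern <- function(occ) {
      quota <- floor(seq_len(n_frames) * occ + 1e-9)
      diff(c(0, quota)) == 1L
    }
    patterns <- lapply(seq_len(nc), function(i)
      on_pattern(planted_contacts$occupancy[i]))
    coords <- array(NA_real_, dim = c(n_frames, nrow(atoms), 3))
    for (f in seq_len(n_frames)) {
      fr <- rbind(sc$coords, matrix(NA_real_, n_lig, 3))
      for (i in seq_len(nc))
        fr[nrow(prot_at) + i, ] <-
          if (patterns[[i]][f]) on_pos[[i]] else off_pos[[i]]
      fr[nrow(prot_at) + nc + 1L, ] <- far
      fr[nrow(prot_at) + nc + 2L, ] <- far + c(5, 0, 0)
      coords[f, , ] <- fr
    }
    truth <- list(
      contacts = if (nc > 0) cbind(planted_contacts,
        realized = vapply(patterns, mean, numeric(1)),
        distance_used = dist_i) else planted_contacts,
      seed = seed)
    list(topology = top, trajectory = trajectory(coords),
         ligand_selection = lig_idx, truth = truth)
  })
}

#' Generate a hollow spherical shell enclosing a cavity of known volume
#'
#' Atoms are placed on one or more concentric golden-spiral spheres so that
#' the probe-eroded interior is a cavity of effective radius `inner_radius`
#' (shell centre radius = `inner_radius + atom_radius + probe_radius`). The
#' analytic cavity volume `(4/3) * pi * inner_radius^3` is recorded in the
#' truth. The seed randomizes the spiral orientation only.
#'
#' @param inner_radius Effective cavity radius, angstrom; must exceed the
#'   probe radius.
#' @param shell_thickness Radial shell extent (angstrom); extra layers are
#'   added every `spacing` until it is covered (default one layer).
#' @param atom_radius Intrinsic radius of the shell atoms (default 1.5).
#' @param spacing Target spacing between shell atoms (angstrom, default 1);
#'   must not exceed `atom_radius + probe_radius`, or the shell would leak.
#' @param probe_radius Probe the shell must be tight against (default 1.4).
#' @param seed Integer seed.
#' @return List with `topology`, `trajectory` (single frame), `center` and
#'   `truth` (`volume` = analytic cavity volume, `inner_radius`, `seed`).
#' @export
gen_pocket_structure <- function(inner_radius = 6, shell_thickness = 1,
                                 atom_radius = 1.5, spacing = 1.0,
                                 probe_radius = 1.4, seed = 1) {
  if (inner_radius <= probe_radius)
    stop("gen_pocket_structure: inner radius must exceed the probe radius")
  if (spacing > atom_radius + probe_radius)
    stop("gen_pocket_structure: spacing ", spacing,
         " leaves holes larger than the probe (cavity would leak)")
  with_seed(seed, {
    ## random rotation for the spiral orientation
    q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
    R <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
      2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
      2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
      1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
    r0 <- inner_radius + atom_radius + probe_radius
    layer_radii <- seq(r0, r0 + shell_thickness, by = spacing)
    coords <- do.call(rbind, lapply(layer_radii, function(rad) {
      n <- ceiling(4 * pi * rad^2 / spacing^2)
      k <- seq_len(n)
      z <- (2 * k - 1) / n - 1
      th <- k * pi * (3 - sqrt(5))
      rho <- sqrt(pmax(0, 1 - z^2))
      rad * cbind(rho * cos(th), rho * sin(th), z) %*% t(R)
    }))
    n_at <- nrow(coords)
    top <- topology(data.frame(
      serial = seq_len(n_at), name = "C", element = "C",
      resname = "SPH", resid = seq_len(n_at), chain = "A",
      stringsAsFactors = FALSE),
      radii = rep(atom_radius, n_at))
    truth <- list(volume = 4 / 3 * pi * inner_radius^3,
                  inner_radius = inner_radius, seed = seed)
    list(topology = top, trajectory = trajectory(coords),
         center = c(0, 0, 0), truth = truth)
  })
}

#' Generate a synthetic SIE energy table with known coefficients
#'
#' Components are drawn uniformly from the given ranges and the reference
#' free energy follows the linear model
#' `dG = alpha * sum(components) + C + N(0, noise_sd)`.
#'
#' @param n_rows Number of rows, at least 2.
#' @param alpha,C Model coefficients (defaults from [sie_coefficients()]).
#' @param component_ranges Named list of `c(lo, hi)` ranges per component;
#'   defaults span typical protein-oligomer interaction magnitudes.
#' @param noise_sd Gaussian noise on dG, kcal/mol (default 0).
#' @param seed Integer seed.
#' @return An `energy_table` data.frame with the four component columns and
#'   `dG`; the truth (`alpha`, `C`, `noise_sd`, `seed`) is attached as
#'   attribute `"truth"`. A rank warning is issued when all component ranges
#'   are degenerate (the calibration design would be singular).
#' @export
gen_energy_table <- function(n_rows, alpha = 0.1048, C = -2.89,
                             component_ranges = list(
                               E_vdw = c(-60, -35), E_coul = c(-25, 30),
                               E_rf = c(-25, 20), E_cav = c(-12, -7)),
                             noise_sd = 0, seed = 1) {
  if (n_rows < 2) stop("gen_energy_table: need at least 2 rows")
  widths <- vapply(component_ranges, function(r) diff(range(r)), numeric(1))
  if (all(widths == 0))
    warning("gen_energy_table: all component ranges degenerate; ",
            "calibration design will be rank-deficient")
  with_seed(seed, {
    df <- as.data.frame(lapply(component_ranges, function(r)
      stats::runif(n_rows, r[1], r[2])))
    df$dG <- alpha * rowSums(df) + C + stats::rnorm(n_rows, sd = noise_sd)
    class(df) <- c("energy_table", class(df))
    attr(df, "truth") <- list(alpha = alpha, C = C, noise_sd = noise_sd,
                              seed = seed)
    df
  })
}
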