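## conformational_landscape: Cartesian PCA, free-energy landscapes, minima,
## clustering, stable-window selection.
##
## The free-energy landscape (FEL) is the binned surface
## dG(b) = -kT * ln(P(b) / P_max) over the first two principal components,
## with kT = kB * T (kB = 0.0019872041 kcal/mol/K). At the default
## simulation temperature of 313.15 K, kT ~ 0.6223 kcal/mol.

#' Fit a Cartesian PCA model to a trajectory
#'
#' Frames are superposed onto the mean structure over the selection (two-pass
#' scheme, as in [rmsf_profile()]) unless `superpose = FALSE`, then the
#' 3N x 3N covariance of the selected coordinates is eigendecomposed.
#' Variance fractions are eigenvalues divided by the covariance trace.
#' Component sign convention: each component's largest-magnitude element is
#' made positive, so orientations are reproducible.
#'
#' @param traj A [trajectory] with at least 2 frames.
#' @param selection Optional selection; PCA runs on these atoms only.
#' @param superpose Superpose frames onto the mean structure first
#'   (default TRUE). Set FALSE when frames are already aligned.
#' @return Object of class `pca_model`: `mean_structure` (3N vector,
#'   angstrom), `components` (3N x k orthonormal matrix), `eigenvalues`
#'   (angstrom^2, descending), `variance_fractions`, `atom_indices`.
#' @export
pca_fit <- function(traj, selection = NULL, superpose = TRUE) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 2) stop("pca_fit: need at least 2 frames")
  idx <- resolve_selection(selection, n_atoms(traj))
  if (length(idx) < 3) stop("pca_fit: need at least 3 selected atoms")
  if (superpose) {
    ref1 <- frame_coords(traj, 1)
    pass1 <- superpose_all(traj, ref1, idx)
    mean1 <- apply(pass1, c(2, 3), mean)
    aligned <- superpose_all(trajectory(pass1), mean1, idx)
  } else {
    aligned <- traj$coords
  }
  ## frames x 3N matrix of selected coordinates (x1 y1 z1 x2 ...)
  X <- t(vapply(seq_len(nf), function(i) {
    as.numeric(t(matrix(aligned[i, idx, ], ncol = 3)))
  }, numeric(3 * length(idx))))
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  total_var <- sum(Xc^2) / (nf - 1)
  if (total_var <= 0) stop("pca_fit: zero total variance")
  C <- crossprod(Xc) / (nf - 1)
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  V <- eg$vectors
  ## reproducible sign: largest-|element| of each component positive
  for (k in seq_len(ncol(V))) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(mean_structure = mu, components = V, eigenvalues = ev,
                 variance_fractions = ev / sum(ev), atom_indices = idx),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  vf <- x$variance_fractions
  cat(sprintf(
    "<pca_model> %d coordinates; PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%% of variance\n",
    length(x$mean_structure), 100 * vf[1], 100 * vf[2],
    if (length(vf) >= 3) 100 * vf[3] else NA))
  invisible(x)
}

#' Project a trajectory onto principal components
#'
#' Each frame is superposed onto the model's mean structure over the model's
#' atom selection (unless `superpose = FALSE`), centred, and projected.
#' Projecting the mean structure itself gives the zero vector; using the
#' full basis reconstructs the centred coordinates exactly.
#'
#' @param model A `pca_model` from [pca_fit()].
#' @param traj A [trajectory] with a compatible atom count.
#' @param n_components Number of leading components to project onto.
#' @param superpose Superpose frames onto the model mean first (default TRUE).
#' @return `n_frames x n_components` matrix of projections (angstrom).
#' @export
pca_project <- function(model, traj, n_components = 2, superpose = TRUE) {
  stopifnot(inherits(model, "pca_model"), inherits(traj, "trajectory"))
  if (n_components > ncol(model$components))
    stop("pca_project: n_components exceeds available components")
  idx <- model$atom_indices
  if (max(idx) > n_atoms(traj))
    stop("pca_project: trajectory atom count incompatible with model")
  nf <- n_frames(traj)
  mean_mat <- matrix(model$mean_structure, ncol = 3, byrow = TRUE)
  X <- t(vapply(seq_len(nf), function(i) {
    fr <- matrix(traj$coords[i, idx, ], ncol = 3)
    if (superpose) {
      sp <- kabsch_superpose(fr, mean_mat, NULL)
      fr <- apply_superposition(fr, sp)
    }
    as.numeric(t(fr))
  }, numeric(3 * length(idx))))
  Xc <- sweep(X, 2, model$mean_structure)
  proj <- Xc %*% model$components[, seq_len(n_components), drop = FALSE]
  colnames(proj) <- paste0("PC", seq_len(n_components))
  proj
}

#' Build a free-energy landscape on PC1/PC2
#'
#' Bins the first two projection columns on a regular grid and converts
#' occupation probabilities to free energies:
#' `dG(b) = -kT * ln(P(b) / P_max)`, so the most occupied bin is exactly 0.
#' Empty bins are assigned a finite cap.
#'
#' @param projections Matrix with at least 2 columns (PC1, PC2), angstrom.
#' @param n_bins Bins per axis (default 60); the grid spans the data range
#'   padded by 2% on each side.
#' @param temperature_K Temperature in kelvin (default 313.15).
#' @param cap Free energy assigned to empty bins (kcal/mol); default: max
#'   occupied dG + 1 kT.
#' @return Object of class `fel_surface`: `pc1_edges`, `pc2_edges`, `dG`
#'   (n_bins x n_bins, kcal/mol), `counts`, `kT`, `cap`.
#' @export
fel_build <- function(projections, n_bins = 60, temperature_K = 313.15,
                      cap = NULL) {
  projections <- as.matrix(projections)
  if (nrow(projections) < 1) stop("fel_build: no projection points")
  if (ncol(projections) < 2) stop("fel_build: need at least 2 components")
  if (n_bins < 2) stop("fel_build: need at least 2 bins per axis")
  if (temperature_K <= 0) stop("fel_build: temperature must be positive")
  kT <- .kB * temperature_K
  pad_edges <- function(v) {
    r <- range(v)
    span <- diff(r)
    if (span == 0) span <- 1  # degenerate axis: unit-width grid
    lo <- r[1] - 0.02 * span
    hi <- r[2] + 0.02 * span
    seq(lo, hi, length.out = n_bins + 1)
  }
  e1 <- pad_edges(projections[, 1])
  e2 <- pad_edges(projections[, 2])
  b1 <- pmin(pmax(findInterval(projections[, 1], e1, rightmost.closed = TRUE),
                  1L), n_bins)
  b2 <- pmin(pmax(findInterval(projections[, 2], e2, rightmost.closed = TRUE),
                  1L), n_bins)
  counts <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(b1, levels = seq_len(n_bins)),
               factor(b2, levels = seq_len(n_bins)))
  counts[] <- as.integer(tab)
  occupied <- counts > 0
  dG <- matrix(NA_real_, n_bins, n_bins)
  dG[occupied] <- -kT * log(counts[occupied] / max(counts))
  if (is.null(cap)) cap <- max(dG[occupied]) + kT
  if (any(occupied) && cap < max(dG[occupied]))
    stop("fel_build: cap below the maximum occupied free energy")
  dG[!occupied] <- cap
  structure(list(pc1_edges = e1, pc2_edges = e2, dG = dG, counts = counts,
                 kT = kT, cap = cap),
            class = "fel_surface")
}

#' @export
print.fel_surface <- function(x, ...) {
  cat(sprintf(
    "<fel_surface> %d x %d bins, kT = %.4f kcal/mol, cap = %.3f, %d occupied\n",
    nrow(x$dG), ncol(x$dG), x$kT, x$cap, sum(x$counts > 0)))
  invisible(x)
}

#' Plot a free-energy landscape
#'
#' @param x A `fel_surface`.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.fel_surface <- function(x, ...) {
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::image(mids(x$pc1_edges), mids(x$pc2_edges), x$dG,
                  col = grDevices::hcl.colors(32, "viridis", rev = TRUE),
                  xlab = "PC1 (Å)", ylab = "PC2 (Å)", ...)
  invisible(x)
}

## 3x3 box smoothing with edge truncation (average over available cells).
box_smooth <- function(M) {
  n1 <- nrow(M); n2 <- ncol(M)
  S <- matrix(0, n1, n2); W <- matrix(0, n1, n2)
  for (di in -1:1) for (dj in -1:1) {
    i_src <- max(1, 1 - di):min(n1, n1 - di)
    j_src <- max(1, 1 - dj):min(n2, n2 - dj)
    S[i_src + di, j_src + dj] <- S[i_src + di, j_src + dj] +
      M[i_src, j_src]
    W[i_src + di, j_src + dj] <- W[i_src + di, j_src + dj] + 1
  }
  S / W
}

#' Locate free-energy minima on a landscape
#'
#' The surface is smoothed with a uniform 3x3 box filter; occupied bins that
#' are minima of the smoothed surface within their 8-neighbourhood become
#' candidates. Finite sampling always fragments a broad basin into several
#' shallow local minima, so candidates lying in the same 8-connected region
#' of occupied bins are merged into one basin - genuinely separated wells
#' stay apart because the bins between them are empty. Each basin's centre
#' is its lowest raw `dG` bin (ties broken by row-major bin order); basins
#' whose centre lies more than `depth_window` above the global minimum are
#' dropped, and the survivors are ranked by centre `dG` ascending. On a
#' perfectly flat occupied surface every bin is a candidate in a single
#' connected region, giving one minimum at the first bin in row-major
#' order.
#'
#' Two depths are reported per basin: `dG`, the raw surface value at the
#' centre bin (the conventional landscape depth, read from a single
#' histogram bin), and `dG_basin`, the basin free energy
#' `-kT * ln(P_basin / P_deepest)` computed from the total occupancy of the
#' basin's bins. The occupancy-based `dG_basin` is the statistically
#' reliable depth estimate on finite samples: single-bin counts carry
#' Poisson noise and a maximum-over-bins bias, whereas basin occupancies
#' are binomial with negligible bias.
#'
#' @param surface A `fel_surface` from [fel_build()].
#' @param smoothing_bins Number of 3x3 smoothing passes (default 1; 0 to
#'   disable).
#' @param max_minima Maximum number of minima returned (default 4).
#' @param depth_window Retain basins whose centre `dG` is within this many
#'   kcal/mol of the global minimum (default 2).
#' @return data.frame of class `fel_minima` with columns `rank`, `bin1`,
#'   `bin2`, `pc1`, `pc2`, `dG`, `occupancy` (fraction of all frames in the
#'   basin), `dG_basin`; empty when the surface has no occupied bin.
#' @export
find_minima <- function(surface, smoothing_bins = 1, max_minima = 4,
                        depth_window = 2.0) {
  stopifnot(inherits(surface, "fel_surface"))
  occupied <- surface$counts > 0
  empty_res <- data.frame(rank = integer(), bin1 = integer(),
                          bin2 = integer(), pc1 = numeric(), pc2 = numeric(),
                          dG = numeric(), occupancy = numeric(),
                          dG_basin = numeric())
  class(empty_res) <- c("fel_minima", class(empty_res))
  if (!any(occupied)) return(empty_res)
  sm <- surface$dG
  if (smoothing_bins > 0) for (p in seq_len(smoothing_bins)) sm <- box_smooth(sm)
  n1 <- nrow(sm); n2 <- ncol(sm)
  is_cand <- matrix(FALSE, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    if (!occupied[i, j]) next
    ii <- max(1, i - 1):min(n1, i + 1)
    jj <- max(1, j - 1):min(n2, j + 1)
    if (sm[i, j] <= min(sm[ii, jj])) is_cand[i, j] <- TRUE
  }
  if (!any(is_cand)) return(empty_res)
  ## label 8-connected components of occupied bins
  comp <- matrix(0L, n1, n2)
  ncomp <- 0L
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    if (!occupied[i, j] || comp[i, j] != 0L) next
    ncomp <- ncomp + 1L
    stack <- list(c(i, j)); comp[i, j] <- ncomp
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        a <- p[1] + di; b <- p[2] + dj
        if (a >= 1 && a <= n1 && b >= 1 && b <= n2 &&
            occupied[a, b] && comp[a, b] == 0L) {
          comp[a, b] <- ncomp
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  ## a basin = an occupied component containing at least one candidate
  cand_comps <- sort(unique(comp[is_cand]))
  total <- sum(surface$counts)
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  m1 <- mids(surface$pc1_edges); m2 <- mids(surface$pc2_edges)
  basins <- lapply(cand_comps, function(k) {
    in_comp <- comp == k
    ## centre: lowest raw dG bin of the component; ties row-major
    v <- surface$dG
    v[!in_comp] <- Inf
    best_v <- min(v)
    hits <- which(v <= best_v + 1e-12, arr.ind = TRUE)
    hits <- hits[order(hits[, 2], hits[, 1]), , drop = FALSE]
    c(hits[1, 1], hits[1, 2], best_v, sum(surface$counts[in_comp]) / total)
  })
  basins <- do.call(rbind, basins)
  keep <- basins[, 3] <= min(basins[, 3]) + depth_window
  basins <- basins[keep, , drop = FALSE]
  ord <- order(basins[, 3], basins[, 2], basins[, 1])
  basins <- basins[ord, , drop = FALSE]
  if (nrow(basins) > max_minima)
    basins <- basins[seq_len(max_minima), , drop = FALSE]
  out <- data.frame(rank = seq_len(nrow(basins)),
                    bin1 = as.integer(basins[, 1]),
                    bin2 = as.integer(basins[, 2]),
                    pc1 = m1[basins[, 1]], pc2 = m2[basins[, 2]],
                    dG = basins[, 3],
                    occupancy = basins[, 4],
                    dG_basin = surface$kT *
                      log(max(basins[, 4]) / basins[, 4]))
  class(out) <- c("fel_minima", class(out))
  out
}

#' Representative frame for a free-energy minimum
#'
#' Returns the index of the frame whose (PC1, PC2) point lies closest
#' (Euclidean) to the minimum's bin centre; ties are broken by the lowest
#' frame index.
#'
#' @param projections The projection matrix the surface was built from.
#' @param minimum One row of a `fel_minima` data.frame (or any list with
#'   `pc1` and `pc2`).
#' @return Integer frame index.
#' @export
representative_frame <- function(projections, minimum) {
  projections <- as.matrix(projections)
  if (nrow(projections) < 1) stop("representative_frame: no frames")
  d2 <- (projections[, 1] - minimum$pc1)^2 + (projections[, 2] - minimum$pc2)^2
  which.min(d2)   # which.min returns the first (lowest-index) minimiser
}

#' Cluster trajectory frames by pairwise superposed RMSD
#'
#' Average-linkage agglomerative clustering ([stats::hclust()]) on the
#' matrix of pairwise Kabsch-superposed RMSDs over the selection, cut at
#' `rmsd_cutoff`. Each cluster's representative is the frame with the
#' minimal mean RMSD to the other members (its medoid). Cluster labels are
#' renumbered by decreasing size (label 1 = largest).
#'
#' @param traj A [trajectory].
#' @param selection Optional selection for the superposition and RMSD.
#' @param rmsd_cutoff Height (angstrom) at which the dendrogram is cut;
#'   must be positive.
#' @return Object of class `cluster_result`: `labels` (per frame), `sizes`,
#'   `largest_fraction`, `representatives` (frame index per cluster),
#'   `rmsd_matrix`.
#' @export
cluster_frames <- function(traj, selection = NULL, rmsd_cutoff = 2.0) {
  stopifnot(inherits(traj, "trajectory"))
  if (rmsd_cutoff <= 0) stop("cluster_frames: cutoff must be positive")
  nf <- n_frames(traj)
  idx <- resolve_selection(selection, n_atoms(traj))
  M <- matrix(0, nf, nf)
  if (nf > 1) {
    for (i in seq_len(nf - 1)) {
      fi <- frame_coords(traj, i)
      for (j in (i + 1):nf) {
        r <- kabsch_superpose(frame_coords(traj, j), fi, idx)$rmsd
        M[i, j] <- r; M[j, i] <- r
      }
    }
  }
  if (nf == 1) {
    labels <- 1L
  } else {
    hc <- stats::hclust(stats::as.dist(M), method = "average")
    ## identical frames give zero distances whose averaged merge heights can
    ## drift below machine epsilon out of order; rounding restores the
    ## monotonicity cutree requires
    hc$height <- round(hc$height, 8)
    labels <- stats::cutree(hc, h = rmsd_cutoff)
  }
  ## renumber clusters by decreasing size; ties by first occurrence
  sz <- table(labels)
  ord <- order(-as.integer(sz),
               vapply(names(sz), function(l) min(which(labels == l)),
                      numeric(1)))
  remap <- stats::setNames(seq_along(ord), names(sz)[ord])
  labels <- as.integer(remap[as.character(labels)])
  sizes <- as.integer(table(labels))
  reps <- vapply(seq_along(sizes), function(k) {
    members <- which(labels == k)
    if (length(members) == 1) return(members)
    mean_r <- rowMeans(M[members, members, drop = FALSE])
    members[which.min(mean_r)]
  }, integer(1))
  structure(list(labels = labels, sizes = sizes,
                 largest_fraction = max(sizes) / nf,
                 representatives = reps, rmsd_matrix = M),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d frames in %d cluster(s); largest %.1f%%\n",
              length(x$labels), length(x$sizes), 100 * x$largest_fraction))
  invisible(x)
}

#' Select the most stable contiguous time window
#'
#' Scans all contiguous windows of the requested length (each starting at a
#' frame time) and returns the one maximising the fraction of its frames
#' that belong to the largest cluster. Ties are broken by the earliest
#' window.
#'
#' @param cluster_result A `cluster_result` from [cluster_frames()].
#' @param frame_times Per-frame times in nanoseconds (strictly increasing).
#' @param window_length_ns Window length in nanoseconds; must not exceed the
#'   trajectory time span.
#' @param min_fraction Threshold for the `stable` flag (default 0.5: the
#'   window should represent at least half of the sampled conformations).
#' @return List with `start_ns`, `end_ns`, `fraction`, `stable` (logical),
#'   `frames` (indices inside the window).
#' @export
select_stable_window <- function(cluster_result, frame_times,
                                 window_length_ns, min_fraction = 0.5) {
  stopifnot(inherits(cluster_result, "cluster_result"))
  nf <- length(cluster_result$labels)
  if (length(frame_times) != nf)
    stop("select_stable_window: frame_times length mismatch")
  if (any(diff(frame_times) <= 0))
    stop("select_stable_window: frame times must be strictly increasing")
  span <- frame_times[nf] - frame_times[1]
  if (window_length_ns > span + 1e-9)
    stop("select_stable_window: window longer than the trajectory span")
  in_largest <- cluster_result$labels == 1L
  best <- NULL
  for (s in seq_len(nf)) {
    t0 <- frame_times[s]
    t1 <- t0 + window_length_ns
    if (t1 > frame_times[nf] + 1e-9) break
    inside <- frame_times >= t0 - 1e-9 & frame_times <= t1 + 1e-9
    frac <- mean(in_largest[inside])
    if (is.null(best) || frac > best$fraction + 1e-12) {
      best <- list(start_ns = t0, end_ns = t1, fraction = frac,
                   frames = which(inside))
    }
  }
  best$stable <- best$fraction >= min_fraction
  best
}
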