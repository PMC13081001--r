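# Cartesian PCA, free-energy landscapes, minima, clustering, windows.

test_that("pca_fit recovers a planted direction against background noise", {
  set.seed(41)
  n <- 10
  base <- as.numeric(t(random_coords(n, sd = 5)))
  dir <- stats::rnorm(3 * n); dir <- dir / sqrt(sum(dir^2))
  nf <- 500
  X <- t(vapply(seq_len(nf), function(i)
    base + stats::rnorm(1, sd = 2.0) * dir + stats::rnorm(3 * n, sd = 0.05),
    numeric(3 * n)))
  tr <- trajectory(array(aperm(array(t(X), dim = c(3, n, nf)), c(3, 2, 1)),
                         dim = c(nf, n, 3)))
  model <- pca_fit(tr, superpose = FALSE)
  expect_gt(abs(sum(model$components[, 1] * dir)), 0.99)
  expect_gt(model$variance_fractions[1], 0.95)
  expect_equal(sum(model$variance_fractions), 1, tolerance = 1e-8)
})

test_that("pure isotropic noise spreads variance across components", {
  set.seed(42)
  n <- 10; nf <- 5000
  coords <- array(stats::rnorm(nf * n * 3), dim = c(nf, n, 3))
  model <- pca_fit(trajectory(coords), superpose = FALSE)
  expect_lt(max(model$variance_fractions),
            3 * mean(model$variance_fractions))
})

test_that("pca model is orthonormal and matches an SVD cross-check", {
  set.seed(43)
  n <- 8; nf <- 60
  coords <- array(stats::rnorm(nf * n * 3, sd = 2), dim = c(nf, n, 3))
  tr <- trajectory(coords)
  model <- pca_fit(tr, superpose = FALSE)
  V <- model$components
  expect_equal(crossprod(V), diag(ncol(V)), tolerance = 1e-8)
  ## prcomp is an independent (SVD) route to the same spectrum
  X <- t(vapply(seq_len(nf), function(i)
    as.numeric(t(coords[i, , ])), numeric(3 * n)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(length(model$eigenvalues), length(pc$sdev))
  expect_equal(model$eigenvalues[seq_len(k)], pc$sdev[seq_len(k)]^2,
               tolerance = 1e-6)
})

test_that("projections centre, reconstruct, and reproduce eigenvalues", {
  set.seed(44)
  n <- 6; nf <- 80
  coords <- array(stats::rnorm(nf * n * 3, sd = 1.5), dim = c(nf, n, 3))
  tr <- trajectory(coords)
  model <- pca_fit(tr, superpose = FALSE)

  mean_traj <- trajectory(array(matrix(model$mean_structure, n, 3,
                                       byrow = TRUE), dim = c(1, n, 3)))
  expect_equal(as.numeric(pca_project(model, mean_traj, 2,
                                      superpose = FALSE)),
               c(0, 0), tolerance = 1e-8)

  full <- pca_project(model, tr, ncol(model$components), superpose = FALSE)
  recon <- full %*% t(model$components)
  X <- t(vapply(seq_len(nf), function(i)
    as.numeric(t(coords[i, , ])), numeric(3 * n)))
  Xc <- sweep(X, 2, model$mean_structure)
  expect_equal(recon, Xc, tolerance = 1e-6, ignore_attr = TRUE)

  pvar <- apply(full, 2, stats::var)
  expect_equal(as.numeric(pvar), model$eigenvalues[seq_len(ncol(full))],
               tolerance = 1e-6)
  expect_error(pca_project(model, tr, 3 * n + 1), "exceeds")
})

test_that("projections are rigid-motion invariant when superposing", {
  g <- gen_multibasin_trajectory(n_frames = 60, seed = 45)
  tr <- g$trajectory
  model <- pca_fit(tr)
  p0 <- pca_project(model, tr, 2)
  set.seed(45)
  R <- random_rotation(); tvec <- c(5, -3, 11)
  nf <- n_frames(tr)
  moved <- tr
  for (i in seq_len(nf))
    moved$coords[i, , ] <- frame_coords(tr, i) %*% R +
      matrix(tvec, n_atoms(tr), 3, byrow = TRUE)
  p1 <- pca_project(model, moved, 2)
  expect_equal(p1, p0, tolerance = 1e-6)
})

test_that("fel_build reproduces analytic occupancy free energies", {
  kT <- kB * 313.15
  ## two point clusters 0.8/0.2, each inside one bin
  proj <- rbind(matrix(rep(c(0, 0), 800), ncol = 2, byrow = TRUE),
                matrix(rep(c(10, 10), 200), ncol = 2, byrow = TRUE))
  surf <- fel_build(proj, n_bins = 10, temperature_K = 313.15)
  occ <- sort(unique(surf$dG[surf$counts > 0]))
  expect_equal(occ[1], 0)
  expect_equal(occ[2], kT * log(4), tolerance = 1e-10)
  expect_equal(occ[2], 0.863, tolerance = 1e-3)

  ## uniform occupancy -> exactly zero everywhere occupied
  grid <- as.matrix(expand.grid(x = 1:5, y = 1:5))
  surf_u <- fel_build(grid, n_bins = 5)
  expect_true(all(surf_u$dG[surf_u$counts > 0] == 0))

  ## every empty bin carries exactly the cap
  expect_true(all(surf$dG[surf$counts == 0] == surf$cap))
  expect_equal(surf$cap, max(surf$dG[surf$counts > 0]) + kT)
  expect_error(fel_build(proj, temperature_K = -1), "positive")
})

test_that("find_minima locates planted wells and ranks by occupancy", {
  set.seed(46)
  ## four tight wells, centres far apart, occupancies 0.4/0.3/0.2/0.1
  centres <- rbind(c(0, 0), c(20, 0), c(0, 20), c(20, 20))
  occ <- c(0.4, 0.3, 0.2, 0.1)
  n <- 2000
  counts <- round(occ * n)
  pts <- do.call(rbind, lapply(1:4, function(k)
    matrix(stats::rnorm(2 * counts[k], sd = 0.3), ncol = 2) +
      matrix(centres[k, ], counts[k], 2, byrow = TRUE)))
  surf <- fel_build(pts, n_bins = 40)
  mins <- find_minima(surf)
  expect_equal(nrow(mins), 4)
  ## rank order matches occupancy order; centres recovered
  for (k in 1:4) {
    expect_lt(sqrt(sum((c(mins$pc1[k], mins$pc2[k]) - centres[k, ])^2)), 2)
    expect_equal(mins$occupancy[k], occ[k], tolerance = 0.02)
  }
  expect_equal(mins$dG[1], 0)
  expect_equal(mins$rank, 1:4)
})

test_that("find_minima handles single wells, flat and empty surfaces", {
  set.seed(47)
  well <- matrix(stats::rnorm(4000, sd = 0.5), ncol = 2)
  mins <- find_minima(fel_build(well, n_bins = 20))
  expect_equal(nrow(mins), 1)
  expect_lt(sqrt(mins$pc1^2 + mins$pc2^2), 0.5)

  ## perfectly flat occupied surface -> one minimum, first bin row-major
  grid <- as.matrix(expand.grid(x = 1:6, y = 1:6))
  flat <- find_minima(fel_build(grid, n_bins = 6))
  expect_equal(nrow(flat), 1)
  expect_equal(c(flat$bin1, flat$bin2), c(1, 1))
})

test_that("representative_frame equals exhaustive nearest-point search", {
  set.seed(48)
  proj <- matrix(stats::rnorm(400), ncol = 2)
  proj[17, ] <- c(0.5, -0.25)
  minimum <- list(pc1 = 0.5, pc2 = -0.25)
  expect_equal(representative_frame(proj, minimum), 17)

  d2 <- (proj[, 1] - 0.3)^2 + (proj[, 2] + 0.1)^2
  expect_equal(representative_frame(proj, list(pc1 = 0.3, pc2 = -0.1)),
               which.min(d2))

  ## two equidistant frames: the lower index wins
  tie <- rbind(c(1, 0), c(-1, 0), c(2, 0))
  expect_equal(representative_frame(tie, list(pc1 = 0, pc2 = 0)), 1)
})

test_that("clustering separates planted conformers with exact fractions", {
  g <- gen_multibasin_trajectory(occupancies = c(0.7, 0.3), n_frames = 60,
                                 jitter_sd = 0.05, seed = 49,
                                 assign = "exact")
  cl <- cluster_frames(g$trajectory,
                       select_atoms(g$topology, preset = "backbone"),
                       rmsd_cutoff = 2)
  expect_equal(length(cl$sizes), 2)
  expect_equal(sort(cl$sizes / 60, decreasing = TRUE), c(0.7, 0.3))
  expect_equal(cl$largest_fraction, 0.7)
  ## labels match the planted assignment up to renaming
  expect_equal(length(unique(paste(cl$labels, g$truth$assignment))), 2)

  ## all frames identical -> one cluster
  base <- frame_coords(g$trajectory, 1)
  static <- traj_from_frames(list(base, base, base))
  cls <- cluster_frames(static, rmsd_cutoff = 1)
  expect_equal(cls$largest_fraction, 1.0)

  ## cutoff above max pairwise rmsd -> single cluster
  all_one <- cluster_frames(g$trajectory,
                            select_atoms(g$topology, preset = "backbone"),
                            rmsd_cutoff = 100)
  expect_equal(length(all_one$sizes), 1)
  expect_error(cluster_frames(static, rmsd_cutoff = 0), "positive")
})

test_that("clustering is invariant under frame permutation", {
  g <- gen_multibasin_trajectory(occupancies = c(0.5, 0.5), n_frames = 30,
                                 jitter_sd = 0.1, seed = 50)
  tr <- g$trajectory
  cl1 <- cluster_frames(tr, rmsd_cutoff = 2)
  set.seed(50)
  perm <- sample(n_frames(tr))
  shuffled <- trajectory(tr$coords[perm, , , drop = FALSE])
  cl2 <- cluster_frames(shuffled, rmsd_cutoff = 2)
  ## partitions agree up to label renaming
  expect_equal(length(unique(paste(cl1$labels[perm], cl2$labels))),
               length(unique(cl1$labels)))
  expect_equal(sort(cl1$sizes), sort(cl2$sizes))
})

test_that("cluster representatives minimise mean RMSD to their members", {
  g <- gen_multibasin_trajectory(occupancies = c(0.6, 0.4), n_frames = 25,
                                 jitter_sd = 0.2, seed = 51)
  cl <- cluster_frames(g$trajectory, rmsd_cutoff = 2)
  M <- cl$rmsd_matrix
  for (k in seq_along(cl$sizes)) {
    members <- which(cl$labels == k)
    means <- rowMeans(M[members, members, drop = FALSE])
    expect_equal(cl$representatives[k], members[which.min(means)])
  }
})

test_that("stable-window selection recovers a constructed interval", {
  ## 101 frames at 0..1000 ns; conformer A only inside 200-500 ns and the
  ## largest of four planted conformers
  set.seed(52)
  refs <- lapply(1:4, function(k) random_coords(5, sd = 4))
  times <- seq(0, 1000, by = 10)
  inside <- times >= 200 & times <= 500         # 31 frames
  labels <- integer(length(times))
  labels[inside] <- 1
  labels[!inside] <- rep(2:4, length.out = sum(!inside))
  frames <- lapply(labels, function(l) refs[[l]])
  tr <- traj_from_frames(frames, times)
  cl <- cluster_frames(tr, rmsd_cutoff = 2)
  expect_equal(cl$labels[inside][1], 1L)   # planted A is the largest cluster
  w <- select_stable_window(cl, times, window_length_ns = 300)
  expect_equal(c(w$start_ns, w$end_ns), c(200, 500))
  expect_equal(w$fraction, 1.0)
  expect_true(w$stable)

  ## exhaustive-scan oracle over all start frames
  frac <- vapply(times, function(t0) {
    if (t0 + 300 > max(times)) return(NA_real_)
    mean(cl$labels[times >= t0 & times <= t0 + 300] == 1)
  }, numeric(1))
  expect_equal(w$fraction, max(frac, na.rm = TRUE))
  expect_equal(w$start_ns, times[which.max(frac)])

  ## uniform membership -> earliest window wins the tie
  uni <- cluster_frames(traj_from_frames(rep(list(refs[[1]]), 11),
                                         seq(0, 100, by = 10)),
                        rmsd_cutoff = 2)
  wu <- select_stable_window(uni, seq(0, 100, by = 10), 50)
  expect_equal(wu$start_ns, 0)
  expect_error(select_stable_window(uni, seq(0, 100, by = 10), 500),
               "longer")
})
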