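# Pocket volumes, hydrogen bonds, interaction fingerprints.

test_that("pocket volume matches the analytic hollow-shell cavity", {
  g <- gen_pocket_structure(inner_radius = 6, seed = 61)
  expect_equal(g$truth$volume, 4 / 3 * pi * 6^3, tolerance = 1e-12)
  pv <- pocket_volume(frame_coords(g$trajectory, 1),
                      atom_radii(g$topology), g$center,
                      search_radius = 9, grid_spacing = 0.5)
  expect_false(pv$seed_blocked)
  expect_false(pv$leak)
  expect_equal(pv$volume, g$truth$volume, tolerance = 0.05)
  expect_equal(pv$volume, pv$n_points * 0.5^3)
})

test_that("pocket volume converges under grid refinement", {
  g <- gen_pocket_structure(inner_radius = 6, seed = 62)
  fr <- frame_coords(g$trajectory, 1)
  r <- atom_radii(g$topology)
  v1 <- pocket_volume(fr, r, g$center, 9, grid_spacing = 1.0)$volume
  v05 <- pocket_volume(fr, r, g$center, 9, grid_spacing = 0.5)$volume
  expect_lt(abs(v05 - v1) / v05, 0.05)
})

test_that("pocket volume is invariant under global rigid motion", {
  g <- gen_pocket_structure(inner_radius = 5, seed = 63)
  fr <- frame_coords(g$trajectory, 1)
  r <- atom_radii(g$topology)
  v0 <- pocket_volume(fr, r, g$center, 8, grid_spacing = 0.5)$volume
  set.seed(63)
  R <- random_rotation(); tvec <- c(12, -7, 4)
  moved <- fr %*% R + matrix(tvec, nrow(fr), 3, byrow = TRUE)
  seed2 <- as.numeric(g$center %*% R) + tvec
  v1 <- pocket_volume(moved, r, seed2, 8, grid_spacing = 0.5)$volume
  expect_equal(v1, v0, tolerance = 0.05)
})

test_that("a blocked seed yields zero volume with a diagnostic", {
  ## solid block of atoms; seed right next to an atom centre
  grid <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0:4)) * 1.5
  pv <- pocket_volume(grid, rep(1.5, nrow(grid)), c(3, 3, 3),
                      search_radius = 5, grid_spacing = 0.5)
  expect_true(pv$seed_blocked)
  expect_equal(pv$volume, 0)
})

test_that("hydrogen-bond detection applies distance and angle criteria", {
  ## linear D-H...A at 2.9 A, angle 170 deg
  mk <- function(da, angle_deg) {
    h <- c(1.0, 0, 0)
    d <- c(0, 0, 0)
    phi <- (180 - angle_deg) * pi / 180
    a <- h + (da - 1.0) * c(cos(phi), sin(phi), 0)
    rbind(d, h, a)
  }
  donors <- data.frame(donor = 1L, hydrogen = 2L)
  hit <- detect_hbonds(mk(2.9, 170), donors, 3L)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$distance, 2.9, tolerance = 0.15)
  expect_gt(hit$angle, 160)

  expect_equal(nrow(detect_hbonds(mk(3.8, 170), donors, 3L)), 0)
  expect_equal(nrow(detect_hbonds(mk(2.9, 100), donors, 3L)), 0)

  ## without hydrogen the distance criterion alone applies
  no_h <- detect_hbonds(mk(2.9, 100), 1L, 3L)
  expect_equal(nrow(no_h), 1)
  expect_true(is.na(no_h$angle))
  expect_error(detect_hbonds(mk(2.9, 170), donors, 99L), "range")
})

test_that("planted hydrogen-bond occupancies are recovered exactly", {
  contacts <- data.frame(resid = 121L, class = "hbond_donor",
                         occupancy = 0.5)
  g <- gen_toy_complex(contacts, n_frames = 200, seed = 64)
  occ <- hbond_occupancy(g$trajectory, g$topology, 121,
                         g$ligand_selection, replicate_bounds = c(1L, 101L))
  expect_equal(occ$mean, 0.5)
  expect_equal(occ$sd, 0)           # interleaved pattern: equal per replicate
  expect_equal(occ$n_replicates, 2)

  persistent <- gen_toy_complex(
    data.frame(resid = 120L, class = "hbond_acceptor", occupancy = 1),
    n_frames = 50, seed = 65)
  occ2 <- hbond_occupancy(persistent$trajectory, persistent$topology, 120,
                          persistent$ligand_selection)
  expect_equal(occ2$mean, 1.0)
  expect_equal(occ2$sd, 0)
  expect_error(
    hbond_occupancy(g$trajectory, g$topology, 777, g$ligand_selection),
    "777")
})

test_that("hbond_occupancy equals a frame-by-frame composition oracle", {
  contacts <- data.frame(resid = 43L, class = "hbond_donor",
                         occupancy = 0.3)
  g <- gen_toy_complex(contacts, n_frames = 40, seed = 66)
  occ <- hbond_occupancy(g$trajectory, g$topology, 43, g$ligand_selection)
  ## oracle: residue backbone N is the only donor; ligand O atoms accept
  at <- g$topology$atoms
  donor <- which(at$resid == 43 & at$name == "N")
  lig_O <- intersect(g$ligand_selection, which(at$element == "O"))
  counts <- vapply(seq_len(n_frames(g$trajectory)), function(i) {
    fr <- frame_coords(g$trajectory, i)
    sum(vapply(lig_O, function(a)
      sqrt(sum((fr[donor, ] - fr[a, ])^2)) <= 3.5, logical(1)))
  }, numeric(1))
  expect_equal(occ$mean, mean(counts))
})

test_that("fingerprints recover planted contacts of every class", {
  contacts <- data.frame(
    resid = c(120L, 121L, 45L, 185L),
    class = c("hydrophobic", "hbond_donor", "hbond_acceptor", "vdw_contact"),
    occupancy = c(0.75, 0.5, 0.25, 1.0))
  g <- gen_toy_complex(contacts, n_frames = 80, seed = 67)
  fp <- interaction_fingerprint(g$trajectory, g$topology,
                                g$ligand_selection)
  cell <- function(res, cls) fp[[cls]][match(res, fp$resid)]
  expect_equal(cell(120, "hydrophobic"), 0.75)
  expect_equal(cell(121, "hbond_donor"), 0.5)
  expect_equal(cell(45, "hbond_acceptor"), 0.25)
  expect_equal(cell(185, "vdw_contact"), 1.0)
  expect_true(all(as.matrix(fp[, 4:7]) >= 0 & as.matrix(fp[, 4:7]) <= 1))
})

test_that("an absent ligand produces an empty fingerprint", {
  g <- gen_toy_complex(data.frame(), n_frames = 10, seed = 68)
  fp <- interaction_fingerprint(g$trajectory, g$topology,
                                g$ligand_selection)
  expect_equal(nrow(fp), 0)   # all-zero rows are omitted
})

test_that("fingerprint occupancies shrink monotonically with cutoffs", {
  contacts <- data.frame(
    resid = c(120L, 185L), class = c("hydrophobic", "hydrophobic"),
    occupancy = c(0.8, 0.6), distance = c(4.2, 3.8))
  g <- gen_toy_complex(contacts, n_frames = 50, seed = 69)
  loose <- interaction_fingerprint(g$trajectory, g$topology,
                                   g$ligand_selection)
  tight <- interaction_fingerprint(
    g$trajectory, g$topology, g$ligand_selection,
    interaction_criteria(hbond_dist = 3.0, hydrophobic_dist = 4.0,
                         vdw_dist = 3.5))
  ## the 4.2 A contact is seen at the 4.5 A default and lost at 4.0 A
  expect_equal(loose$hydrophobic[match(120, loose$resid)], 0.8)
  expect_false(120 %in% tight$resid && {
    v <- tight$hydrophobic[match(120, tight$resid)]; !is.na(v) && v > 0
  })
  ## every occupancy is non-increasing under tighter criteria
  for (res in tight$resid) {
    for (cls in c("hydrophobic", "hbond_donor", "hbond_acceptor",
                  "vdw_contact")) {
      lv <- loose[[cls]][match(res, loose$resid)]
      if (is.na(lv)) lv <- 0
      expect_lte(tight[[cls]][match(res, tight$resid)], lv + 1e-12)
    }
  }
  expect_error(
    interaction_fingerprint(g$trajectory, g$topology,
                            seq_len(n_atoms(g$topology))),
    "proper subset")
})

test_that("fingerprint and hbond results do not depend on frame order", {
  contacts <- data.frame(resid = 121L, class = "hbond_donor",
                         occupancy = 0.4)
  g <- gen_toy_complex(contacts, n_frames = 20, seed = 70)
  fp1 <- interaction_fingerprint(g$trajectory, g$topology,
                                 g$ligand_selection)
  set.seed(70)
  perm <- sample(20)
  shuffled <- trajectory(g$trajectory$coords[perm, , , drop = FALSE])
  fp2 <- interaction_fingerprint(shuffled, g$topology, g$ligand_selection)
  expect_equal(fp1, fp2)
})
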