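# SIE scoring, calibration and the physical component terms.

test_that("sie_score reproduces published component/affinity rows", {
  coeffs <- sie_coefficients(alpha = 0.1048, C = -2.89)
  expect_equal(round(sie_score(c(E_vdw = -54.84, E_coul = -6.20,
                                 E_rf = 11.64, E_cav = -10.53), coeffs), 2),
               -9.17)
  expect_equal(round(sie_score(c(E_vdw = -40.19, E_coul = 29.32,
                                 E_rf = -23.19, E_cav = -8.03), coeffs), 2),
               -7.30)
  ## all-zero components return the constant offset
  expect_equal(sie_score(c(E_vdw = 0, E_coul = 0, E_rf = 0, E_cav = 0),
                         coeffs), -2.89)
})

test_that("sie_score is affine in the components", {
  coeffs <- sie_coefficients()
  comp <- c(E_vdw = -50, E_coul = -10, E_rf = 15, E_cav = -9)
  base <- sie_score(comp, coeffs) - coeffs$C
  for (lam in c(0.5, 2, -1))
    expect_equal(sie_score(lam * comp, coeffs) - coeffs$C, lam * base,
                 tolerance = 1e-12)
})

test_that("sie_calibrate recovers exact coefficients and flags outliers", {
  ## two exact rows -> machine precision
  two <- data.frame(E_vdw = c(-50, -40), E_coul = c(-5, 10),
                    E_rf = c(10, -5), E_cav = c(-10, -8))
  two$dG <- 0.11 * rowSums(two) - 3.5
  cal <- sie_calibrate(two)
  expect_equal(cal$coefficients$alpha, 0.11, tolerance = 1e-12)
  expect_equal(cal$coefficients$C, -3.5, tolerance = 1e-12)

  ## the five mutually consistent published rows
  five <- consistent_sie_rows()
  cal5 <- sie_calibrate(five)
  expect_equal(cal5$coefficients$alpha, 0.1048, tolerance = 0.002 / 0.1048)
  expect_equal(cal5$coefficients$C, -2.89, tolerance = 0.05 / 2.89)
  expect_lt(max(abs(cal5$residuals)), 0.01)
  expect_false(any(cal5$outliers))

  ## adding the inconsistent row flags it - and only it
  six <- read_energy_table(sie_table_path())
  cal6 <- sie_calibrate(six)
  flagged <- which(cal6$outliers)
  expect_equal(six$system[flagged], "MrCut3")
  expect_equal(six$polymer[flagged], "PES")
  expect_equal(abs(cal6$residuals[flagged]), 4, tolerance = 0.2)

  ## rank-deficient design
  flat <- data.frame(E_vdw = c(-10, -10), E_coul = c(0, 0),
                     E_rf = c(0, 0), E_cav = c(0, 0), dG = c(-1, -2))
  expect_error(sie_calibrate(flat), "rank")
})

test_that("Lennard-Jones and Coulomb pair sums match closed forms", {
  ## two neutral atoms at the combined rmin sit at the LJ minimum
  top2 <- toy_topology(n_res = 2)
  top2$charges <- c(0, 0)
  top2$lj <- data.frame(epsilon = c(0.2, 0.45), rmin_half = c(1.9, 1.7))
  coords <- rbind(c(0, 0, 0), c(3.6, 0, 0))   # rmin = 1.9 + 1.7
  e <- lj_coulomb_interaction(coords, top2, 2L)
  expect_equal(unname(e["E_vdw"]), -sqrt(0.2 * 0.45), tolerance = 1e-12)
  expect_equal(unname(e["E_coul"]), 0)

  ## unit charges at ke/100 angstrom give exactly -100 kcal/mol
  top2$charges <- c(1, -1)
  top2$lj <- data.frame(epsilon = c(0, 0), rmin_half = c(1, 1))
  coords <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  e2 <- lj_coulomb_interaction(coords, top2, 2L, eps_in = 1)
  expect_equal(unname(e2["E_coul"]), -100, tolerance = 1e-6)
})

test_that("pair energies equal an independent double-loop oracle", {
  set.seed(81)
  n <- 5
  top <- toy_topology(n_res = n)
  top$charges <- stats::runif(n, -0.8, 0.8)
  top$lj <- data.frame(epsilon = stats::runif(n, 0.05, 0.3),
                       rmin_half = stats::runif(n, 1.2, 2.0))
  coords <- random_coords(n, sd = 4)
  lig <- c(4L, 5L)
  e <- lj_coulomb_interaction(coords, top, lig, eps_in = 2)
  vdw <- 0; coul <- 0
  for (i in 1:3) for (j in lig) {
    r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    eps <- sqrt(top$lj$epsilon[i] * top$lj$epsilon[j])
    rm <- top$lj$rmin_half[i] + top$lj$rmin_half[j]
    vdw <- vdw + eps * ((rm / r)^12 - 2 * (rm / r)^6)
    coul <- coul + 332.0636 * top$charges[i] * top$charges[j] / (2 * r)
  }
  expect_equal(unname(e["E_vdw"]), vdw, tolerance = 1e-10)
  expect_equal(unname(e["E_coul"]), coul, tolerance = 1e-10)
})

test_that("generalized-Born energies match the Born closed form", {
  ## single ion: G = -1/2 (1 - 1/78.5) ke q^2 / a
  g <- mdscape:::gb_energy(matrix(0, 1, 3), charges = 1, born = 2,
                           eps_in = 1, eps_out = 78.5)
  expect_equal(g, -0.5 * (1 - 1 / 78.5) * 332.0636 / 2, tolerance = 1e-6)

  ## two-atom system against a hand-evaluated pairwise formula
  coords <- rbind(c(0, 0, 0), c(3, 0, 0))
  q <- c(0.5, -0.4); a <- c(1.6, 2.1)
  got <- mdscape:::gb_energy(coords, q, a, 2.25, 78.5)
  pref <- -0.5 * 332.0636 * (1 / 2.25 - 1 / 78.5)
  f12 <- sqrt(9 + a[1] * a[2] * exp(-9 / (4 * a[1] * a[2])))
  want <- pref * (q[1]^2 / a[1] + q[2]^2 / a[2] + 2 * q[1] * q[2] / f12)
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("reaction field vanishes at infinite separation and with equal
           dielectrics", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(1e5, 0, 0), c(1e5 + 2, 0, 0))
  q <- c(0.3, -0.2, 0.4, -0.5)
  a <- rep(1.8, 4)
  e_far <- gb_reaction_field(coords, q, a, 1, 78.5,
                             ligand_selection = c(3L, 4L))
  expect_lt(abs(e_far), 1e-4)   # cross terms vanish, self terms cancel

  near <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0), c(6, 0, 0))
  e_near <- gb_reaction_field(near, q, a, 1, 78.5,
                              ligand_selection = c(3L, 4L))
  expect_gt(abs(e_near), 0.1)
  ## eps_out -> eps_in: the reaction field goes to zero monotonically
  eps_seq <- c(80, 20, 5, 1.5, 1.0001)
  vals <- vapply(eps_seq, function(eo)
    abs(gb_reaction_field(near, q, a, 1, eo, ligand_selection = c(3L, 4L))),
    numeric(1))
  expect_true(all(diff(vals) < 1e-12))
  expect_lt(vals[length(vals)], 1e-3)
  expect_error(gb_reaction_field(near, q, c(1, 1, -1, 1), 1, 78.5, c(3L, 4L)),
               "positive")
})

test_that("Shrake-Rupley areas match analytic spheres", {
  ## isolated atom: full probe-inflated sphere
  a1 <- sasa_shrake_rupley(matrix(0, 1, 3), 1.6, probe_radius = 1.4,
                           n_sphere_points = 960)
  expect_equal(a1, 4 * pi * 3^2, tolerance = 0.005)

  ## two distant atoms keep their isolated areas
  a2 <- sasa_shrake_rupley(rbind(c(0, 0, 0), c(100, 0, 0)), c(1.6, 1.6))
  expect_equal(a2, rep(4 * pi * 3^2, 2), tolerance = 0.005)

  ## an atom enclosed in a tight shell is fully buried
  k <- 1:200
  z <- (2 * k - 1) / 200 - 1
  th <- k * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  shell <- 3.0 * cbind(rho * cos(th), rho * sin(th), z)
  coords <- rbind(c(0, 0, 0), shell)
  a3 <- sasa_shrake_rupley(coords, rep(1.5, nrow(coords)))
  expect_equal(a3[1], 0)
  expect_error(sasa_shrake_rupley(matrix(0, 1, 3), 1.5, probe_radius = -1),
               ">= 0")
})

test_that("the cavity term is linear in gamma and area burial", {
  expect_equal(cavity_term(100, 60, 40, gamma = 0.0129), 0)
  expect_equal(cavity_term(1000, 1000, 816.3, gamma = 0.0129),
               -10.53, tolerance = 1e-3)
  expect_equal(cavity_term(50, 60, 40, gamma = 0.0258),
               2 * cavity_term(50, 60, 40, gamma = 0.0129))
  expect_error(cavity_term(-1, 0, 0), ">= 0")
})

test_that("trajectory SIE equals sie_score on mean components", {
  set.seed(82)
  n <- 6
  top <- toy_topology(n_res = n)
  top$charges <- stats::runif(n, -0.5, 0.5)
  top$lj <- data.frame(epsilon = rep(0.15, n), rmin_half = rep(1.7, n))
  base <- random_coords(n, sd = 3)
  ## static complex: constant per-frame dG, zero spread
  static <- traj_from_frames(list(base, base, base))
  res <- sie_from_trajectory(static, top, c(5L, 6L),
                             n_sphere_points = 240)
  expect_equal(stats::sd(res$per_frame$dG), 0)
  expect_equal(unname(res$component_sds), rep(0, 4), ignore_attr = TRUE)
  expect_equal(res$dG,
               sie_score(as.list(res$component_means), sie_coefficients()),
               tolerance = 1e-10)

  ## moving complex: pooled means recombine exactly through sie_score
  frames <- lapply(1:4, function(i)
    base + matrix(stats::rnorm(3 * n, sd = 0.2), n, 3))
  res2 <- sie_from_trajectory(traj_from_frames(frames), top, c(5L, 6L),
                              replicate_bounds = c(1L, 3L),
                              n_sphere_points = 240)
  expect_equal(res2$n_replicates, 2)
  expect_equal(res2$dG,
               sie_score(as.list(res2$component_means), sie_coefficients()),
               tolerance = 1e-10)
  expect_error(
    sie_from_trajectory(traj_from_frames(frames, times = 1:4), top,
                        c(5L, 6L), window = c(100, 200)),
    "empty window")
})
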