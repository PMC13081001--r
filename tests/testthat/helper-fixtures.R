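## Shared fixtures and independent oracles for the test suite. Everything is
## built in code; no binary fixtures.

## Minimal topology: n residues x 1 CA atom unless atom names given.
toy_topology <- function(n_res = 4,
                         names = rep("CA", n_res),
                         elements = rep("C", n_res),
                         resid = seq_len(n_res),
                         resname = rep("ALA", n_res),
                         chain = "A") {
  topology(data.frame(
    serial = seq_along(names), name = names, element = elements,
    resname = resname, resid = as.integer(resid), chain = chain,
    stringsAsFactors = FALSE))
}

## One-residue topology with a full backbone plus CB.
backbone_topology <- function() {
  toy_topology(n_res = 5,
               names = c("N", "CA", "C", "O", "CB"),
               elements = c("N", "C", "C", "O", "C"),
               resid = rep(1L, 5), resname = rep("ALA", 5))
}

## Random non-degenerate coordinates.
random_coords <- function(n, sd = 3) matrix(stats::rnorm(3 * n, sd = sd), n, 3)

## Rotation matrix about z by `theta` radians.
rot_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta), cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

## Random proper rotation (QR of a Gaussian matrix, det forced to +1).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## Independent brute-force superposition oracle: centre both sets, then
## minimise RMSD over rotations parameterised by Euler angles, with a grid
## of starting points refined by Nelder-Mead. Deliberately shares no code
## with kabsch_superpose.
brute_force_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  euler_rot <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cc <- cos(p[3]); sc <- sin(p[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(p) sqrt(mean(rowSums((A %*% euler_rot(p) - B)^2)))
  best <- Inf
  starts <- expand.grid(a = seq(0, 2 * pi, length.out = 5)[-5],
                        b = seq(0, pi, length.out = 4),
                        c = seq(0, 2 * pi, length.out = 5)[-5])
  for (s in seq_len(nrow(starts))) {
    r <- stats::optim(as.numeric(starts[s, ]), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
    if (r$value < best) best <- r$value
  }
  best
}

## Build a trajectory directly from a list of per-frame coordinate matrices.
traj_from_frames <- function(frames, times = NULL) {
  coords <- array(NA_real_, dim = c(length(frames), nrow(frames[[1]]), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  trajectory(coords, times)
}

## Path to the printed SIE component table shipped with the package.
sie_table_path <- function() {
  system.file("extdata", "sie_table2_components.csv", package = "mdscape")
}

## The five mutually consistent rows of the printed component table.
consistent_sie_rows <- function() {
  tab <- read_energy_table(sie_table_path())
  tab[!(tab$system == "MrCut3" & tab$polymer == "PES"), ]
}

kB <- 0.0019872041
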