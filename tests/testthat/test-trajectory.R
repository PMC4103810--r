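make_static_traj <- function(n_res = 10, n_frames = 5) {
  base <- cbind(3.8 * seq_len(n_res), 0, sin(seq_len(n_res)))
  arr <- array(rep(base, n_frames), dim = c(n_res, 3, n_frames))
  trajectory(arr, data.frame(residue_index = seq_len(n_res),
                             residue_name = "GLY", atom_name = "CA",
                             element = "C", chain = "A"))
}

test_that("superposition removes rigid transforms exactly", {
  set.seed(21)
  A <- matrix(rnorm(36), 12, 3)
  expect_equal(superpose(A, A)$rmsd, 0, tolerance = 1e-12)
  R <- rand_rotation()
  B <- sweep(A %*% t(R), 2, c(5, -3, 11), "+")
  sp <- superpose(A, B)
  expect_equal(sp$rmsd, 0, tolerance = 1e-9)
  expect_equal(sp$fitted, A, tolerance = 1e-9)
})

test_that("superposition RMSD equals the quaternion-method oracle", {
  set.seed(22)
  for (i in 1:50) {
    A <- matrix(rnorm(45), 15, 3)
    B <- A + matrix(rnorm(45, 0, 0.4), 15, 3)
    B <- sweep(B %*% t(rand_rotation()), 2, rnorm(3, 0, 10), "+")
    expect_equal(superpose(A, B)$rmsd, quaternion_rmsd(A, B), tolerance = 1e-9)
  }
})

test_that("superposition rejects degenerate geometry", {
  A <- matrix(rnorm(6), 2, 3)
  expect_error(superpose(A, A), ">= 3")
  L <- cbind(1:5, 2 * (1:5), -1 * (1:5))   # collinear points
  expect_error(superpose(L, L + 0.01), "collinear")
})

test_that("RMSD series: static trajectories are zero, displacement is measured", {
  tr <- make_static_traj()
  expect_equal(rmsd_series(tr), rep(0, 5), tolerance = 1e-9)
  expect_error(rmsd_series(tr, ref_frame = 9), "out of range")
  # two frames, one atom moved; RMSD after alignment from the quaternion oracle
  arr <- tr$coords[, , 1:2]
  arr[4, 2, 2] <- arr[4, 2, 2] + 1.0
  tr2 <- trajectory(arr, tr$atoms)
  expect_equal(rmsd_series(tr2)[2],
               quaternion_rmsd(arr[, , 1], arr[, , 2]), tolerance = 1e-9)
  expect_equal(rmsd_series(tr2)[1], 0, tolerance = 1e-12)
})

test_that("geometric results are invariant under global rigid motion of the input", {
  tr <- make_toy_trajectory(40, rep(c(0.3, 0.8), 15), seed = 31)
  r0 <- rmsd_series(tr); f0 <- rmsf(tr)
  set.seed(32)
  R <- rand_rotation(); tvec <- c(12, -7, 3)
  arr <- tr$coords
  for (f in seq_len(dim(arr)[3]))
    arr[, , f] <- sweep(arr[, , f] %*% t(R), 2, tvec, "+")
  tr2 <- trajectory(arr, tr$atoms)
  expect_equal(rmsd_series(tr2), r0, tolerance = 1e-9)
  expect_equal(rmsf(tr2)$rmsf, f0$rmsf, tolerance = 1e-9)
})

test_that("RMSF: zeros for static input, closed form for a two-frame oscillation", {
  expect_equal(rmsf(make_static_traj())$rmsf, rep(0, 10), tolerance = 1e-9)
  expect_error(rmsf(trajectory(array(0, c(4, 3, 1)),
                               data.frame(residue_index = 1:4,
                                          atom_name = "CA", element = "C",
                                          residue_name = "GLY", chain = "A"))),
               "2 frames")
  # one residue displaced +-a along y, others fixed: two-frame RMSF = a
  a <- 0.7
  base <- cbind(5 * (1:12), 0, cos(1:12))
  arr <- array(rep(base, 2), dim = c(12, 3, 2))
  arr[6, 2, 1] <- arr[6, 2, 1] + a
  arr[6, 2, 2] <- arr[6, 2, 2] - a
  tr <- trajectory(arr, data.frame(residue_index = 1:12, residue_name = "GLY",
                                   atom_name = "CA", element = "C", chain = "A"))
  rf <- rmsf(tr, align = FALSE)
  expect_equal(rf$rmsf[6], a, tolerance = 1e-12)
  expect_equal(rf$rmsf[-6], rep(0, 11), tolerance = 1e-12)
})

test_that("RMSF recovers an imposed per-residue fluctuation profile", {
  profile <- 0.4 + 0.6 * sin(seq(0, pi, length.out = 60))^2
  tr <- make_toy_trajectory(500, profile, seed = 33)
  rf <- rmsf(tr)
  expect_lt(max(abs(rf$rmsf / profile - 1)), 0.10)
})

test_that("snapshot PCA: 1-D motion, trace identity, orthonormality, oracle", {
  # motion confined to one coordinate -> PC1 captures everything
  base <- cbind(3.8 * (1:10), 0, 0)
  arr <- array(rep(base, 20), dim = c(10, 3, 20))
  arr[5, 1, ] <- arr[5, 1, ] + 2 * sin(seq(0, 3, length.out = 20))
  tr <- trajectory(arr, data.frame(residue_index = 1:10, residue_name = "GLY",
                                   atom_name = "CA", element = "C", chain = "A"))
  p <- pca_snapshots(tr, align = FALSE)
  expect_gte(p$eigenvalues[1] / sum(p$eigenvalues), 0.999)
  # general case: trace identity + orthonormal components on aligned coords
  tr2 <- make_toy_trajectory(60, rep(c(0.4, 0.9), 10), seed = 34)
  tr2a <- align_trajectory(tr2)
  p2 <- pca_snapshots(tr2, align = TRUE)
  M <- t(apply(tr2a$coords, 3, function(m) as.numeric(t(m))))
  expect_equal(sum(p2$eigenvalues), sum(diag(cov(M))), tolerance = 1e-9)
  G <- crossprod(p2$components)
  expect_equal(G, diag(ncol(G)), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(diff(p2$eigenvalues) <= 1e-12))
  # projections match an independent SVD-route oracle (up to column signs)
  sv <- svd(sweep(M, 2, colMeans(M)))
  k <- min(5, ncol(sv$u))
  for (j in seq_len(k)) {
    pr <- sv$u[, j] * sv$d[j]
    expect_equal(abs(p2$projections[, j]), abs(pr), tolerance = 1e-8)
  }
  # retained components reproduce the centered coordinates
  rec <- p2$projections %*% t(p2$components)
  expect_equal(rec, sweep(M, 2, colMeans(M)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(pca_snapshots(make_static_traj(10, 2)), "3 frames")
})

test_that("dropped residues are excluded from the PCA", {
  tr <- make_toy_trajectory(30, rep(0.5, 20), seed = 35)
  p <- pca_snapshots(tr, drop_residues = 17:20)
  expect_equal(length(p$atom_index), 16)
  expect_false(any(tr$atoms$residue_index[p$atom_index] %in% 17:20))
})

test_that("multi-model PDB files round-trip through the trajectory container", {
  tr <- make_toy_trajectory(4, rep(0.5, 8), seed = 36)
  f <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(tr, f)
  tr2 <- read_pdb_trajectory(f)
  expect_equal(tr2$coords, round(tr$coords, 3), tolerance = 1e-9)
  expect_equal(tr2$atoms$residue_index, tr$atoms$residue_index)
  # mismatched models are rejected with the offending model number
  lines <- readLines(f)
  bad <- tempfile(fileext = ".pdb")
  writeLines(lines[-grep("^ATOM", lines)[9]], bad)  # drop an atom in model 2
  expect_error(read_pdb_trajectory(bad), "model 2")
})

test_that("PDB reading agrees with the bio3d reference reader", {
  tr <- make_toy_trajectory(3, rep(0.6, 10), seed = 37)
  f <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(tr, f)
  ref <- bio3d::read.pdb(f, multi = TRUE)
  expect_equal(dim(ref$xyz)[1], 3)
  mine <- read_pdb_trajectory(f)
  for (k in 1:3)
    expect_equal(as.numeric(t(mine$coords[, , k])), as.numeric(ref$xyz[k, ]),
                 tolerance = 1e-9)
})

test_that("selection strings resolve chain and residue ranges", {
  atoms <- data.frame(residue_index = rep(1:5, 2), residue_name = "GLY",
                      atom_name = "CA", element = "C",
                      chain = rep(c("A", "B"), each = 5))
  expect_equal(resolve_selection(atoms, "A:2-4"), 2:4)
  expect_equal(resolve_selection(atoms, "B:1-5"), 6:10)
  expect_error(resolve_selection(atoms, "A;1-5"), "bad selection")
})
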