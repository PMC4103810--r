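one_atom <- function() data.frame(residue_index = 1L, residue_name = "ALA",
                                  atom_name = "CA", element = "C", chain = "A")

test_that("single-atom SASA equals the analytic sphere area", {
  s <- sasa(matrix(0, 1, 3), one_atom(), probe_radius = 1.4, n_points = 960)
  expect_equal(s$sasa, 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("far-apart atoms contribute independent areas; enclosed atoms none", {
  atoms <- rbind(one_atom(), transform(one_atom(), residue_index = 2L))
  coords <- rbind(c(0, 0, 0), c(100, 0, 0))
  s <- sasa(coords, atoms)
  expect_equal(sum(s$sasa), 2 * 4 * pi * 3.1^2, tolerance = 0.01)
  # atom caged tightly inside an icosahedral shell is fully occluded
  tc <- make_toy_complex(n_res = 1, buried = 1, seed = 2)
  sc <- sasa(tc$complex_coords, tc$complex_atoms)
  expect_lt(sc$sasa[sc$residue_index == 1], 1e-6)
})

test_that("SASA converges in the sphere-point count", {
  # chain of 8 residues x 5 atoms (CA plus side-chain beads); per-residue
  # areas aggregate several atoms, as in real structures
  set.seed(41)
  res <- rep(1:8, each = 5)
  base <- cbind(3.8 * res, 0, 0)
  coords <- base + matrix(rnorm(length(res) * 3, sd = 1.5), ncol = 3)
  atoms <- data.frame(residue_index = res, residue_name = "ALA",
                      atom_name = rep(c("CA", "CB", "CG", "CD", "CE"), 8),
                      element = "C", chain = "A")
  s1 <- sasa(coords, atoms, n_points = 960)
  s2 <- sasa(coords, atoms, n_points = 1920)
  rel <- abs(s1$sasa - s2$sasa) / s2$sasa
  expect_lt(max(rel), 0.01)
  # deterministic given n_points
  expect_identical(s1$sasa, sasa(coords, atoms, n_points = 960)$sasa)
})

test_that("atoms without an assigned radius are reported by name", {
  atoms <- one_atom(); atoms$element <- "ZZ"; atoms$atom_name <- "QQ1"
  expect_error(sasa(matrix(0, 1, 3), atoms), "QQ1")
})

test_that("delta-SASA isolates interface burial", {
  tc <- make_toy_complex(n_res = 6, buried = c(2, 5), seed = 1)
  d <- delta_sasa(tc$complex_coords, tc$complex_atoms, ligand = tc$ligand_index)
  # buried residues lose their whole isolated surface
  expect_equal(d$delta_sasa[tc$buried], d$sasa_free[tc$buried], tolerance = 1e-6)
  expect_true(all(d$sasa_free[tc$buried] > 70))
  # exposed residues lose (almost) nothing; never negative beyond sampling noise
  expect_lt(max(abs(d$delta_sasa[-tc$buried])), 0.5)
  expect_gt(min(d$delta_sasa), -0.5)
  # peptide pulled 50 A out of the groove: no burial anywhere
  far <- make_toy_complex(n_res = 6, buried = c(2, 5), seed = 1,
                          offset = c(0, 0, 50))
  dfar <- delta_sasa(far$complex_coords, far$complex_atoms,
                     ligand = far$ligand_index)
  expect_lt(max(abs(dfar$delta_sasa)), 0.5)
  expect_error(delta_sasa(tc$complex_coords, tc$complex_atoms,
                          ligand = integer(0)), "empty")
})

test_that("per-residue SASA agrees with an independent engine within 2%", {
  tc <- make_toy_complex(n_res = 6, buried = c(2, 5), seed = 1)
  tr <- trajectory(array(tc$complex_coords,
                         dim = c(nrow(tc$complex_coords), 3, 1)),
                   tc$complex_atoms)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_trajectory(tr, pdb)
  out <- tempfile(fileext = ".txt")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, mdtraj, numpy as np",
    sprintf("t = mdtraj.load(%s)", shQuote(pdb)),
    "s = mdtraj.shrake_rupley(t, probe_radius=0.14, n_sphere_points=960, mode='residue')",
    sprintf("np.savetxt(%s, s[0]*100.0)", shQuote(out))), script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  ref <- scan(out, quiet = TRUE)
  mine <- sasa(tc$complex_coords, tc$complex_atoms)$sasa
  # compare sorted profiles (residue bookkeeping differs between engines)
  m <- sort(mine, decreasing = TRUE); r <- sort(ref, decreasing = TRUE)
  nz <- r > 1
  expect_lt(max(abs(m[nz] - r[nz]) / r[nz]), 0.02)
})

test_that("anchor/tether classification follows the burial threshold and evidence", {
  d <- data.frame(residue_index = 1:4,
                  delta_sasa = c(130, 32.7, 70.0, 5))
  ev <- data.frame(residue_index = 2, partner = "backbone Asp232")
  at <- classify_anchor(d, ev)
  expect_equal(as.character(at$class), c("anchor", "tether", "other", "other"))
  expect_match(at$evidence[2], "Asp232")
  # threshold is a strict inequality: 70.0 exactly is not an anchor
  at2 <- classify_anchor(d, ev, threshold = 70)
  expect_equal(as.character(at2$class[3]), "other")
  # evidence on an anchor residue does not demote it
  ev2 <- rbind(ev, data.frame(residue_index = 1, partner = "Gln131"))
  expect_equal(as.character(classify_anchor(d, ev2)$class[1]), "anchor")
})

test_that("construction-guaranteed burial classifies as anchor", {
  tc <- make_toy_complex(n_res = 6, buried = c(2, 5), seed = 3)
  d <- delta_sasa(tc$complex_coords, tc$complex_atoms, ligand = tc$ligand_index)
  at <- classify_anchor(data.frame(residue_index = d$residue_index,
                                   delta_sasa = d$delta_sasa))
  expect_equal(as.character(at$class[tc$buried]), rep("anchor", 2))
  expect_equal(as.character(at$class[-tc$buried]), rep("other", 4))
})

test_that("hydrogen-bond presence obeys inclusive distance and angle bounds", {
  # donor, hydrogen, acceptor placed to give exact geometries
  mk <- function(d_da, angle_deg) {
    # D at origin, H 1 A along x; A placed so that the D-H...A angle at H is
    # angle_deg and |D-A| = d_da
    th <- angle_deg * pi / 180
    # place A in the x-y plane at angle th from the H->D direction, with the
    # radial distance rho solving |DA| = d_da (law of cosines, |DH| = 1)
    rho <- cos(th) + sqrt(d_da^2 - sin(th)^2)
    A <- c(1, 0, 0) + rho * c(-cos(th), sin(th), 0)
    rbind(D = c(0, 0, 0), H = c(1, 0, 0), A = A)
  }
  pairs <- data.frame(donor = 1L, acceptor = 3L, hydrogen = 2L)
  h1 <- hbond_presence(mk(2.8, 170), pairs)
  expect_true(h1$present)
  expect_equal(h1$distance, 2.8, tolerance = 1e-9)
  expect_equal(h1$angle, 170, tolerance = 1e-6)
  expect_false(hbond_presence(mk(5.0, 170), pairs)$present)
  # boundary: 3.5 A and 120 degrees exactly are inclusive
  hb <- hbond_presence(mk(3.5, 120), pairs)
  expect_equal(hb$distance, 3.5, tolerance = 1e-9)
  expect_equal(hb$angle, 120, tolerance = 1e-6)
  expect_true(hb$present)
  expect_false(hbond_presence(mk(3.5, 100), pairs)$present)
  # without a resolved hydrogen, distance alone decides
  p2 <- data.frame(donor = 1L, acceptor = 3L, hydrogen = NA_integer_)
  expect_true(hbond_presence(mk(3.2, 90), p2)$present)
  expect_error(hbond_presence(mk(2.8, 170),
                              data.frame(donor = 1L, acceptor = 9L)),
               "out of range")
})
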