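#' @title Synthetic assay and structure generators with known ground truth
#' @description The FP assay data underlying the published fits were not
#'   deposited, so validation relies on simulated datasets generated under the
#'   printed assay conditions: 50 nM labeled probe, 1 uM protein monomer,
#'   probe K_d1 = 760 nM, anisotropy window 0.0470-0.1587, quantum-yield
#'   ratio Q = 0.70, N = 4 replicates with Gaussian anisotropy noise and
#'   occasional outliers. Every generator is a pure function of its
#'   parameters and seed.
#' @name synthetic_data
NULL

#' Canonical concentration grids for simulated FP assays
#'
#' Twelve log-spaced concentrations from 10 nM to 100 uM, bracketing the
#' ~1 uM curve midpoints of the emulated assay (probe K_d and typical
#' competitor IC50) by two decades on either side — the design a titration
#' or competition experiment at these affinities would use.
#'
#' @param n_points Number of grid points (default 12).
#' @return Strictly increasing molar concentrations.
#' @export
default_assay_grid <- function(n_points = 12L) {
  10^seq(-8, -4, length.out = n_points)
}

#' Ground truth for simulated FP assays
#'
#' @param K_d1 Probe dissociation constant (molar).
#' @param K_d2 Competitor dissociation constant (molar; NULL for titrations).
#' @param K_d3 Ternary-complex probe constant (molar; NULL for complete
#'   displacement).
#' @param calibration An [fp_calibration()].
#' @param hill_n Hill slope of the direct titration.
#' @param noise_sd Gaussian anisotropy noise SD (default 0.003, about 3% of
#'   the assay window).
#' @param n_replicates Replicates per concentration (default 4).
#' @param outlier_rate Per-replicate probability of an injected outlier
#'   (default 0; must be < 0.5).
#' @param outlier_magnitude Absolute anisotropy offset of injected outliers
#'   (default 0.05, roughly half the assay window: a gross artifact such as a
#'   bubble or dust event; sign random).
#' @return An object of class `"assay_truth"`.
#' @export
assay_ground_truth <- function(K_d1 = 7.6e-7, K_d2 = NULL, K_d3 = NULL,
                               calibration = fp_calibration(), hill_n = 1,
                               noise_sd = 0.003, n_replicates = 4L,
                               outlier_rate = 0, outlier_magnitude = 0.05) {
  stopifnot(K_d1 > 0, noise_sd >= 0, n_replicates >= 1,
            outlier_rate >= 0, outlier_rate < 0.5, outlier_magnitude >= 0)
  if (!is.null(K_d2)) stopifnot(K_d2 > 0)
  if (!is.null(K_d3)) stopifnot(K_d3 > 0)
  structure(list(K_d1 = K_d1, K_d2 = K_d2, K_d3 = K_d3,
                 calibration = as_fp_calibration(calibration), hill_n = hill_n,
                 noise_sd = noise_sd, n_replicates = as.integer(n_replicates),
                 outlier_rate = outlier_rate,
                 outlier_magnitude = outlier_magnitude),
            class = "assay_truth")
}

.noisy_reps <- function(r_true, truth) {
  n <- truth$n_replicates
  out <- vector("list", length(r_true))
  inj <- NULL
  for (i in seq_along(r_true)) {
    r <- r_true[i] + stats::rnorm(n, 0, truth$noise_sd)
    if (truth$outlier_rate > 0) {
      hit <- stats::runif(n) < truth$outlier_rate
      r[hit] <- r[hit] + sample(c(-1, 1), sum(hit), replace = TRUE) *
        truth$outlier_magnitude
      if (any(hit)) inj <- rbind(inj, data.frame(point = i, replicate = which(hit)))
    }
    out[[i]] <- r
  }
  attr(out, "outliers") <- inj
  out
}

#' Simulate a direct FP titration
#'
#' Anisotropies follow the Hill isotherm through the inverse calibration,
#' plus Gaussian noise of SD `noise_sd` on the anisotropy scale.
#'
#' @param truth An [assay_ground_truth()].
#' @param conc Protein monomer grid (molar, strictly increasing, spanning at
#'   least two decades).
#' @param probe_total Total probe (molar, default 50 nM).
#' @param seed Integer seed; the dataset is reproducible per seed.
#' @return A [titration_series()] with attribute `"seed"`.
#' @export
simulate_titration <- function(truth, conc, probe_total = 5e-8, seed = 1L) {
  stopifnot(inherits(truth, "assay_truth"))
  pos <- conc[conc > 0]
  if (log10(max(pos) / min(pos)) < 2)
    stop("concentration grid must span at least two decades", call. = FALSE)
  fb <- hill_fraction_bound(conc, truth$K_d1, truth$hill_n)
  r_true <- fraction_bound_to_anisotropy(fb, truth$calibration)
  reps <- with_preserved_seed(seed, .noisy_reps(r_true, truth))
  out <- titration_series(probe_total, conc, reps)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- truth
  attr(out, "outliers") <- attr(reps, "outliers")
  out
}

#' Simulate an FP competition series
#'
#' Fraction bound comes from the exact complete-displacement solver when the
#' truth carries no `K_d3`, and from the four-state solver otherwise; it is
#' converted to anisotropy through the inverse calibration before noise and
#' (optionally) seeded outliers of magnitude `outlier_magnitude` are added.
#'
#' @param truth An [assay_ground_truth()] with `K_d2` set.
#' @param conc Competitor grid (molar, strictly increasing).
#' @param protein_total Total protein monomer (molar, default 1 uM).
#' @param probe_total Total probe (molar, default 50 nM).
#' @param seed Integer seed.
#' @return A [competition_series()] with attributes `"seed"`, `"truth"` and
#'   `"outliers"` (positions of injected outliers, NULL when none).
#' @export
simulate_competition <- function(truth, conc, protein_total = 1e-6,
                                 probe_total = 5e-8, seed = 1L) {
  stopifnot(inherits(truth, "assay_truth"))
  if (is.null(truth$K_d2)) stop("truth must carry K_d2", call. = FALSE)
  model <- if (is.null(truth$K_d3)) "complete" else "incomplete"
  fb <- .competition_fb_model(model, conc, protein_total, probe_total,
                              truth$K_d1, truth$K_d2, truth$K_d3)
  r_true <- fraction_bound_to_anisotropy(fb, truth$calibration)
  sim <- with_preserved_seed(seed, .noisy_reps(r_true, truth))
  out <- competition_series(probe_total, protein_total, conc, sim,
                            truth$calibration)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "truth") <- truth
  attr(out, "outliers") <- attr(sim, "outliers")
  out
}

#' Generate a toy C-alpha trajectory with a known fluctuation profile
#'
#' Builds a gently helical C-alpha-only chain (a straight line would make
#' rigid superposition ill-posed) and, for each frame, adds
#' independent Gaussian displacements per residue (isotropic, per-axis SD
#' `profile/sqrt(3)` so the 3-D RMSF ground truth equals `profile`), then
#' applies a random global rotation and translation. Recovering the profile
#' therefore requires superposition, exercising the alignment pipeline.
#'
#' @param n_frames Number of frames (>= 2).
#' @param profile Per-residue RMSF ground truth (angstrom, length = number of
#'   residues).
#' @param seed Integer seed.
#' @param spacing C-alpha spacing along the chain axis (angstrom, default 3.8).
#' @return A `"pip_trajectory"` (see [trajectory()]) with attribute
#'   `"rmsf_truth"`.
#' @export
make_toy_trajectory <- function(n_frames, profile, seed = 1L, spacing = 3.8) {
  stopifnot(n_frames >= 2, all(profile >= 0))
  n_res <- length(profile)
  i <- seq_len(n_res)
  base <- cbind(x = spacing * i, y = 2.3 * sin(i / 2), z = 2.3 * cos(i / 2))
  sd_axis <- profile / sqrt(3)
  coords <- with_preserved_seed(seed, {
    arr <- array(0, dim = c(n_res, 3, n_frames))
    for (f in seq_len(n_frames)) {
      disp <- matrix(stats::rnorm(n_res * 3, 0, rep(sd_axis, 3)), ncol = 3)
      X <- base + disp
      R <- .random_rotation()
      tr <- stats::runif(3, -20, 20)
      arr[, , f] <- sweep(X %*% t(R), 2, tr, "+")
    }
    arr
  })
  atoms <- data.frame(residue_index = seq_len(n_res),
                      residue_name = "GLY", atom_name = "CA",
                      element = "C", chain = "A",
                      stringsAsFactors = FALSE)
  tr <- trajectory(coords, atoms)
  attr(tr, "rmsf_truth") <- profile
  attr(tr, "seed") <- as.integer(seed)
  tr
}

.random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Build a toy peptide-in-groove complex with known buried residues
#'
#' Constructs a coarse-grained single-bead-per-residue peptide along the x
#' axis and a "receptor" consisting of icosahedral atom cages enclosing the
#' designated buried residues (cage atoms clashing with the peptide chain are
#' skipped). The default bead spacing (12 angstrom) exceeds the mutual
#' occlusion range of two carbon atoms with a water probe (6.2 angstrom), so
#' residues do not shadow one another: buried residues lose exactly their
#' isolated accessible surface on binding and exposed residues lose none,
#' giving a construction-guaranteed anchor/other split for [delta_sasa()]
#' and [classify_anchor()].
#'
#' @param n_res Number of peptide residues.
#' @param buried Integer indices of residues to enclose.
#' @param seed Integer seed (cage orientation jitter).
#' @param spacing Bead spacing (angstrom, default 12).
#' @param cage_radius Cage shell radius (angstrom, default 4).
#' @param offset Rigid translation applied to the whole peptide relative to
#'   the receptor (length-3, default none); use e.g. `c(0, 0, 50)` to pull
#'   the peptide out of the groove.
#' @return A list with `complex_coords`, `complex_atoms`, `ligand_index`
#'   (rows of the complex that form the peptide), and `buried`.
#' @export
make_toy_complex <- function(n_res = 6, buried = c(2, 5), seed = 1L,
                             spacing = 12, cage_radius = 4, offset = c(0, 0, 0)) {
  stopifnot(n_res >= 1, all(buried >= 1), all(buried <= n_res))
  pep0 <- cbind(x = spacing * seq_len(n_res), y = 0, z = 0)
  # icosahedron vertices (unit)
  phi <- (1 + sqrt(5)) / 2
  ico <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
               c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
               c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  ico <- ico / sqrt(1 + phi^2)
  rot <- with_preserved_seed(seed, .random_rotation())
  cage <- NULL
  for (b in buried) {
    pts <- sweep(ico %*% t(rot) * cage_radius, 2, pep0[b, ], "+")
    dmin <- min(apply(pts, 1, function(p) min(sqrt(colSums((t(pep0) - p)^2)))))
    if (dmin < 2.0)
      stop("steric overlap between receptor cage and peptide", call. = FALSE)
    # drop cage atoms near other peptide beads (possible at tight spacings)
    others <- pep0[-b, , drop = FALSE]
    keep <- if (nrow(others)) apply(pts, 1, function(p)
      min(sqrt(colSums((t(others) - p)^2))) >= 3.0) else rep(TRUE, nrow(pts))
    cage <- rbind(cage, pts[keep, , drop = FALSE])
  }
  # the receptor cage stays put; the peptide may be translated out of it
  pep <- sweep(pep0, 2, offset, "+")
  coords <- rbind(pep, cage)
  n_cage <- if (is.null(cage)) 0L else nrow(cage)
  atoms <- data.frame(
    residue_index = c(seq_len(n_res), n_res + seq_len(n_cage)),
    residue_name = c(rep("ALA", n_res), rep("REC", n_cage)),
    atom_name = "CA", element = "C",
    chain = c(rep("B", n_res), rep("A", n_cage)),
    stringsAsFactors = FALSE)
  list(complex_coords = coords, complex_atoms = atoms,
       ligand_index = seq_len(n_res), buried = buried)
}
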