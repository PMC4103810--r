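#' @title Trajectory-ensemble analytics
#' @description Post-simulation analysis of structural ensembles: rigid
#'   superposition (Kabsch), per-frame RMSD against a reference frame,
#'   per-residue RMSF, and principal component analysis of aligned snapshot
#'   coordinates. Coordinates are in angstrom throughout.
#' @name structdyn
NULL

#' Trajectory container
#'
#' @param coords Numeric array `n_atoms x 3 x n_frames` (angstrom), or a list
#'   of `n_atoms x 3` matrices with identical dimensions.
#' @param atoms data.frame of per-atom metadata with columns `residue_index`,
#'   `residue_name`, `atom_name`, `element`, `chain` (one row per atom, same
#'   order in every frame).
#' @param frame_times Optional frame times (ps).
#' @return An object of class `"pip_trajectory"`.
#' @export
trajectory <- function(coords, atoms, frame_times = NULL) {
  if (is.list(coords)) {
    stopifnot(length(coords) >= 1)
    dims <- vapply(coords, dim, integer(2))
    if (any(dims != dims[, 1])) stop("frames differ in atom count", call. = FALSE)
    arr <- array(unlist(coords), dim = c(dims[1, 1], 3, length(coords)))
    coords <- arr
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3, dim(coords)[2] == 3)
  if (any(!is.finite(coords))) stop("non-finite coordinates", call. = FALSE)
  stopifnot(is.data.frame(atoms), nrow(atoms) == dim(coords)[1])
  need <- c("residue_index", "atom_name")
  if (!all(need %in% names(atoms)))
    stop("atoms needs at least columns residue_index and atom_name", call. = FALSE)
  if (!is.null(frame_times)) stopifnot(length(frame_times) == dim(coords)[3])
  structure(list(coords = coords, atoms = atoms, frame_times = frame_times),
            class = "pip_trajectory")
}

#' @export
print.pip_trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("Trajectory: %d atoms x %d frames\n", d[1], d[3]))
  invisible(x)
}

n_frames <- function(traj) dim(traj$coords)[3]

#' Resolve an atom selection on a trajectory or atom table
#'
#' Selections are either a logical/integer atom index vector, or a string
#' `"CHAIN:FROM-TO"` (e.g. `"A:1-257"`) optionally restricted to C-alpha
#' atoms via `ca_only`.
#'
#' @param atoms Atom metadata data.frame.
#' @param select Selection (NULL = all atoms).
#' @param ca_only Keep only CA atoms (default FALSE).
#' @return Integer atom indices.
#' @export
resolve_selection <- function(atoms, select = NULL, ca_only = FALSE) {
  idx <- seq_len(nrow(atoms))
  if (is.character(select)) {
    m <- regmatches(select, regexec("^([A-Za-z0-9]+):(-?[0-9]+)-(-?[0-9]+)$", select))[[1]]
    if (length(m) != 4) stop("bad selection string (want CHAIN:FROM-TO): ", select,
                             call. = FALSE)
    keep <- atoms$chain == m[2] &
      atoms$residue_index >= as.integer(m[3]) &
      atoms$residue_index <= as.integer(m[4])
    idx <- idx[keep]
  } else if (is.logical(select)) {
    idx <- idx[select]
  } else if (is.numeric(select)) {
    idx <- as.integer(select)
  }
  if (ca_only) idx <- idx[atoms$atom_name[idx] == "CA"]
  idx
}

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between the
#' masked atoms of `mobile` and `reference`, via SVD of the cross-covariance
#' with reflection correction.
#'
#' @param reference,mobile `n x 3` coordinate matrices.
#' @param mask Optional atom indices used for the superposition (default all).
#' @return A list with `rotation` (3x3), `translation` (length 3; the fitted
#'   transform is `mobile %*% t(rotation) + translation`), `rmsd` (over the
#'   masked atoms) and `fitted` (all mobile atoms transformed).
#' @export
superpose <- function(reference, mobile, mask = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  stopifnot(ncol(reference) == 3, ncol(mobile) == 3,
            nrow(reference) == nrow(mobile))
  if (is.null(mask)) mask <- seq_len(nrow(reference))
  A <- reference[mask, , drop = FALSE]
  B <- mobile[mask, , drop = FALSE]
  if (nrow(A) < 3) stop("superposition needs >= 3 masked atoms", call. = FALSE)
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  H <- crossprod(B0, A0)              # 3x3 cross-covariance
  sv <- svd(H)
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate geometry: masked atoms are (nearly) collinear", call. = FALSE)
  s <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, s))
  R <- sv$v %*% D %*% t(sv$u)
  translation <- ca - as.numeric(R %*% cb)
  fitted <- sweep(mobile %*% t(R), 2, translation, "+")
  rmsd <- sqrt(mean(rowSums((fitted[mask, , drop = FALSE] - A)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd, fitted = fitted)
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame is rigidly superposed (over the masked atoms) onto the
#' reference frame before the RMSD is taken, reproducing the usual
#' "C-alpha RMSD from t = 0" convergence trace.
#'
#' @param traj A [trajectory()].
#' @param mask Atom selection (indices, logical, or `"CHAIN:FROM-TO"`).
#' @param ref_frame Reference frame index (default 1).
#' @return Numeric vector of per-frame RMSD (angstrom); the reference frame
#'   contributes 0.
#' @export
rmsd_series <- function(traj, mask = NULL, ref_frame = 1L) {
  stopifnot(inherits(traj, "pip_trajectory"))
  nf <- n_frames(traj)
  if (ref_frame < 1 || ref_frame > nf) stop("ref_frame out of range", call. = FALSE)
  idx <- resolve_selection(traj$atoms, mask)
  ref <- traj$coords[, , ref_frame]
  vapply(seq_len(nf), function(f) {
    superpose(ref, traj$coords[, , f], mask = idx)$rmsd
  }, numeric(1))
}

#' Align all frames of a trajectory to a reference frame
#'
#' @inheritParams rmsd_series
#' @return The trajectory with every frame superposed onto `ref_frame` over
#'   the masked atoms.
#' @export
align_trajectory <- function(traj, mask = NULL, ref_frame = 1L) {
  stopifnot(inherits(traj, "pip_trajectory"))
  idx <- resolve_selection(traj$atoms, mask)
  ref <- traj$coords[, , ref_frame]
  for (f in seq_len(n_frames(traj)))
    traj$coords[, , f] <- superpose(ref, traj$coords[, , f], mask = idx)$fitted
  traj
}

#' Per-residue root-mean-square fluctuation
#'
#' After aligning all frames to the first (over the masked atoms), computes
#' \deqn{RMSF_i = \sqrt{\langle |x_i(t) - \langle x_i \rangle|^2 \rangle_t}}
#' per masked atom and reports it by residue index.
#'
#' @param traj A [trajectory()] (>= 2 frames).
#' @param mask Atom selection.
#' @param align Align to frame 1 first (default TRUE; set FALSE for
#'   pre-aligned input).
#' @return data.frame with `residue_index` and `rmsf` (angstrom).
#' @export
rmsf <- function(traj, mask = NULL, align = TRUE) {
  stopifnot(inherits(traj, "pip_trajectory"))
  if (n_frames(traj) < 2) stop("RMSF needs at least 2 frames", call. = FALSE)
  idx <- resolve_selection(traj$atoms, mask)
  if (align) traj <- align_trajectory(traj, mask = idx)
  X <- traj$coords[idx, , , drop = FALSE]
  mu <- apply(X, c(1, 2), mean)
  dev2 <- sweep(X, c(1, 2), mu)^2
  msf <- apply(dev2, 1, mean) * 3       # mean over (xyz, frames) * 3 = |.|^2 mean
  data.frame(residue_index = traj$atoms$residue_index[idx],
             rmsf = sqrt(msf))
}

#' Principal component analysis of trajectory snapshots
#'
#' Eigendecomposition of the 3N x 3N covariance matrix of aligned Cartesian
#' coordinates (frames as observations). Residues dominated by terminal
#' motions can be excluded via `drop_residues`.
#'
#' @param traj A [trajectory()] (>= 3 frames).
#' @param mask Atom selection applied before `drop_residues`.
#' @param drop_residues Residue indices to exclude from the analysis.
#' @param align Align frames to frame 1 first (default TRUE).
#' @return A list with `eigenvalues` (non-increasing), `components`
#'   (columns, orthonormal, in coordinate space), `projections` (frames x
#'   components scores of the centered coordinates), `mean` (the mean
#'   structure, flattened) and `atom_index` (atoms used).
#' @export
pca_snapshots <- function(traj, mask = NULL, drop_residues = NULL, align = TRUE) {
  stopifnot(inherits(traj, "pip_trajectory"))
  nf <- n_frames(traj)
  if (nf < 3) stop("PCA needs at least 3 frames", call. = FALSE)
  idx <- resolve_selection(traj$atoms, mask)
  if (!is.null(drop_residues))
    idx <- idx[!(traj$atoms$residue_index[idx] %in% drop_residues)]
  if (align) traj <- align_trajectory(traj, mask = idx)
  # frames x 3N matrix (x1 y1 z1 x2 ...)
  M <- t(apply(traj$coords[idx, , , drop = FALSE], 3, function(m) as.numeric(t(m))))
  mu <- colMeans(M)
  C <- stats::cov(M)
  eg <- eigen(C, symmetric = TRUE)
  proj <- sweep(M, 2, mu) %*% eg$vectors
  list(eigenvalues = eg$values, components = eg$vectors, projections = proj,
       mean = mu, atom_index = idx)
}
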