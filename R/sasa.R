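#' @title Solvent-accessible surface area and interface classification
#' @description Shrake-Rupley SASA with Bondi-type van der Waals radii,
#'   bound/unbound surface-burial (delta-SASA) of a ligand selection, and the
#'   anchor/tether classification of ligand residues: an anchor buries more
#'   than 70 A^2 of accessible surface on binding, a tether stabilizes the
#'   complex through peripheral polar contacts despite a small delta-SASA.
#' @name sasa_module
NULL

# Bondi-type van der Waals radii (angstrom)
.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

.element_of <- function(atoms) {
  el <- atoms$element
  if (is.null(el) || all(is.na(el)) || all(el == "")) {
    # infer from the atom name's first alphabetic character
    el <- toupper(sub("^[0-9]*([A-Za-z]).*$", "\\1", atoms$atom_name))
  }
  toupper(trimws(el))
}

# deterministic quasi-uniform sphere points (golden-spiral lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Rolls a spherical probe over every atom: each atom's extended sphere
#' (vdW + probe radius) is sampled with a deterministic golden-spiral point
#' lattice, points falling inside any neighbor's extended sphere are occluded,
#' and the exposed fraction times the extended-sphere area gives the per-atom
#' SASA, aggregated per residue.
#'
#' @param coords `n x 3` coordinate matrix (angstrom).
#' @param atoms Atom metadata data.frame (`residue_index`, `atom_name`,
#'   optionally `element`).
#' @param probe_radius Probe radius (angstrom, default 1.4, water).
#' @param n_points Lattice points per atom (default 960).
#' @return An object of class `"sasa_profile"`: data.frame with
#'   `residue_index` and `sasa` (A^2), with per-atom values in attribute
#'   `"atom_sasa"`.
#' @export
sasa <- function(coords, atoms, probe_radius = 1.4, n_points = 960L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3, nrow(coords) == nrow(atoms), n_points >= 12)
  el <- .element_of(atoms)
  r <- .vdw_radii[el]
  if (anyNA(r))
    stop("no van der Waals radius for atoms: ",
         paste(unique(atoms$atom_name[is.na(r)]), collapse = ", "), call. = FALSE)
  rext <- unname(r) + probe_radius
  n <- nrow(coords)
  pts <- .sphere_points(n_points)
  atom_sasa <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    if (!length(nb)) { atom_sasa[i] <- 4 * pi * rext[i]^2; next }
    sp <- sweep(pts * rext[i], 2, coords[i, ], "+")
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- (sp[, 1] - coords[j, 1])^2 + (sp[, 2] - coords[j, 2])^2 +
        (sp[, 3] - coords[j, 3])^2
      exposed <- exposed & dj2 > rext[j]^2
      if (!any(exposed)) break
    }
    atom_sasa[i] <- 4 * pi * rext[i]^2 * sum(exposed) / n_points
  }
  agg <- rowsum(atom_sasa, group = atoms$residue_index)
  out <- data.frame(residue_index = as.integer(rownames(agg)), sasa = agg[, 1])
  rownames(out) <- NULL
  structure(out, class = c("sasa_profile", "data.frame"),
            probe_radius = probe_radius, n_points = as.integer(n_points),
            radii_set = "bondi", atom_sasa = atom_sasa)
}

#' Change in ligand SASA on binding (delta-SASA)
#'
#' For each ligand residue, the accessible surface it loses when the complex
#' forms: \eqn{\Delta SASA_i = SASA_i(\mathrm{ligand\ alone}) -
#' SASA_i(\mathrm{ligand\ in\ complex})}. Non-negative up to point-sampling
#' noise.
#'
#' @param coords,atoms Complex coordinates and metadata.
#' @param ligand Selection of the ligand atoms (indices, logical, or
#'   `"CHAIN:FROM-TO"`).
#' @param probe_radius,n_points Passed to [sasa()].
#' @return data.frame with `residue_index`, `sasa_free`, `sasa_bound`,
#'   `delta_sasa` (A^2) for the ligand residues.
#' @export
delta_sasa <- function(coords, atoms, ligand, probe_radius = 1.4,
                       n_points = 960L) {
  coords <- as.matrix(coords)
  idx <- resolve_selection(atoms, ligand)
  if (!length(idx)) stop("empty ligand selection", call. = FALSE)
  s_complex <- sasa(coords, atoms, probe_radius, n_points)
  s_free <- sasa(coords[idx, , drop = FALSE], atoms[idx, , drop = FALSE],
                 probe_radius, n_points)
  lig_res <- unique(atoms$residue_index[idx])
  bound <- s_complex$sasa[match(lig_res, s_complex$residue_index)]
  free <- s_free$sasa[match(lig_res, s_free$residue_index)]
  data.frame(residue_index = lig_res, sasa_free = free, sasa_bound = bound,
             delta_sasa = free - bound)
}

#' Classify ligand residues as anchor, tether, or other
#'
#' An anchor residue buries more than `threshold` (default 70 A^2, strict
#' inequality) of accessible surface on binding; a non-anchor residue with at
#' least one polar-contact evidence entry (hydrogen bond or salt bridge) is a
#' tether; everything else is "other".
#'
#' @param delta A data.frame from [delta_sasa()] (needs `residue_index`,
#'   `delta_sasa`).
#' @param evidence Optional data.frame of polar contacts with columns
#'   `residue_index` and `partner` (free-text description).
#' @param threshold Anchor threshold (A^2, default 70).
#' @return An `"anchor_table"`: data.frame with `residue_index`,
#'   `delta_sasa`, `class` (factor anchor/tether/other) and `evidence`
#'   (collapsed partner list, `""` if none).
#' @export
classify_anchor <- function(delta, evidence = NULL, threshold = 70) {
  stopifnot(all(c("residue_index", "delta_sasa") %in% names(delta)))
  ev <- vapply(delta$residue_index, function(ri) {
    if (is.null(evidence)) return("")
    paste(evidence$partner[evidence$residue_index == ri], collapse = "; ")
  }, character(1))
  cls <- ifelse(delta$delta_sasa > threshold, "anchor",
                ifelse(nzchar(ev), "tether", "other"))
  out <- data.frame(residue_index = delta$residue_index,
                    delta_sasa = delta$delta_sasa,
                    class = factor(cls, levels = c("anchor", "tether", "other")),
                    evidence = ev, stringsAsFactors = FALSE)
  class(out) <- c("anchor_table", "data.frame")
  out
}

#' Hydrogen-bond presence by geometric criteria
#'
#' A donor/acceptor pair is scored present when the donor-acceptor heavy-atom
#' distance is at most `dist_cutoff` (inclusive) and, when a donor hydrogen is
#' given, the D-H...A angle is at least `angle_cutoff` (inclusive).
#'
#' @param coords `n x 3` coordinates, or a [trajectory()] (then the presence
#'   table gains one row per frame).
#' @param pairs data.frame with integer atom-index columns `donor` and
#'   `acceptor`, and optionally `hydrogen` (NA when the H is not resolved).
#' @param dist_cutoff Heavy-atom distance cutoff (angstrom, default 3.5).
#' @param angle_cutoff D-H...A angle cutoff (degrees, default 120).
#' @return data.frame with `frame`, `donor`, `acceptor`, `distance`, `angle`
#'   (NA without hydrogen) and logical `present`.
#' @export
hbond_presence <- function(coords, pairs, dist_cutoff = 3.5, angle_cutoff = 120) {
  stopifnot(all(c("donor", "acceptor") %in% names(pairs)))
  frames <- if (inherits(coords, "pip_trajectory")) {
    lapply(seq_len(n_frames(coords)), function(f) coords$coords[, , f])
  } else list(as.matrix(coords))
  out <- do.call(rbind, lapply(seq_along(frames), function(f) {
    X <- frames[[f]]
    n <- nrow(X)
    if (any(pairs$donor > n | pairs$acceptor > n))
      stop("donor/acceptor atom index out of range", call. = FALSE)
    d <- sqrt(rowSums((X[pairs$donor, , drop = FALSE] -
                         X[pairs$acceptor, , drop = FALSE])^2))
    ang <- rep(NA_real_, nrow(pairs))
    if ("hydrogen" %in% names(pairs)) {
      hv <- which(!is.na(pairs$hydrogen))
      for (k in hv) {
        Dv <- X[pairs$donor[k], ] - X[pairs$hydrogen[k], ]
        Av <- X[pairs$acceptor[k], ] - X[pairs$hydrogen[k], ]
        ang[k] <- acos(min(1, max(-1, sum(Dv * Av) /
                                    (sqrt(sum(Dv^2)) * sqrt(sum(Av^2)))))) * 180 / pi
      }
    }
    # inclusive bounds, with a 1e-9 guard so constructed boundary geometries
    # are not lost to floating-point round-off
    present <- d <= dist_cutoff + 1e-9 & (is.na(ang) | ang >= angle_cutoff - 1e-9)
    data.frame(frame = f, donor = pairs$donor, acceptor = pairs$acceptor,
               distance = d, angle = ang, present = present)
  }))
  rownames(out) <- NULL
  out
}
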