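# Chromophore geometry and fluctuation descriptors from trajectory frames.
#
# Descriptor definitions (atoms in 11-cis retinal carbon nomenclature):
#   Torsion 15: dihedral C7-C6-C5-C18        (median over frames)
#   Angle 3   : geometric angle C3-C7-C8, vertex C7
#   Torsion 3 : dihedral C15-C14-C13-C20
#   Torsion 12: dihedral C19-C9-C8-C7
#   RMSF AUC  : area under the per-atom RMSF curve of the LYS+RET atom series

.DESCRIPTOR_ATOMS <- list(
  torsion15 = c("C7", "C6", "C5", "C18"),
  angle3    = c("C3", "C7", "C8"),
  torsion3  = c("C15", "C14", "C13", "C20"),
  torsion12 = c("C19", "C9", "C8", "C7")
)

#' Construct a chromophore trajectory
#'
#' @param atoms Character vector of unique atom labels (retinal carbons
#'   `C1`..`C20` plus lysine atoms), in the fixed order used for the RMSF
#'   curve.
#' @param coords Numeric array `[frames, atoms, 3]` of coordinates in
#'   Angstrom, or a list of per-frame `atoms x 3` matrices.
#' @param frame_spacing Informational time spacing between frames.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, frame_spacing = NA_real_) {
  if (is.list(coords)) {
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  if (anyDuplicated(atoms)) stop("atom labels must be unique")
  if (dim(coords)[2] != length(atoms)) {
    stop("coords second dimension must match number of atoms")
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  structure(list(atoms = as.character(atoms), coords = coords,
                 frame_spacing = frame_spacing),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", dim(x$coords)[1], " frames x ", length(x$atoms),
      " atoms\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

.atom_index <- function(traj, atoms) {
  idx <- match(atoms, traj$atoms)
  if (anyNA(idx)) {
    stop("atom(s) missing from trajectory: ",
         paste(atoms[is.na(idx)], collapse = ", "))
  }
  idx
}

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.row_norm <- function(a) sqrt(rowSums(a * a))

#' Signed dihedral angle of four points
#'
#' Standard atan2 construction on the normals of the two planes; the sign
#' convention is fixed by the frozen example
#' `dihedral(c(0,0,0), c(1,0,0), c(1,1,0), c(1,1,1)) == -90`. Planar cis
#' arrangements give 0, planar trans 180; values lie in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric length-3 points, or n-row matrices for a
#'   vectorized series.
#' @return Dihedral(s) in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3); p4 <- rbind(p4)
  }
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .row_cross(b1, b2)
  n2 <- .row_cross(b2, b3)
  ln1 <- .row_norm(n1); ln2 <- .row_norm(n2)
  bad <- ln1 < 1e-10 | ln2 < 1e-10
  if (any(bad)) {
    stop("undefined dihedral: collinear triple at observation ",
         which(bad)[1])
  }
  b2hat <- b2 / .row_norm(b2)
  y <- rowSums(.row_cross(n2, n1) * b2hat)
  x <- rowSums(n1 * n2)
  d <- atan2(y, x) * 180 / pi
  unname(wrap_deg(d))
}

#' Geometric bond angle of three points (vertex at the middle point)
#'
#' @param p1,p2,p3 Numeric length-3 points, or n-row matrices.
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @export
bond_angle <- function(p1, p2, p3) {
  if (is.null(dim(p1))) {
    p1 <- rbind(p1); p2 <- rbind(p2); p3 <- rbind(p3)
  }
  v1 <- p1 - p2; v2 <- p3 - p2
  l1 <- .row_norm(v1); l2 <- .row_norm(v2)
  if (any(l1 < 1e-10 | l2 < 1e-10)) stop("zero-length vector in bond angle")
  cosang <- pmin(1, pmax(-1, rowSums(v1 * v2) / (l1 * l2)))
  unname(acos(cosang) * 180 / pi)
}

#' Wrap angles in degrees to (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Wrapped angles; 180 and -180 both map to 180.
#' @export
wrap_deg <- function(x) x - 360 * ceiling((x - 180) / 360)

#' Circular-aware median of an angle series in degrees
#'
#' Values are re-branched around their circular mean before taking the
#' ordinary median, so distributions straddling the +/-180 seam are handled
#' without wrap artifacts (e.g. frames alternating +179 and -179 give 180,
#' not 0).
#'
#' @param x Angles in degrees.
#' @return Median in (-180, 180].
#' @export
circular_median_deg <- function(x) {
  rad <- x * pi / 180
  mu <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  wrap_deg(mu + median(wrap_deg(x - mu)))
}

#' Per-frame angle series and its median
#'
#' Computes the named angle in every frame (dihedral for a four-atom spec,
#' geometric angle for a three-atom spec) and returns the circular-aware
#' median for dihedrals, the plain median for geometric angles (which live
#' in `[0, 180]` and cannot wrap).
#'
#' @param traj A [trajectory()].
#' @param angle_spec Character vector of 3 or 4 atom names, or a descriptor
#'   name among `r paste(names(.DESCRIPTOR_ATOMS), collapse = ", ")`.
#' @param series Return the full per-frame series instead of the median.
#' @return Median angle in degrees (or the per-frame series).
#' @export
angle_series_median <- function(traj, angle_spec, series = FALSE) {
  if (length(angle_spec) == 1L && angle_spec %in% names(.DESCRIPTOR_ATOMS)) {
    angle_spec <- .DESCRIPTOR_ATOMS[[angle_spec]]
  }
  stopifnot(length(angle_spec) %in% c(3L, 4L))
  idx <- .atom_index(traj, angle_spec)
  pts <- lapply(idx, function(i) traj$coords[, i, , drop = FALSE][, 1, ])
  pts <- lapply(pts, function(p) if (is.null(dim(p))) rbind(p) else p)
  vals <- tryCatch(
    if (length(idx) == 4L) dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    else bond_angle(pts[[1]], pts[[2]], pts[[3]]),
    error = function(e) stop("frame-level geometry error: ",
                             conditionMessage(e)))
  if (series) return(vals)
  if (length(idx) == 4L) circular_median_deg(vals) else median(vals)
}

.traj_xyz <- function(traj, idx) {
  # bio3d xyz convention: frames in rows, coordinates x1,y1,z1,x2,... in cols
  nf <- n_frames(traj)
  m <- matrix(0, nf, 3L * length(idx))
  for (k in seq_along(idx)) {
    m[, 3L * k - 2L] <- traj$coords[, idx[k], 1]
    m[, 3L * k - 1L] <- traj$coords[, idx[k], 2]
    m[, 3L * k]      <- traj$coords[, idx[k], 3]
  }
  m
}

#' Per-atom root mean square fluctuation after rigid superposition
#'
#' Frames are least-squares superposed (Kabsch fit, via bio3d) onto the mean
#' structure of the selected atoms themselves, obtained by two fit/average
#' iterations started from the first frame; per-atom RMSF is then the root
#' mean squared deviation from each atom's mean position. The superposition
#' removes global rigid-body motion, so rigid-body-translated or rotated
#' copies of a single frame give exactly zero fluctuation.
#'
#' @param traj A [trajectory()] with at least two frames.
#' @param selection Atom names to superpose and report (default: all).
#' @param reference Optional reference frame (`length(selection) x 3`
#'   matrix) to fit against instead of the iterated mean structure.
#' @return Named numeric vector of per-atom RMSF values in Angstrom.
#' @export
rmsf_per_atom <- function(traj, selection = traj$atoms, reference = NULL) {
  if (n_frames(traj) < 2L) stop("need at least 2 frames for RMSF")
  if (!length(selection)) stop("empty selection")
  idx <- .atom_index(traj, selection)
  xyz <- .traj_xyz(traj, idx)
  fm <- matrix(xyz[1, ], ncol = 3L, byrow = TRUE)
  if (nrow(fm) > 1L && max(abs(sweep(fm, 2, colMeans(fm)))) < 1e-8) {
    stop("degenerate superposition: selected atoms coincide")
  }
  inds <- seq_len(ncol(xyz))
  if (is.null(reference)) {
    ref <- xyz[1, ]
    for (it in 1:2) {
      fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                               fixed.inds = inds, mobile.inds = inds)
      ref <- colMeans(fitted)
    }
  } else {
    stopifnot(nrow(reference) == length(idx), ncol(reference) == 3L)
    ref <- as.numeric(t(reference))
  }
  fitted <- bio3d::fit.xyz(fixed = ref, mobile = xyz,
                           fixed.inds = inds, mobile.inds = inds)
  mu <- colMeans(fitted)
  dev2 <- sweep(fitted, 2, mu)^2
  per_atom <- vapply(seq_along(idx), function(k) {
    sqrt(mean(rowSums(dev2[, (3L * k - 2L):(3L * k), drop = FALSE])))
  }, numeric(1))
  setNames(per_atom, traj$atoms[idx])
}

#' Area under the per-atom RMSF curve
#'
#' Trapezoidal integral of RMSF against atom index at unit spacing, with the
#' atoms taken in the fixed LYS+RET series order.
#'
#' @param per_atom_values Numeric vector of per-atom RMSF values, in atom
#'   order.
#' @return Area in Angstrom times atom index.
#' @export
rmsf_auc <- function(per_atom_values) {
  n <- length(per_atom_values)
  if (n < 2L) stop("need at least 2 atoms for an RMSF curve")
  sum((per_atom_values[-1] + per_atom_values[-n]) / 2)
}

#' Compute the full chromophore descriptor set
#'
#' @param traj A [trajectory()] of the LYS+RET moiety containing atoms C3,
#'   C5, C6, C7, C8, C9, C13, C14, C15, C18, C19, C20.
#' @param pigment_id Label carried into the result.
#' @return A `descriptor_set`: list with `torsion15_median`, `angle3_median`,
#'   `torsion3_median`, `torsion12_median`, `rmsf_auc`.
#' @export
compute_descriptors <- function(traj, pigment_id = "pigment") {
  needed <- unique(unlist(.DESCRIPTOR_ATOMS))
  missing <- setdiff(needed, traj$atoms)
  if (length(missing)) {
    stop("trajectory lacks named atom(s): ", paste(missing, collapse = ", "))
  }
  descriptor_set(
    torsion15_median = angle_series_median(traj, "torsion15"),
    angle3_median    = angle_series_median(traj, "angle3"),
    torsion3_median  = angle_series_median(traj, "torsion3"),
    torsion12_median = angle_series_median(traj, "torsion12"),
    rmsf_auc         = rmsf_auc(rmsf_per_atom(traj)),
    pigment_id = pigment_id)
}

#' Construct a descriptor set directly
#'
#' @param torsion15_median,angle3_median,torsion3_median,torsion12_median
#'   Angle medians in degrees (NA where not computed).
#' @param rmsf_auc Area under the RMSF curve (NA where not computed).
#' @param pigment_id Label.
#' @return A `descriptor_set`.
#' @export
descriptor_set <- function(torsion15_median = NA_real_,
                           angle3_median = NA_real_,
                           torsion3_median = NA_real_,
                           torsion12_median = NA_real_,
                           rmsf_auc = NA_real_, pigment_id = "pigment") {
  chk <- function(x, lo, hi) is.na(x) || (x > lo - 1e-9 && x <= hi + 1e-9)
  stopifnot(chk(torsion15_median, -180, 180), chk(angle3_median, 0, 180),
            chk(torsion3_median, -180, 180), chk(torsion12_median, -180, 180),
            is.na(rmsf_auc) || rmsf_auc >= 0)
  structure(list(pigment_id = pigment_id,
                 torsion15_median = torsion15_median,
                 angle3_median = angle3_median,
                 torsion3_median = torsion3_median,
                 torsion12_median = torsion12_median,
                 rmsf_auc = rmsf_auc),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("<descriptor_set> ", x$pigment_id, "\n", sep = "")
  v <- unlist(x[-1])
  print(round(v, 4))
  invisible(x)
}

#' Write descriptor sets as TSV
#'
#' Columns exactly: `pigment_id`, `torsion15`, `angle3`, `torsion3`,
#' `torsion12`, `rmsf_auc`.
#'
#' @param descriptors A `descriptor_set` or list of them.
#' @param path Output file (or connection).
#' @return The assembled data frame, invisibly.
#' @export
write_descriptors_tsv <- function(descriptors, path) {
  if (inherits(descriptors, "descriptor_set")) descriptors <- list(descriptors)
  df <- do.call(rbind, lapply(descriptors, function(d) {
    data.frame(pigment_id = d$pigment_id, torsion15 = d$torsion15_median,
               angle3 = d$angle3_median, torsion3 = d$torsion3_median,
               torsion12 = d$torsion12_median, rmsf_auc = d$rmsf_auc)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Read descriptor sets from TSV
#'
#' Expects the column layout written by [write_descriptors_tsv()]; an
#' optional `opsin_class` column is carried through as an attribute.
#'
#' @param path TSV file.
#' @return List of `descriptor_set` objects.
#' @export
read_descriptors_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("pigment_id", "torsion15", "angle3", "torsion3", "torsion12",
            "rmsf_auc")
  if (!all(need %in% names(df))) {
    stop("descriptor TSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    d <- descriptor_set(torsion15_median = df$torsion15[i],
                        angle3_median = df$angle3[i],
                        torsion3_median = df$torsion3[i],
                        torsion12_median = df$torsion12[i],
                        rmsf_auc = df$rmsf_auc[i],
                        pigment_id = df$pigment_id[i])
    if ("opsin_class" %in% names(df)) {
      attr(d, "opsin_class") <- df$opsin_class[i]
    }
    d
  })
}

#' Read a trajectory from a plain TSV table
#'
#' Layout: columns `frame` (1-based), `atom`, `x`, `y`, `z` in Angstrom.
#' Atom order is taken from the first frame.
#'
#' @param path TSV file.
#' @param frame_spacing Informational time spacing.
#' @return A [trajectory()].
#' @export
read_trajectory_tsv <- function(path, frame_spacing = NA_real_) {
  df <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("trajectory TSV must have columns: ", paste(need, collapse = ", "))
  }
  frames <- sort(unique(df$frame))
  atoms <- df$atom[df$frame == frames[1]]
  coords <- array(NA_real_, c(length(frames), length(atoms), 3L))
  for (fi in seq_along(frames)) {
    sub <- df[df$frame == frames[fi], ]
    idx <- match(atoms, sub$atom)
    if (anyNA(idx)) stop("frame ", frames[fi], " misses atom(s)")
    coords[fi, , ] <- as.matrix(sub[idx, c("x", "y", "z")])
  }
  trajectory(atoms, coords, frame_spacing)
}

#' Write a trajectory as a plain TSV table
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path) {
  nf <- n_frames(traj)
  na <- length(traj$atoms)
  df <- data.frame(frame = rep(seq_len(nf), each = na),
                   atom = rep(traj$atoms, nf),
                   x = as.vector(t(traj$coords[, , 1])),
                   y = as.vector(t(traj$coords[, , 2])),
                   z = as.vector(t(traj$coords[, , 3])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a multi-model PDB as a trajectory
#'
#' Each MODEL becomes one frame; atoms are matched by PDB atom name.
#'
#' @param path PDB file.
#' @return A [trajectory()].
#' @export
read_trajectory_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = TRUE)
  atoms <- pdb$atom$elety
  xyz <- pdb$xyz
  nf <- nrow(xyz)
  coords <- array(NA_real_, c(nf, length(atoms), 3L))
  for (k in seq_along(atoms)) {
    coords[, k, 1] <- xyz[, 3L * k - 2L]
    coords[, k, 2] <- xyz[, 3L * k - 1L]
    coords[, k, 3] <- xyz[, 3L * k]
  }
  trajectory(atoms, coords)
}

#' Write a trajectory as a multi-model PDB
#'
#' Atoms are emitted as HETATM records of a single RET residue so that named
#' retinal carbons (C1..C20) and lysine atoms round-trip through standard
#' PDB readers.
#'
#' @param traj A [trajectory()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    for (k in seq_along(traj$atoms)) {
      writeLines(sprintf(
        "HETATM%5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        k, traj$atoms[k], "RET", 1L,
        traj$coords[f, k, 1], traj$coords[f, k, 2], traj$coords[f, k, 3]),
        con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
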