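# Synthetic inputs with recorded ground truth: chromophore trajectories,
# opsin coding sequences, and developmental count tables.
#
# Trajectory realism is deliberately minimal: the scaffold is an idealized
# retinal-plus-lysine atom chain, and only the statistics the descriptors
# measure (named angle distributions, fluctuation amplitudes, rigid-body
# motion) are controlled. No force field is emulated.

# LYS + RET atom series in curve order: lysine backbone/side chain, then the
# retinal polyene from the Schiff-base carbon C15 back to the beta-ionone
# ring, with methyl carbons (C16-C20) as branches.
.LYSRET_CHAIN <- c("N", "CA", "CB", "CG", "CD", "CE", "NZ",
                   "C15", "C14", "C13", "C12", "C11", "C10", "C9", "C8",
                   "C7", "C6", "C5", "C4", "C3", "C2", "C1")
.LYSRET_BRANCHES <- list(
  C   = list(parent = "CA", offset = c(0.4, 1.25, 0.55)),
  O   = list(parent = "C",  offset = c(0.2, 1.00, -0.60)),
  C20 = list(parent = "C13", offset = c(0.3, -1.20, 0.70)),
  C19 = list(parent = "C9",  offset = c(-0.2, 1.25, 0.50)),
  C18 = list(parent = "C5",  offset = c(0.4, -1.10, -0.80)),
  C16 = list(parent = "C1",  offset = c(0.5, 1.20, 0.30)),
  C17 = list(parent = "C1",  offset = c(0.4, -0.90, 1.00))
)
.LYSRET_ORDER <- c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ",
                   "C15", "C14", "C13", "C20", "C12", "C11", "C10", "C9",
                   "C19", "C8", "C7", "C6", "C5", "C18", "C4", "C3", "C2",
                   "C1", "C16", "C17")

.lysret_scaffold <- function() {
  pos <- list()
  for (i in seq_along(.LYSRET_CHAIN)) {
    pos[[.LYSRET_CHAIN[i]]] <-
      c(1.35 * i, 1.1 * sin(0.9 * i), 0.8 * cos(0.7 * i))
  }
  for (nm in names(.LYSRET_BRANCHES)) {
    b <- .LYSRET_BRANCHES[[nm]]
    pos[[nm]] <- pos[[b$parent]] + b$offset
  }
  xyz <- do.call(rbind, pos[.LYSRET_ORDER])
  rownames(xyz) <- .LYSRET_ORDER
  list(atoms = .LYSRET_ORDER, xyz = xyz)
}

.rodrigues <- function(v, axis, theta) {
  k <- axis / sqrt(sum(axis^2))
  v * cos(theta) + .row_cross(rbind(k), rbind(v))[1, ] * sin(theta) +
    k * sum(k * v) * (1 - cos(theta))
}

.rotate_about_line <- function(p, point, axis, theta) {
  point + .rodrigues(p - point, axis, theta)
}

# Set one named angle spec exactly by rotating its single mobile atom:
# torsion15 moves C18 about the C6->C5 axis, torsion3 moves C20 about
# C14->C13, torsion12 moves C19 about C9->C8, angle3 rotates C3 in the
# C3-C7-C8 plane about C7. All four mobile atoms are leaves of the scaffold,
# so the specs are independently settable.
.set_named_angle <- function(xyz, spec, target) {
  atoms <- .DESCRIPTOR_ATOMS[[spec]]
  p <- lapply(atoms, function(a) xyz[a, ])
  if (length(atoms) == 4L) {
    mobile <- if (spec == "torsion12") atoms[1] else atoms[4]
    cur <- dihedral(p[[1]], p[[2]], p[[3]], p[[4]])
    axis <- p[[3]] - p[[2]]
    point <- p[[2]]
  } else {
    mobile <- atoms[1]
    cur <- bond_angle(p[[1]], p[[2]], p[[3]])
    axis <- .row_cross(rbind(p[[1]] - p[[2]]), rbind(p[[3]] - p[[2]]))[1, ]
    point <- p[[2]]
  }
  delta <- (target - cur) * pi / 180
  cand <- .rotate_about_line(xyz[mobile, ], point, axis, delta)
  xyz2 <- xyz
  xyz2[mobile, ] <- cand
  new <- if (length(atoms) == 4L) {
    dihedral(xyz2[atoms[1], ], xyz2[atoms[2], ], xyz2[atoms[3], ],
             xyz2[atoms[4], ])
  } else {
    bond_angle(xyz2[atoms[1], ], xyz2[atoms[2], ], xyz2[atoms[3], ])
  }
  if (abs(wrap_deg(new - target)) > 1e-6) {
    xyz2[mobile, ] <- .rotate_about_line(xyz[mobile, ], point, axis, -delta)
  }
  xyz2
}

.random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Recipe for a synthetic chromophore trajectory
#'
#' Defaults emulate the trajectory statistics of a weakly twisted 11-cis
#' chromophore: 5000 frames (as sampled from a 100 ns production run),
#' near-planar torsions with spreads of a few degrees, and thermal jitter
#' giving an RMSF-curve area of order 0.8 over the 29-atom LYS+RET series.
#'
#' @param n_frames Number of frames (>= 2).
#' @param dihedral_targets Named list over any of `torsion15`, `angle3`,
#'   `torsion3`, `torsion12`; each entry `c(location, spread)` in degrees.
#'   Torsions are sampled wrapped-normal, the geometric angle plain normal
#'   (clamped to (0, 180)).
#' @param jitter_sigma Isotropic Gaussian jitter, Angstrom per axis.
#' @param global_motion `"none"` or `"rigid"` (random rigid rotation and
#'   translation per frame, removed again by RMSF superposition).
#' @param seed Seed making the trajectory fully deterministic.
#' @return A `trajectory_recipe` list.
#' @export
trajectory_recipe <- function(n_frames = 5000,
                              dihedral_targets = list(
                                torsion15 = c(3.64, 8),
                                angle3 = c(132.33, 4),
                                torsion3 = c(2.14, 8),
                                torsion12 = c(-5.1, 8)),
                              jitter_sigma = 0.02,
                              global_motion = c("none", "rigid"),
                              seed = 1L) {
  global_motion <- match.arg(global_motion)
  stopifnot(n_frames >= 2)
  bad <- setdiff(names(dihedral_targets), names(.DESCRIPTOR_ATOMS))
  if (length(bad)) {
    stop("non-rotatable angle spec(s): ", paste(bad, collapse = ", "),
         "; settable specs: ", paste(names(.DESCRIPTOR_ATOMS), collapse = ", "))
  }
  for (t in dihedral_targets) stopifnot(length(t) == 2L, t[2] >= 0)
  structure(list(n_frames = as.integer(n_frames),
                 dihedral_targets = dihedral_targets,
                 jitter_sigma = jitter_sigma, global_motion = global_motion,
                 seed = as.integer(seed)),
            class = "trajectory_recipe")
}

#' Jitter amplitude realizing a target RMSF-curve area
#'
#' Least-squares superposition removes the six rigid-body degrees of
#' freedom, so isotropic jitter of per-axis amplitude sigma yields an
#' expected per-atom RMSF of `sigma * sqrt(3 * (1 - 2/N))` over N atoms and
#' an RMSF-curve area of that times `N - 1`. This inverts the relation.
#'
#' @param target_auc Desired area under the RMSF curve.
#' @param n_atoms Number of atoms in the series (default: the LYS+RET 29).
#' @return Per-axis jitter sigma in Angstrom.
#' @export
jitter_for_auc <- function(target_auc, n_atoms = length(.LYSRET_ORDER)) {
  target_auc / (sqrt(3 * (1 - 2 / n_atoms)) * (n_atoms - 1))
}

#' Generate a synthetic chromophore trajectory
#'
#' Builds frames from the idealized LYS+RET scaffold: each targeted angle is
#' set exactly to a value drawn from its recipe distribution (wrapped normal
#' for torsions), isotropic Gaussian jitter is added, and optional global
#' rigid motion applied. The recorded ground truth gives the target medians
#' and the expected RMSF-curve area (exact for zero angle spreads; for
#' nonzero spreads the tangential motion of each mobile atom, at its lever
#' arm from the rotation axis, is added in quadrature and the value is
#' flagged approximate).
#'
#' @param recipe A [trajectory_recipe()].
#' @return A [trajectory()]; `ground_truth(traj)` returns the recorded
#'   targets.
#' @export
make_trajectory <- function(recipe) {
  stopifnot(inherits(recipe, "trajectory_recipe"))
  set.seed(recipe$seed)
  scaf <- .lysret_scaffold()
  N <- length(scaf$atoms)
  nf <- recipe$n_frames
  specs <- names(recipe$dihedral_targets)
  coords <- array(NA_real_, c(nf, N, 3L))
  for (f in seq_len(nf)) {
    m <- scaf$xyz
    for (nm in specs) {
      tgt <- recipe$dihedral_targets[[nm]]
      val <- if (nm == "angle3") {
        min(max(rnorm(1, tgt[1], tgt[2]), 1), 179)
      } else {
        wrap_deg(tgt[1] + rnorm(1, 0, tgt[2]))
      }
      m <- .set_named_angle(m, nm, val)
    }
    if (recipe$jitter_sigma > 0) {
      m <- m + matrix(rnorm(3L * N, 0, recipe$jitter_sigma), N, 3L)
    }
    if (recipe$global_motion == "rigid") {
      R <- .random_rotation()
      m <- m %*% t(R) + matrix(runif(3, -5, 5), N, 3L, byrow = TRUE)
    }
    coords[f, , ] <- m
  }
  traj <- trajectory(scaf$atoms, coords)

  # expected per-atom RMSF: jitter term (with the 6-DOF fit correction)
  # plus, for each mobile atom, circular tangential variance r^2(1-e^(-s^2))
  base_var <- 3 * recipe$jitter_sigma^2 * (1 - 2 / N)
  extra <- setNames(numeric(N), scaf$atoms)
  approx_auc <- FALSE
  scaffold_after <- scaf$xyz
  for (nm in specs) {
    tgt <- recipe$dihedral_targets[[nm]]
    scaffold_after <- .set_named_angle(scaffold_after, nm, tgt[1])
  }
  for (nm in specs) {
    tgt <- recipe$dihedral_targets[[nm]]
    if (tgt[2] <= 0) next
    approx_auc <- TRUE
    atoms <- .DESCRIPTOR_ATOMS[[nm]]
    mobile <- if (length(atoms) == 3L || nm == "torsion12") atoms[1] else atoms[4]
    if (length(atoms) == 4L) {
      a1 <- scaffold_after[atoms[2], ]; a2 <- scaffold_after[atoms[3], ]
    } else {
      a1 <- scaffold_after[atoms[2], ]
      a2 <- a1 + .row_cross(rbind(scaffold_after[atoms[1], ] - a1),
                            rbind(scaffold_after[atoms[3], ] - a1))[1, ]
    }
    u <- (a2 - a1) / sqrt(sum((a2 - a1)^2))
    w <- scaffold_after[mobile, ] - a1
    r <- sqrt(sum((w - sum(w * u) * u)^2))
    s <- tgt[2] * pi / 180
    extra[mobile] <- extra[mobile] + r^2 * (1 - exp(-s^2))
  }
  exp_rmsf <- sqrt(base_var + extra)
  gt <- list(
    targets = lapply(recipe$dihedral_targets, function(t) {
      c(location = unname(t[1]), spread = unname(t[2]))
    }),
    jitter_sigma = recipe$jitter_sigma,
    rmsf_auc = sum((exp_rmsf[-1] + exp_rmsf[-N]) / 2),
    rmsf_auc_approximate = approx_auc,
    global_motion = recipe$global_motion,
    seed = recipe$seed)
  attr(traj, "ground_truth") <- gt
  traj
}

#' Ground truth recorded by a generator
#'
#' @param x Object returned by [make_trajectory()], [make_sequence()] or
#'   [make_counts()].
#' @return The recorded ground-truth list.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Write a generator's ground truth as a JSON sidecar
#'
#' @param x Generator output carrying ground truth.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(x, path) {
  jsonlite::write_json(ground_truth(x), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# sequences

.CODON_FOR <- c(A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT",
                Q = "CAA", E = "GAA", G = "GGT", H = "CAT", I = "ATT",
                L = "CTG", K = "AAA", M = "ATG", F = "TTT", P = "CCT",
                S = "TCT", T = "ACT", W = "TGG", Y = "TAT", V = "GTT")

#' Synthetic intact reference opsin for a class
#'
#' A clean full-length coding sequence built by reverse-translating the
#' bovine rod-opsin protein with canonical codons (plus a TAA stop), labeled
#' with the requested class. Because the backbone is the numbering reference
#' itself, bovine site k maps to protein position k exactly, which makes
#' planted-site ground truth trivial to record. This is a synthetic
#' stand-in, not a cloned salmonid sequence.
#'
#' @param opsin_class Class label for the record.
#' @param id Record id (default `syn_<class>_ref`).
#' @return An [opsin_sequence()] with CDS.
#' @export
synthetic_reference_opsin <- function(opsin_class = "rh1", id = NULL) {
  prot <- bovine_rhodopsin()$protein
  cds <- paste0(paste(.CODON_FOR[strsplit(prot, "")[[1]]], collapse = ""),
                "TAA")
  if (is.null(id)) id <- paste0("syn_", opsin_class, "_ref")
  opsin_sequence(id, cds = cds, species = "synthetic",
                 opsin_class = opsin_class)
}

#' Describe one sequence lesion
#'
#' @param type `"deletion"`, `"insertion"` or `"stop"`.
#' @param position For deletions/insertions the 1-based reference nucleotide
#'   position of the first affected base; for stops the 1-based codon
#'   position to overwrite with TAA.
#' @param length Lesion length in nucleotides (ignored for `"stop"`).
#' @return A `lesion` list.
#' @export
lesion <- function(type = c("deletion", "insertion", "stop"), position,
                   length = 1L) {
  type <- match.arg(type)
  if (type == "stop") length <- 3L
  stopifnot(position >= 1, length >= 1)
  structure(list(type = type, position = as.integer(position),
                 length = as.integer(length)), class = "lesion")
}

.lesion_nt_range <- function(l) {
  if (l$type == "stop") {
    c(3L * l$position - 2L, 3L * l$position)
  } else if (l$type == "insertion") {
    c(l$position, l$position)  # insertion point
  } else {
    c(l$position, l$position + l$length - 1L)
  }
}

#' Recipe for a synthetic opsin coding sequence
#'
#' @param opsin_class Class of the sequence.
#' @param site_residues Named character vector: bovine site -> residue to
#'   plant (e.g. `c("86" = "F")`).
#' @param lesions List of [lesion()] objects; must not overlap one another
#'   or a planted site's codon.
#' @param seed Seed (used for insertion base content).
#' @return A `sequence_recipe` list.
#' @export
sequence_recipe <- function(opsin_class = "rh1", site_residues = NULL,
                            lesions = list(), seed = 1L) {
  opsin_class <- match.arg(opsin_class, .OPSIN_CLASSES)
  if (!is.null(site_residues)) {
    stopifnot(!is.null(names(site_residues)),
              all(site_residues %in% names(.CODON_FOR)))
  }
  ranges <- lapply(lesions, .lesion_nt_range)
  if (length(ranges) > 1L) {
    for (i in seq_len(length(ranges) - 1L)) {
      for (j in seq(i + 1L, length(ranges))) {
        if (ranges[[i]][1] <= ranges[[j]][2] &&
            ranges[[j]][1] <= ranges[[i]][2]) {
          stop("lesions overlap")
        }
      }
    }
  }
  structure(list(opsin_class = opsin_class, site_residues = site_residues,
                 lesions = lesions, seed = as.integer(seed)),
            class = "sequence_recipe")
}

#' Generate a synthetic opsin coding sequence
#'
#' Copies the reference CDS, replaces the codons at the requested
#' bovine-numbered tuning sites so they encode the planted residues, then
#' applies lesions. Ground truth records the planted protein positions and
#' each lesion's reference codon position, frame effect, and the verdict it
#' should produce under [evaluate_orf()].
#'
#' @param recipe A [sequence_recipe()].
#' @param reference Intact [opsin_sequence()] with CDS (default:
#'   [synthetic_reference_opsin()] of the recipe's class).
#' @return An [opsin_sequence()] carrying a `ground_truth` attribute.
#' @export
make_sequence <- function(recipe,
                          reference = synthetic_reference_opsin(
                            recipe$opsin_class)) {
  stopifnot(inherits(recipe, "sequence_recipe"))
  set.seed(recipe$seed)
  cds <- reference$cds
  map <- map_to_bovine_numbering(reference)
  planted <- integer(0)
  if (length(recipe$site_residues)) {
    sites <- as.integer(names(recipe$site_residues))
    for (i in seq_along(sites)) {
      qp <- map$query_pos[!is.na(map$bovine_pos) & map$bovine_pos == sites[i]]
      qp <- qp[!is.na(qp)]
      if (length(qp) != 1L) {
        stop("bovine site ", sites[i], " not alignable in reference")
      }
      codon_rng <- c(3L * qp - 2L, 3L * qp)
      for (l in recipe$lesions) {
        r <- .lesion_nt_range(l)
        if (r[1] <= codon_rng[2] && codon_rng[1] <= r[2]) {
          stop("requested residue at site ", sites[i],
               " overlaps a lesion; impossible to plant")
        }
      }
      substr(cds, codon_rng[1], codon_rng[2]) <-
        .CODON_FOR[[recipe$site_residues[i]]]
      planted[as.character(sites[i])] <- qp
    }
  }
  lesion_gt <- list()
  les <- recipe$lesions
  if (length(les)) {
    # apply right-to-left in reference nucleotide coordinates so earlier
    # lesion positions stay valid
    ord <- order(vapply(les, function(l) .lesion_nt_range(l)[1], integer(1)),
                 decreasing = TRUE)
    for (l in les[ord]) {
      if (l$type == "deletion") {
        cds <- paste0(substr(cds, 1L, l$position - 1L),
                      substr(cds, l$position + l$length, nchar(cds)))
      } else if (l$type == "insertion") {
        ins <- paste(sample(c("A", "C", "G", "T"), l$length, replace = TRUE),
                     collapse = "")
        cds <- paste0(substr(cds, 1L, l$position - 1L), ins,
                      substr(cds, l$position, nchar(cds)))
      } else {
        substr(cds, 3L * l$position - 2L, 3L * l$position) <- "TAA"
      }
    }
    lesion_gt <- lapply(les, function(l) {
      nt <- if (l$type == "stop") 3L * l$position - 2L else l$position
      list(type = l$type, ref_nt_position = nt,
           ref_codon_position = (nt - 1L) %/% 3L + 1L,
           length_nt = l$length,
           frame_effect = if (l$type == "stop") "stop"
                          else if (l$length %% 3L == 0L) "in-frame"
                          else "frameshift")
    })
  }
  frameshift <- any(vapply(lesion_gt, function(g)
    g$frame_effect == "frameshift", logical(1)))
  has_stop <- any(vapply(lesion_gt, function(g) g$type == "stop", logical(1)))
  big_del <- any(vapply(lesion_gt, function(g)
    g$type == "deletion" && g$frame_effect == "in-frame" &&
      g$length_nt >= 30L, logical(1)))
  expected_verdict <- if (frameshift || has_stop) "pseudogene"
                      else if (big_del) "nonfunctional_suspect"
                      else "intact"
  id <- paste0("syn_", recipe$opsin_class, "_",
               if (length(les) || length(planted)) "edit" else "copy")
  out <- opsin_sequence(id, cds = cds, species = "synthetic",
                        opsin_class = recipe$opsin_class)
  attr(out, "ground_truth") <- list(
    reference_id = reference$id,
    planted_sites = as.list(planted),
    site_residues = as.list(recipe$site_residues),
    lesions = lesion_gt,
    expected_verdict = expected_verdict,
    seed = recipe$seed)
  out
}

# ---------------------------------------------------------------------------
# counts

.SALMON_OPSINS <- c("rh1-1", "sws1-1", "sws2", "rh2-1", "rh2-2", "rh2-3",
                    "rh2-4", "lws1", "lws2", "lws3", "lws4")

#' Generate a synthetic developmental count table
#'
#' Negative-binomial counts over a gene-by-(stage x replicate) design with
#' stage-specific gene abundances and unequal library depths. Defaults
#' emulate a four-stage whole-embryo developmental series of the 11-gene
#' salmonid visual opsin repertoire with four replicates per stage.
#'
#' @param n_genes Number of genes (11 uses the salmonid opsin labels).
#' @param n_stages Number of developmental stages (>= 2).
#' @param n_reps Replicates per stage.
#' @param depth_range Library depth range, sampled uniformly per sample.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @param fold_change Optional planted effect
#'   `list(gene = <name or index>, fold = <x>)`: the gene's relative
#'   abundance rises geometrically from the first to the last stage by the
#'   given fold.
#' @param seed Seed.
#' @return A [count_matrix()] of raw counts with a `ground_truth` attribute
#'   (true per-stage proportions, depths, planted log2 fold change).
#' @export
make_counts <- function(n_genes = 11, n_stages = 4, n_reps = 4,
                        depth_range = c(1e5, 2e5), dispersion = 0.1,
                        fold_change = NULL, seed = 1L) {
  stopifnot(n_stages >= 2, n_reps >= 1, n_genes >= 1)
  set.seed(seed)
  genes <- if (n_genes == 11) .SALMON_OPSINS else
    paste0("gene", seq_len(n_genes))
  stages <- if (n_stages == 4) c("dd225", "dd320", "dd410", "dd800") else
    paste0("stage", seq_len(n_stages))
  base <- exp(rnorm(n_genes, 4, 1.5))
  trend <- rnorm(n_genes, 0, 0.4)
  mu <- outer(base, rep(1, n_stages)) *
    exp(outer(trend, seq_len(n_stages) - 1))
  rownames(mu) <- genes
  if (!is.null(fold_change)) {
    g <- if (is.character(fold_change$gene)) match(fold_change$gene, genes)
         else fold_change$gene
    stopifnot(!is.na(g))
    mu[g, ] <- mu[g, 1] * fold_change$fold^((seq_len(n_stages) - 1) /
                                              (n_stages - 1))
  }
  pi_gs <- sweep(mu, 2, colSums(mu), "/")
  counts <- matrix(0, n_genes, n_stages * n_reps)
  depths <- numeric(n_stages * n_reps)
  cn <- character(n_stages * n_reps)
  k <- 0L
  for (s in seq_len(n_stages)) for (r in seq_len(n_reps)) {
    k <- k + 1L
    depths[k] <- runif(1, depth_range[1], depth_range[2])
    counts[, k] <- rnbinom(n_genes, mu = pi_gs[, s] * depths[k],
                           size = 1 / dispersion)
    cn[k] <- paste0(stages[s], "_rep", r)
  }
  dimnames(counts) <- list(genes, cn)
  out <- count_matrix(counts)
  gt <- list(stage_proportions = pi_gs, stages = stages,
             stage_of_sample = rep(stages, each = n_reps),
             target_depths = setNames(depths, cn),
             dispersion = dispersion, seed = seed)
  if (!is.null(fold_change)) {
    g <- if (is.character(fold_change$gene)) match(fold_change$gene, genes)
         else fold_change$gene
    gt$planted <- list(gene = genes[g], fold = fold_change$fold,
                       expected_log2fc = unname(log2(pi_gs[g, n_stages] /
                                                       pi_gs[g, 1])))
  }
  attr(out, "ground_truth") <- gt
  out
}
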