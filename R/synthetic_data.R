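#' @title Synthetic data with known ground truth
#'
#' @description
#' Download-free, seeded generators for every pipeline stage: an analytic
#' catalytic-pocket fixture whose reference geometry reproduces the four
#' anchor distances of the crystal complex exactly, labelled pose clouds
#' (rigid in-pocket perturbations plus displaced decoys), initial-velocity
#' datasets under the Michaelis-Menten / competitive / non-competitive
#' models with multiplicative Gaussian noise, and replicate ddG tables.
#' Every generator is a deterministic function of its arguments including
#' the seed.
#' @name synthetic-data
NULL

.fixture_ligand_atoms <- function() {
  # (2S,3S)-3-methylaspartate heavy atoms with idealised bond lengths
  # (C-C 1.51, C-O 1.25, C-N 1.49 Angstrom), laid out so that the
  # position-4 carboxyl faces the anchor side.
  coords <- rbind(
    C4  = c(0.00,  0.00, 0.00),
    O4A = c(-0.60, 1.10, 0.00),
    O4B = c(-0.60, -1.10, 0.00),
    C3  = c(1.52,  0.00, 0.00),
    CM  = c(2.03, -0.75, 1.21),
    C2  = c(2.03,  1.42, 0.00),
    N2  = c(3.13,  1.42, 1.00),
    C1  = c(3.03,  2.55, 0.00),
    O1A = c(3.63,  3.65, 0.00),
    O1B = c(4.13,  1.95, 0.00))
  elem <- c("C", "O", "O", "C", "C", "C", "N", "C", "O", "O")
  new_atom_table(record = rep("HETATM", nrow(coords)),
                 name = rownames(coords), alt = "", resid = "3MA",
                 chain = "B", resno = 501L, insert = "",
                 x = coords[, 1], y = coords[, 2], z = coords[, 3],
                 element = elem)
}

.fixture_receptor_atoms <- function(ref_dist = c(4.16, 3.08, 2.75, 2.2)) {
  lig <- .fixture_ligand_atoms()
  at <- function(n) as.numeric(lig[lig$name == n, c("x", "y", "z")])
  O4A <- at("O4A"); O4B <- at("O4B"); C3 <- at("C3"); CM <- at("CM")
  N2 <- at("N2"); O1A <- at("O1A"); O1B <- at("O1B")
  # Anchor atoms placed on single axes from their reference ligand atoms so
  # each printed distance is met exactly and the partner oxygen is farther.
  rows <- list(
    # resid chain resno  name element  xyz
    list("PHE", 170L, "CZ",  "C", CM + c(0, -3.25, 0)),
    list("PHE", 170L, "CA",  "C", CM + c(0, -6.75, 0)),
    list("GLN", 172L, "NE2", "N", O1A + c(0, 0, 3.00)),
    list("GLN", 172L, "CA",  "C", O1A + c(0, 0, 6.40)),
    list("HIS", 194L, "NE2", "N", O4B + c(0, -ref_dist[3], 0)),
    list("HIS", 194L, "CA",  "C", O4B + c(0, -ref_dist[3] - 3.2, 0)),
    list("GLN", 329L, "NE2", "N", O4A + c(0, 0, ref_dist[2])),
    list("GLN", 329L, "CA",  "C", O4A + c(0, 0, ref_dist[2] + 3.4)),
    list("LYS", 331L, "NZ",  "N", C3 + c(0, 0, -ref_dist[1])),
    list("LYS", 331L, "CA",  "C", C3 + c(0, 0, -ref_dist[1] - 3.4)),
    list("THR", 360L, "OG1", "O", N2 + c(0, 0, 2.90)),
    list("THR", 360L, "CA",  "C", N2 + c(0, 0, 6.20)),
    list("CYS", 361L, "N",   "N", O1B + c(0, 0, -3.00)),
    list("CYS", 361L, "CA",  "C", O1B + c(0, 0, -6.30)),
    list("LEU", 384L, "CD1", "C", CM + c(0, 0, 4.00)),
    list("LEU", 384L, "CA",  "C", CM + c(0, 0, 7.60)),
    list("TYR", 356L, "CE1", "C", CM + c(2.9, -2.9, 0.8)),
    list("TYR", 356L, "CA",  "C", CM + c(6.0, -6.0, 1.6)))
  tab <- do.call(rbind, lapply(rows, function(r)
    new_atom_table("ATOM", r[[3]], "", r[[1]], "B", r[[2]], "",
                   r[[5]][1], r[[5]][2], r[[5]][3], r[[4]])))
  mg <- O4A + c(0, ref_dist[4], 0)
  rbind(tab,
        new_atom_table("HETATM", "MG", "", "MG", "B", 400L, "",
                       mg[1], mg[2], mg[3], "MG"))
}

#' Analytic catalytic-pocket fixture
#'
#' A self-contained synthetic stand-in for the crystal complex: a minimal
#' receptor carrying the four anchor atoms (K331 NZ, Q329 NE2, H194 NE2,
#' Mg2+) plus the pocket residues discussed for MAL (Q172, T360, C361 and
#' the hydrophobic pocket L384/F170/Y356), and a reference
#' 3-methylaspartate pose. The geometry is constructed — not fitted — so
#' that [measure_distances()] on the reference pose returns exactly the
#' four anchor distances of the reference crystal structure
#' (4.16, 3.08, 2.75, 2.2 Å). Fully deterministic; no randomness.
#'
#' This fixture is synthetic: it reproduces the published pocket distances
#' and contact pattern by construction and stands in for the real crystal
#' structure in download-free runs (see [fetch_reference()]).
#'
#' @param reference_distances the four target anchor distances, Å
#' @return list with `receptor` ([mal_structure()]), `reference`
#'   ([ligand_pose()]), `anchors` ([pocket_anchors()]), `template`
#'   (the 3-methylaspartate [ligand_template()]) and `pocket_residues`
#' @export
make_pocket_fixture <- function(reference_distances = c(4.16, 3.08, 2.75, 2.2)) {
  receptor <- mal_structure(.fixture_receptor_atoms(reference_distances),
                            id = "synthetic-pocket")
  reference <- ligand_pose(.fixture_ligand_atoms(), pose_id = 1L,
                           ligand_name = "3MA")
  anchors <- resolve_anchors(receptor, chain = "B",
                             reference_distances = reference_distances)
  pocket <- data.frame(
    chain = "B",
    resno = c(170L, 172L, 194L, 329L, 331L, 356L, 360L, 361L, 384L, 400L))
  list(receptor = receptor, reference = reference, anchors = anchors,
       template = mal_template("3MA"), pocket_residues = pocket)
}

.rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(a[1]^2 * C + c_,        a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
           a[2] * a[1] * C + a[3] * s, a[2]^2 * C + c_,        a[2] * a[3] * C - a[1] * s,
           a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3]^2 * C + c_),
         nrow = 3, byrow = TRUE)
}

.random_unit_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.transform_pose <- function(pose, rotation, translation, centre) {
  xyz <- as.matrix(pose$atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, centre) %*% t(rotation)
  xyz <- sweep(sweep(xyz, 2, centre, `+`), 2, translation, `+`)
  pose$atoms$x <- xyz[, 1]; pose$atoms$y <- xyz[, 2]; pose$atoms$z <- xyz[, 3]
  pose
}

#' Generate a labelled docking-pose cloud
#'
#' In-pocket poses are small rigid-body perturbations of the reference
#' (rotation up to `rotation_max` degrees about the pose centroid,
#' isotropic Gaussian translation); decoys are displaced by `decoy_offset`
#' along random directions, far beyond the pocket cutoff, so ground-truth
#' labels are unambiguous by construction. Default perturbation sizes are
#' chosen from the geometric margin of the pocket criterion (the tightest
#' in-pocket distance sits 0.92 Å below the 4 Å cutoff) so that every
#' in-pocket pose passes the filter for any seed.
#'
#' @param reference reference [ligand_pose()]
#' @param n_in_pocket,n_decoys pose counts
#' @param rotation_max maximum rotation, degrees
#' @param translation_sigma per-axis translation standard deviation, Å
#' @param decoy_offset decoy displacement, Å (must exceed the pocket cutoff
#'   plus the largest reference distance)
#' @param score_mean,score_sd synthetic docking scores (in-pocket poses are
#'   drawn 1 unit better than decoys)
#' @param shuffle permute pose order (labels follow the poses)
#' @param seed integer RNG seed
#' @return list with `poses` (list of [ligand_pose()]) and `truth`
#'   (data frame `pose_id`, `label`, `rotation_deg`, `translation`)
#' @export
generate_poses <- function(reference, n_in_pocket = 40L, n_decoys = 60L,
                           rotation_max = 3, translation_sigma = 0.1,
                           decoy_offset = 20, score_mean = -5, score_sd = 0.5,
                           shuffle = TRUE, seed = 1L) {
  stopifnot(n_in_pocket >= 0L, n_decoys >= 0L, decoy_offset > 0)
  set.seed(seed)
  centre <- colMeans(as.matrix(reference$atoms[, c("x", "y", "z")]))
  n <- n_in_pocket + n_decoys
  label <- rep(c("in_pocket", "decoy"), c(n_in_pocket, n_decoys))
  poses <- vector("list", n)
  truth <- data.frame(pose_id = seq_len(n), label = label,
                      rotation_deg = NA_real_, translation = NA_real_)
  for (i in seq_len(n)) {
    angle <- stats::runif(1, 0, rotation_max) * pi / 180
    rot <- .rotation_matrix(.random_unit_vector(), angle)
    tr <- stats::rnorm(3, sd = translation_sigma)
    if (label[i] == "decoy") tr <- tr + decoy_offset * .random_unit_vector()
    p <- .transform_pose(reference, rot, tr, centre)
    p$pose_id <- i
    p$docking_score <- stats::rnorm(1, score_mean +
                                      (label[i] == "decoy"), score_sd)
    poses[[i]] <- p
    truth$rotation_deg[i] <- angle * 180 / pi
    truth$translation[i] <- sqrt(sum(tr^2))
  }
  if (shuffle && n > 1L) {
    ord <- sample.int(n)
    poses <- poses[ord]
    truth <- truth[ord, , drop = FALSE]
    for (i in seq_len(n)) {
      poses[[i]]$pose_id <- i
      truth$pose_id[i] <- i
    }
    rownames(truth) <- NULL
  }
  list(poses = poses, truth = truth)
}

.kinetic_model_value <- function(model, S, I, kcat, Km, Ki) {
  switch(model,
         mm = kcat * S / (Km + S),
         competitive = kcat * S / (Km * (1 + I / Ki) + S),
         noncompetitive = kcat * S / ((1 + I / Ki) * (Km + S)))
}

#' Generate an initial-velocity dataset
#'
#' Velocities follow the chosen rate law with multiplicative Gaussian noise
#' `v_obs = v * (1 + e)`, `e ~ N(0, noise_cv^2)` — initial-velocity error
#' scales with signal in plate-reader assays. Defaults mirror the reference
#' assay: the natural-substrate constants `kcat` 17.6 1/s, `Km` 1.0 mM and
#' a substrate grid spanning 1.25-15 mM.
#'
#' @param model `"mm"`, `"competitive"` or `"noncompetitive"`
#' @param kcat,Km,Ki generating parameters (`Ki` required for inhibition
#'   models; mM)
#' @param S_grid substrate concentrations, mM
#' @param I_levels inhibitor concentrations, mM (0 always included)
#' @param replicates replicates per (S, I) point
#' @param noise_cv coefficient of variation of the multiplicative noise
#' @param seed integer RNG seed
#' @return data frame `substrate_mM`, `inhibitor_mM`, `replicate`,
#'   `velocity`; the generating parameters are attached as attribute
#'   `"truth"`
#' @export
generate_kinetics <- function(model = c("mm", "competitive", "noncompetitive"),
                              kcat = 17.6, Km = 1.0, Ki = NULL,
                              S_grid = c(1.25, 2.5, 5, 7.5, 10, 15),
                              I_levels = 0, replicates = 3L,
                              noise_cv = 0.02, seed = 1L) {
  model <- match.arg(model)
  stopifnot(kcat > 0, Km > 0, all(S_grid > 0), all(I_levels >= 0),
            replicates >= 1L, noise_cv >= 0)
  if (model != "mm") {
    if (is.null(Ki) || Ki <= 0)
      stop("inhibition models need Ki > 0", call. = FALSE)
  } else Ki <- Inf
  I_levels <- sort(unique(c(0, I_levels)))
  set.seed(seed)
  grid <- expand.grid(substrate_mM = S_grid, inhibitor_mM = I_levels,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  v <- .kinetic_model_value(model, grid$substrate_mM, grid$inhibitor_mM,
                            kcat, Km, Ki)
  grid$velocity <- v * (1 + stats::rnorm(nrow(grid), sd = noise_cv))
  attr(grid, "truth") <- list(model = model, kcat = kcat, Km = Km, Ki = Ki,
                              noise_cv = noise_cv, seed = seed)
  grid
}

.AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Generate a replicate ddG saturation-scan table
#'
#' Each position receives all 19 substitutions. True per-mutation ddG
#' values are drawn from a declared two-component mixture — neutral
#' `N(0, 0.5)`, destabilising `N(3, 1)` kcal/mol — and each run observes
#' the truth plus `N(0, run_sd)` noise (0.8 kcal/mol, the typical
#' prediction error of structure-based stability calculators).
#'
#' @param positions residue positions to scan
#' @param wild_types 1-letter wild-type residues (recycled/sampled if `NULL`)
#' @param runs number of replicate runs
#' @param run_sd per-run noise, kcal/mol
#' @param planted_fraction probability that a mutation is truly
#'   destabilising
#' @param seed integer RNG seed
#' @return data frame `position`, `wild_type`, `mutant`, `run1..runN`, with
#'   `true_ddg` and `true_label` appended and the configuration attached as
#'   attribute `"truth"`
#' @export
generate_ddg_table <- function(positions, wild_types = NULL, runs = 5L,
                               run_sd = 0.8, planted_fraction = 0.3,
                               seed = 1L) {
  stopifnot(length(positions) >= 1L, runs >= 1L, run_sd >= 0,
            planted_fraction >= 0, planted_fraction <= 1)
  set.seed(seed)
  if (is.null(wild_types))
    wild_types <- sample(.AA1, length(positions), replace = TRUE)
  rows <- lapply(seq_along(positions), function(i) {
    wt <- wild_types[i]
    muts <- setdiff(.AA1, wt)
    destab <- stats::runif(length(muts)) < planted_fraction
    truth <- ifelse(destab, stats::rnorm(length(muts), 3, 1),
                    stats::rnorm(length(muts), 0, 0.5))
    runs_m <- matrix(truth + stats::rnorm(length(muts) * runs, sd = run_sd),
                     nrow = length(muts))
    colnames(runs_m) <- paste0("run", seq_len(runs))
    cbind(data.frame(position = positions[i], wild_type = wt, mutant = muts),
          as.data.frame(runs_m),
          data.frame(true_ddg = truth,
                     true_label = ifelse(destab, "destabilizing", "neutral")))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- list(runs = runs, run_sd = run_sd,
                             planted_fraction = planted_fraction, seed = seed)
  out
}

#' Write a kinetics or ddG table as CSV
#'
#' @param table data frame from [generate_kinetics()] or
#'   [generate_ddg_table()]
#' @param path output CSV path
#' @param truth_json optional path for the JSON ground-truth record
#' @return the table, invisibly
#' @export
write_table_csv <- function(table, path, truth_json = NULL) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  truth <- attr(table, "truth")
  if (!is.null(truth_json) && !is.null(truth)) {
    truth <- lapply(truth, function(x) if (identical(x, Inf)) "Inf" else x)
    jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, digits = NA)
  }
  invisible(table)
}
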