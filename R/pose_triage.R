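#' @title Two-criterion docking-pose triage
#'
#' @description
#' Docked poses of candidate MAL substrates are evaluated against the
#' geometry of the natural substrate in the catalytic pocket:
#'
#' 1. *Four-anchor distance filter.* Distances from the pose to four anchor
#'    atoms — the catalytic lysine N-zeta (K331), the glutamine side-chain
#'    amide nitrogen (Q329), the histidine epsilon nitrogen (H194) and the
#'    catalytic Mg2+ — with the carboxylate two-fold symmetry handled by
#'    taking, for each of the three oxygen-directed distances, the shorter of
#'    the two carboxyl oxygens. A pose is "inside the pocket" when at least
#'    `min_pass` (default 3) of the four distances are strictly below the
#'    cutoff (default 4 Å). In the reference crystal geometry the four
#'    distances are 4.16, 3.08, 2.75 and 2.2 Å, so the crystal substrate
#'    itself passes with exactly 3 of 4.
#' 2. *Common-scaffold RMSD.* Positional (no superposition) RMSD over the six
#'    scaffold atoms shared by all the ligands — the Mg-facing carboxyl carbon,
#'    its two oxygens and the three following backbone carbons — minimised
#'    over the symmetry-equivalent atom mappings (carboxyl-group choice for
#'    dicarboxylic ligands, oxygen swap within a carboxylate).
#'
#' The pose with the lowest scaffold RMSD among the in-pocket poses is
#' selected as the representative binding mode of a ligand.
#' @name pose-triage
NULL

.dist <- function(p, q) sqrt(sum((p - q)^2))

#' Define the four catalytic-pocket anchor atoms
#'
#' Either pass the four atom rows directly, or resolve them from a receptor
#' structure with [resolve_anchors()].
#'
#' @param k331_nz,q329_amide_n,h194_eps_n,mg one-row atom tables (as returned
#'   by [get_atom()]) for the lysine N-zeta, glutamine side-chain amide N,
#'   histidine epsilon N and the Mg2+ ion
#' @param cutoff distance cutoff in Å for the pocket filter
#' @param min_pass minimum number of the four distances that must fall
#'   strictly below `cutoff`
#' @param reference_distances the four anchor distances measured on the
#'   reference crystal complex, Å (reported alongside results for provenance)
#' @return an object of class `pocket_anchors`
#' @export
pocket_anchors <- function(k331_nz, q329_amide_n, h194_eps_n, mg,
                           cutoff = 4.0, min_pass = 3L,
                           reference_distances = c(4.16, 3.08, 2.75, 2.2)) {
  stopifnot(cutoff > 0, min_pass >= 1L, min_pass <= 4L,
            length(reference_distances) == 4L)
  structure(list(k331_nz = .coords(k331_nz),
                 q329_amide_n = .coords(q329_amide_n),
                 h194_eps_n = .coords(h194_eps_n),
                 mg = .coords(mg),
                 cutoff = cutoff, min_pass = as.integer(min_pass),
                 reference_distances = reference_distances),
            class = "pocket_anchors")
}

#' Resolve the pocket anchors on a receptor structure
#'
#' @param receptor a [mal_structure()]
#' @param chain receptor chain carrying the catalytic site
#' @param k331,q329,h194 residue numbers of the anchor residues
#' @param mg_resno residue number of the Mg2+ ion; `NULL` finds the first
#'   magnesium HETATM in the chain
#' @param ... passed to [pocket_anchors()] (cutoff, min_pass, ...)
#' @return a `pocket_anchors` object
#' @export
resolve_anchors <- function(receptor, chain = "B", k331 = 331L, q329 = 329L,
                            h194 = 194L, mg_resno = NULL, ...) {
  if (is.null(mg_resno)) {
    a <- receptor$atoms
    hit <- which(a$chain == chain & a$element == "MG")
    if (!length(hit))
      stop("no magnesium ion found in chain ", chain, call. = FALSE)
    mg_resno <- a$resno[hit[1]]
  }
  pocket_anchors(get_atom(receptor, chain, k331, "NZ"),
                 get_atom(receptor, chain, q329, "NE2"),
                 get_atom(receptor, chain, h194, "NE2"),
                 get_atom(receptor, chain, mg_resno, "MG"), ...)
}

#' Measure the four anchor distances for a pose
#'
#' For dicarboxylic ligands the carboxyl whose carbon lies nearer the Mg2+
#' anchor is used and recorded as `carboxyl_choice`. Each oxygen-directed
#' distance (Q329, H194, Mg) is the minimum over the two oxygens of that
#' carboxylate; the K331 distance is taken to the abstraction carbon of the
#' chosen orientation.
#'
#' @param pose a [ligand_pose()]
#' @param template the pose's [ligand_template()]
#' @param anchors a [pocket_anchors()]
#' @return a one-row data frame: `d_k331_c3`, `d_q329_o`, `d_h194_o`,
#'   `d_mg_o` (Å) and `carboxyl_choice`
#' @export
measure_distances <- function(pose, template, anchors) {
  stopifnot(inherits(template, "ligand_template"),
            inherits(anchors, "pocket_anchors"))
  cc <- vapply(template$carboxyls, function(cx)
    .dist(.pose_atom(pose, cx[1]), anchors$mg), 0)
  choice <- which.min(cc)
  cx <- template$carboxyls[[choice]]
  o1 <- .pose_atom(pose, cx[2]); o2 <- .pose_atom(pose, cx[3])
  c3 <- .pose_atom(pose, template$abstraction[choice])
  min_o <- function(anchor) min(.dist(o1, anchor), .dist(o2, anchor))
  data.frame(d_k331_c3 = .dist(c3, anchors$k331_nz),
             d_q329_o = min_o(anchors$q329_amide_n),
             d_h194_o = min_o(anchors$h194_eps_n),
             d_mg_o = min_o(anchors$mg),
             carboxyl_choice = choice)
}

#' Apply the pocket criterion to a distance set
#'
#' Counts distances strictly below the cutoff; a pose is in the pocket when
#' at least `min_pass` of the four are.
#'
#' @param distances one-row data frame from [measure_distances()]
#' @param anchors a [pocket_anchors()] (supplies cutoff and min_pass)
#' @return list with `n_below_cutoff` and `in_pocket`
#' @export
pose_in_pocket <- function(distances, anchors) {
  d <- as.numeric(distances[1, c("d_k331_c3", "d_q329_o",
                                 "d_h194_o", "d_mg_o")])
  n <- sum(d < anchors$cutoff)
  list(n_below_cutoff = n, in_pocket = n >= anchors$min_pass)
}

#' Symmetry-corrected common-scaffold RMSD
#'
#' Positional root-mean-square deviation over the six mapped scaffold atoms
#' between a pose and the reference substrate, in the shared receptor frame
#' (no superposition). The RMSD is minimised over the pose's carboxyl-group
#' choice (dicarboxylic ligands) and the two-fold oxygen permutation within
#' the carboxylate, so that poses presenting either carboxyl group towards
#' the Mg2+ are not discriminated.
#'
#' @param pose a [ligand_pose()]
#' @param reference the reference [ligand_pose()] (crystal substrate)
#' @param template the pose's [ligand_template()]
#' @param reference_template the reference's template (default: the
#'   3-methylaspartate template)
#' @param reference_choice which carboxyl orientation of the reference is
#'   Mg-facing (default 1, the position-4 carboxyl of 3-methylaspartate)
#' @return list with `rmsd` (Å) and `mapping` (carboxyl choice and oxygen
#'   order used)
#' @export
scaffold_rmsd <- function(pose, reference, template,
                          reference_template = mal_template("3MA"),
                          reference_choice = 1L) {
  ref <- .scaffold_coords(reference, reference_template, reference_choice)
  best <- NULL
  for (choice in seq_along(template$carboxyls)) {
    for (swap in list(c(1L, 2L), c(2L, 1L))) {
      xyz <- .scaffold_coords(pose, template, choice, swap)
      r <- sqrt(mean(rowSums((xyz - ref)^2)))
      if (is.null(best) || r < best$rmsd)
        best <- list(rmsd = r,
                     mapping = sprintf("carboxyl=%d;oxygens=%s", choice,
                                       if (swap[1] == 1L) "direct" else "swapped"))
    }
  }
  best
}

#' Select the representative pose of a ligand
#'
#' Among in-pocket poses, the one with the lowest scaffold RMSD relative to
#' the reference substrate. Ties are broken by better (lower) docking score,
#' then by lower pose id. When no pose is in the pocket an explicit
#' no-selection outcome is returned rather than an error.
#'
#' @param results data frame of per-pose triage results (as built by
#'   [triage_ligand()]), with columns `pose_id`, `in_pocket`,
#'   `scaffold_rmsd`, `docking_score`
#' @return list with `selected` (one-row data frame or `NULL`) and `reason`
#' @export
select_pose <- function(results) {
  if (!is.data.frame(results) || !nrow(results))
    stop("select_pose needs at least one triage result", call. = FALSE)
  inp <- results[results$in_pocket, , drop = FALSE]
  if (!nrow(inp))
    return(list(selected = NULL, reason = "no pose inside the binding pocket"))
  score <- inp$docking_score
  score[is.na(score)] <- Inf                       # unscored poses lose ties
  ord <- order(inp$scaffold_rmsd, score, inp$pose_id)
  list(selected = inp[ord[1], , drop = FALSE], reason = "lowest scaffold RMSD")
}

#' Fraction of poses inside the binding pocket
#'
#' @param results data frame with logical column `in_pocket`
#' @return fraction in `[0, 1]`
#' @export
percent_in_pocket <- function(results) {
  if (!is.data.frame(results) || !nrow(results))
    stop("percent_in_pocket needs at least one triage result", call. = FALSE)
  mean(results$in_pocket)
}

#' Triage a full pose set against a receptor
#'
#' Composes [measure_distances()], [pose_in_pocket()], [scaffold_rmsd()],
#' [select_pose()] and [percent_in_pocket()] into one report.
#'
#' @param receptor a [mal_structure()] (used when `anchors` is `NULL`)
#' @param poses list of [ligand_pose()]
#' @param template the poses' [ligand_template()]
#' @param reference reference [ligand_pose()] for the RMSD criterion
#' @param reference_template template of the reference ligand
#' @param anchors a [pocket_anchors()]; `NULL` resolves the default anchors
#'   on `receptor` via [resolve_anchors()]
#' @param chain receptor chain for anchor resolution
#' @return an object of class `mal_triage` with elements `results` (per-pose
#'   data frame), `selection`, `percent_in_pocket` and `anchors`
#' @export
triage_ligand <- function(receptor, poses, template, reference,
                          reference_template = mal_template("3MA"),
                          anchors = NULL, chain = "B") {
  if (!length(poses)) stop("empty pose set", call. = FALSE)
  if (inherits(poses, "ligand_pose")) poses <- list(poses)
  if (is.null(anchors)) anchors <- resolve_anchors(receptor, chain = chain)
  rows <- lapply(poses, function(p) {
    d <- measure_distances(p, template, anchors)
    crit <- pose_in_pocket(d, anchors)
    r <- scaffold_rmsd(p, reference, template, reference_template)
    cbind(data.frame(pose_id = p$pose_id,
                     docking_score = p$docking_score), d,
          data.frame(n_below_cutoff = crit$n_below_cutoff,
                     in_pocket = crit$in_pocket,
                     scaffold_rmsd = r$rmsd, mapping = r$mapping))
  })
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results,
                 selection = select_pose(results),
                 percent_in_pocket = percent_in_pocket(results),
                 anchors = anchors),
            class = "mal_triage")
}

#' @export
print.mal_triage <- function(x, ...) {
  sel <- x$selection$selected
  cat(sprintf("<mal_triage: %d poses, %.0f%% in pocket; selected pose: %s>\n",
              nrow(x$results), 100 * x$percent_in_pocket,
              if (is.null(sel)) "none" else
                sprintf("%d (RMSD %.2f A)", sel$pose_id, sel$scaffold_rmsd)))
  invisible(x)
}

#' Write a triage report
#'
#' Writes the per-pose table as TSV and the summary (selected pose, percent
#' in pocket, anchor settings) as JSON.
#'
#' @param report a `mal_triage` object
#' @param tsv,json output paths (`NULL` to skip either)
#' @return the report, invisibly
#' @export
write_triage <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "mal_triage"))
  if (!is.null(tsv))
    utils::write.table(report$results, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json)) {
    sel <- report$selection$selected
    jsonlite::write_json(
      list(selected_pose = if (is.null(sel)) NULL else as.list(sel),
           selection_reason = report$selection$reason,
           percent_in_pocket = report$percent_in_pocket,
           cutoff = report$anchors$cutoff,
           min_pass = report$anchors$min_pass,
           reference_distances = report$anchors$reference_distances),
      json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(report)
}
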