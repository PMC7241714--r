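#' Declare the common scaffold of a MAL ligand
#'
#' Pose triage needs, for every ligand, the carboxyl group(s) that can
#' coordinate the catalytic Mg2+, the three backbone carbons that follow each
#' carboxyl carbon, the proton-abstraction carbon, and the amino nitrogens.
#' These are declared explicitly per ligand rather than perceived from bonds:
#' the scaffold atoms (carboxyl C, its two O and the three following backbone
#' C) are exactly the six atoms shared by all the substrates considered, and
#' hand declaration keeps the package free of cheminformatics machinery.
#'
#' For a ligand with two carboxyl groups both orientations are declared; the
#' triage code resolves the symmetry (which carboxyl faces the Mg2+, and the
#' two-fold oxygen permutation within a carboxylate) at measurement time.
#'
#' @param ligand_name free-text name
#' @param carboxyls list of character(3): carboxyl carbon then its two oxygens,
#'   one entry per possible Mg-facing orientation
#' @param backbones list of character(3): the three backbone carbons following
#'   the matching carboxyl carbon, nearest first
#' @param abstraction character, one label per carboxyl choice: the carbon
#'   whose proton the catalytic lysine abstracts (the first backbone carbon
#'   after the Mg-facing carboxyl carbon)
#' @param amino_nitrogens labels of amino-group nitrogens
#' @param apolar_carbons labels of carbons treated as apolar by the
#'   interaction fingerprint (methyl/methylene carbons)
#' @return an object of class `ligand_template`
#' @export
ligand_template <- function(ligand_name, carboxyls, backbones, abstraction,
                            amino_nitrogens = character(),
                            apolar_carbons = character()) {
  stopifnot(is.list(carboxyls), is.list(backbones),
            length(carboxyls) >= 1L, length(carboxyls) <= 2L,
            length(backbones) == length(carboxyls),
            length(abstraction) == length(carboxyls))
  for (cx in carboxyls) stopifnot(length(cx) == 3L)
  for (bb in backbones) stopifnot(length(bb) == 3L)
  structure(list(ligand_name = ligand_name, carboxyls = carboxyls,
                 backbones = backbones, abstraction = abstraction,
                 amino_nitrogens = amino_nitrogens,
                 apolar_carbons = apolar_carbons),
            class = "ligand_template")
}

#' @export
print.ligand_template <- function(x, ...) {
  cat(sprintf("<ligand_template '%s': %d carboxyl orientation(s)>\n",
              x$ligand_name, length(x$carboxyls)))
  invisible(x)
}

#' Built-in ligand templates
#'
#' Scaffold declarations for the natural substrate and the six investigated
#' ligands. Carbon numbering follows the usual chemical numbering of each
#' compound; the Mg-facing carboxyl of 3-methylaspartate is the position-4
#' group, and the abstraction carbon is C3 (the carbon carrying the methyl
#' group), whose counterpart in beta-lysine is C2.
#'
#' @param name one of `"3MA"` (3-methylaspartate), `"ASP"` (aspartate),
#'   `"BLY"` (beta-lysine), `"LYS"` (lysine), `"BGL"` (beta-glutamate),
#'   `"ABU"` (3-aminobutanoate), `"2AA"` (2-aminoadipate)
#' @return a [ligand_template()]
#' @export
mal_template <- function(name = c("3MA", "ASP", "BLY", "LYS", "BGL",
                                  "ABU", "2AA")) {
  name <- match.arg(name)
  switch(name,
    "3MA" = ligand_template("3-methylaspartate",
      carboxyls   = list(c("C4", "O4A", "O4B"), c("C1", "O1A", "O1B")),
      backbones   = list(c("C3", "C2", "C1"),   c("C2", "C3", "C4")),
      abstraction = c("C3", "C2"),
      amino_nitrogens = "N2",
      apolar_carbons  = c("C3", "CM")),
    "ASP" = ligand_template("aspartate",
      carboxyls   = list(c("C4", "O4A", "O4B"), c("C1", "O1A", "O1B")),
      backbones   = list(c("C3", "C2", "C1"),   c("C2", "C3", "C4")),
      abstraction = c("C3", "C2"),
      amino_nitrogens = "N2",
      apolar_carbons  = "C3"),
    "BLY" = ligand_template("beta-lysine",
      carboxyls   = list(c("C1", "O1A", "O1B")),
      backbones   = list(c("C2", "C3", "C4")),
      abstraction = "C2",
      amino_nitrogens = c("N3", "N6"),
      apolar_carbons  = c("C2", "C4", "C5")),
    "LYS" = ligand_template("lysine",
      carboxyls   = list(c("C1", "O1A", "O1B")),
      backbones   = list(c("C2", "C3", "C4")),
      abstraction = "C2",
      amino_nitrogens = c("N2", "N6"),
      apolar_carbons  = c("C3", "C4", "C5")),
    "BGL" = ligand_template("beta-glutamate",
      carboxyls   = list(c("C1", "O1A", "O1B"), c("C5", "O5A", "O5B")),
      backbones   = list(c("C2", "C3", "C4"),   c("C4", "C3", "C2")),
      abstraction = c("C2", "C4"),
      amino_nitrogens = "N3",
      apolar_carbons  = c("C2", "C4")),
    "ABU" = ligand_template("3-aminobutanoate",
      carboxyls   = list(c("C1", "O1A", "O1B")),
      backbones   = list(c("C2", "C3", "C4")),
      abstraction = "C2",
      amino_nitrogens = "N3",
      apolar_carbons  = c("C2", "C4")),
    "2AA" = ligand_template("2-aminoadipate",
      carboxyls   = list(c("C1", "O1A", "O1B"), c("C6", "O6A", "O6B")),
      backbones   = list(c("C2", "C3", "C4"),   c("C5", "C4", "C3")),
      abstraction = c("C2", "C5"),
      amino_nitrogens = "N2",
      apolar_carbons  = c("C3", "C4", "C5")))
}

#' All built-in template names
#' @return character vector of names accepted by [mal_template()]
#' @export
mal_template_names <- function() c("3MA", "ASP", "BLY", "LYS", "BGL",
                                   "ABU", "2AA")

# Resolve a template atom label on a pose; error names the label.
.pose_atom <- function(pose, label) {
  hit <- which(toupper(pose$atoms$name) == toupper(label))
  if (length(hit) != 1L)
    stop(sprintf("template label '%s' does not resolve on pose %d of '%s'",
                 label, pose$pose_id, pose$ligand_name), call. = FALSE)
  as.numeric(pose$atoms[hit, c("x", "y", "z")])
}

# The 6-atom scaffold (C, O, O, B1, B2, B3) for one carboxyl choice and one
# oxygen order, as a 6 x 3 coordinate matrix.
.scaffold_coords <- function(pose, template, choice, oxy_order = c(1L, 2L)) {
  cx <- template$carboxyls[[choice]]
  labels <- c(cx[1], cx[1 + oxy_order], template$backbones[[choice]])
  t(vapply(labels, .pose_atom, numeric(3), pose = pose))
}
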