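#' @title Reduced protein-ligand interaction fingerprints
#'
#' @description
#' Receptor-ligand atomic contacts are classified into a reduced category
#' set per binding-pocket residue: `hydrogen_bond`, `ionic`, `hydrophobic`
#' and `proximal`, in that precedence order. This is a deliberately
#' simplified scheme — full interaction calculators distinguish over a dozen
#' categories using atom typing and angle terms; here only the categories
#' actually discussed for the MAL pocket are kept, with distance-based rules
#' (an angle term applies to hydrogen bonds only when explicit hydrogens are
#' present, which docked heavy-atom poses normally lack).
#'
#' Default rules, applied to every (pocket-residue atom, ligand atom) pair
#' within 5 Å, highest precedence first:
#' * hydrogen_bond: both atoms N or O, distance <= 3.5 Å
#' * ionic: oppositely charged group atoms, distance <= 4.0 Å
#' * hydrophobic: both atoms apolar carbons, distance <= 4.5 Å
#' * proximal: any remaining pair, distance <= 5.0 Å
#' @name interaction-fingerprint
NULL

#' Default contact rules
#'
#' @param hbond_max,ionic_max,hydrophobic_max,proximal_max distance
#'   thresholds, Å
#' @param his_charged treat histidine ring nitrogens as positively charged
#' @return an object of class `contact_rules`
#' @export
contact_rules <- function(hbond_max = 3.5, ionic_max = 4.0,
                          hydrophobic_max = 4.5, proximal_max = 5.0,
                          his_charged = FALSE) {
  stopifnot(hbond_max > 0, ionic_max > 0, hydrophobic_max > 0,
            proximal_max > 0)
  structure(list(hbond_max = hbond_max, ionic_max = ionic_max,
                 hydrophobic_max = hydrophobic_max,
                 proximal_max = proximal_max, his_charged = his_charged),
            class = "contact_rules")
}

# Residue/atom-name lookup of formal charge carriers; no pKa model.
.residue_charge <- function(resid, name, his_charged = FALSE) {
  neg <- (resid == "ASP" & name %in% c("OD1", "OD2")) |
         (resid == "GLU" & name %in% c("OE1", "OE2"))
  pos <- (resid == "LYS" & name == "NZ") |
         (resid == "ARG" & name %in% c("NE", "NH1", "NH2")) |
         (resid %in% c("MG", "MG2") & name %in% c("MG", "MG2"))
  if (his_charged)
    pos <- pos | (resid == "HIS" & name %in% c("ND1", "NE2"))
  ifelse(neg, -1L, ifelse(pos, 1L, 0L))
}

.ligand_charge <- function(name, template) {
  carboxyl_o <- unlist(lapply(template$carboxyls, `[`, 2:3))
  ifelse(name %in% carboxyl_o, -1L,
         ifelse(name %in% template$amino_nitrogens, 1L, 0L))
}

#' Compute the interaction fingerprint of a pose
#'
#' For every atom pair between the listed pocket residues and the ligand
#' within the proximal threshold, the highest-precedence satisfied rule
#' contributes one (residue, category) pair to the fingerprint set. The full
#' contact table (with the minimum distance per residue and category) is
#' attached as the `"contacts"` attribute.
#'
#' @param receptor a [mal_structure()]
#' @param pose a [ligand_pose()]
#' @param pocket_residues data frame with columns `chain`, `resno` (and
#'   optionally `label`), or a character vector like `"B:331"`
#' @param template the pose's [ligand_template()] (charge/apolar assignment)
#' @param rules a [contact_rules()]
#' @return an object of class `mal_fingerprint`: data frame of unique
#'   (`residue`, `category`) rows, sorted; attribute `"contacts"` holds the
#'   per-pair minimum distances
#' @export
compute_fingerprint <- function(receptor, pose, pocket_residues,
                                template = mal_template("3MA"),
                                rules = contact_rules()) {
  stopifnot(inherits(receptor, "mal_structure"),
            inherits(pose, "ligand_pose"))
  if (is.character(pocket_residues)) {
    parts <- strsplit(pocket_residues, ":", fixed = TRUE)
    pocket_residues <- data.frame(
      chain = vapply(parts, `[`, "", 1L),
      resno = as.integer(vapply(parts, `[`, "", 2L)))
  }
  ra <- receptor$atoms
  la <- pose$atoms
  lcharge <- .ligand_charge(la$name, template)
  lapolar <- la$element == "C" & la$name %in% template$apolar_carbons
  lpolar <- la$element %in% c("N", "O")

  out <- list()
  for (i in seq_len(nrow(pocket_residues))) {
    ch <- pocket_residues$chain[i]; rn <- pocket_residues$resno[i]
    sel <- ra[ra$chain == ch & ra$resno == rn, , drop = FALSE]
    if (!nrow(sel))
      stop(sprintf("pocket residue %s:%d not found in receptor", ch, rn),
           call. = FALSE)
    label <- sprintf("%s%d", sel$resid[1], rn)
    rcharge <- .residue_charge(sel$resid, sel$name, rules$his_charged)
    # apolar receptor carbons: side-chain carbons beyond the carbonyl
    rapolar <- sel$element == "C" & !sel$name %in% c("C", "CA", "CG", "CD") |
      (sel$resid %in% c("LEU", "ILE", "VAL", "ALA", "PHE", "TYR", "TRP",
                        "MET", "PRO") & sel$element == "C" & sel$name != "C")
    rpolar <- sel$element %in% c("N", "O")
    for (j in seq_len(nrow(sel))) {
      dists <- sqrt((la$x - sel$x[j])^2 + (la$y - sel$y[j])^2 +
                    (la$z - sel$z[j])^2)
      for (k in which(dists <= rules$proximal_max)) {
        d <- dists[k]
        category <-
          if (rpolar[j] && lpolar[k] && d <= rules$hbond_max) "hydrogen_bond"
          else if (rcharge[j] * lcharge[k] < 0L && d <= rules$ionic_max) "ionic"
          else if (rapolar[j] && lapolar[k] && d <= rules$hydrophobic_max)
            "hydrophobic"
          else "proximal"
        out[[length(out) + 1L]] <-
          data.frame(residue = label, category = category, distance = d)
      }
    }
  }
  contacts <- if (length(out)) do.call(rbind, out) else
    data.frame(residue = character(), category = character(),
               distance = numeric())
  agg <- if (nrow(contacts))
    stats::aggregate(distance ~ residue + category, contacts, min) else contacts
  fp <- agg[order(agg$residue, agg$category), c("residue", "category"),
            drop = FALSE]
  rownames(fp) <- NULL
  structure(fp, class = c("mal_fingerprint", "data.frame"),
            contacts = agg[order(agg$residue, agg$category), , drop = FALSE])
}

.fp_keys <- function(fp) {
  if (!nrow(fp)) character() else paste(fp$residue, fp$category, sep = "|")
}

#' Compare two interaction fingerprints
#'
#' Exact set algebra on (residue, category) pairs, plus the Jaccard index
#' (defined as 1 when both fingerprints are empty).
#'
#' @param a,b fingerprints from [compute_fingerprint()] (or data frames with
#'   `residue` and `category` columns)
#' @return list with `shared`, `only_a`, `only_b` (character vectors of
#'   `"residue|category"` keys) and `jaccard`
#' @export
compare_fingerprints <- function(a, b) {
  ka <- unique(.fp_keys(a)); kb <- unique(.fp_keys(b))
  shared <- intersect(ka, kb)
  uni <- union(ka, kb)
  list(shared = sort(shared),
       only_a = sort(setdiff(ka, kb)),
       only_b = sort(setdiff(kb, ka)),
       jaccard = if (!length(uni)) 1.0 else length(shared) / length(uni))
}

#' Write a fingerprint contact table and comparison report
#'
#' @param fingerprint a `mal_fingerprint`
#' @param tsv path for the contact table (residue, category, min distance)
#' @param comparison optional result of [compare_fingerprints()]
#' @param json path for the JSON comparison report
#' @return the fingerprint, invisibly
#' @export
write_fingerprint <- function(fingerprint, tsv = NULL, comparison = NULL,
                              json = NULL) {
  if (!is.null(tsv))
    utils::write.table(attr(fingerprint, "contacts"), tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(json) && !is.null(comparison))
    jsonlite::write_json(comparison, json, auto_unbox = TRUE, digits = NA)
  invisible(fingerprint)
}
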