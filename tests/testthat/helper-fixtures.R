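# Shared helpers: hand-built text fixtures and independent oracles.

pdb_line <- function(record, serial, name, resid, chain, resno, x, y, z,
                     alt = " ", element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
          alt, resid, chain, resno, x, y, z, element)
}

# A tiny 3-atom receptor fragment used by the parsing tests.
tiny_pdb <- function() {
  c(pdb_line("ATOM", 1, "N",  "ALA", "A", 1, 1.000, 2.000, 3.000),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 2.500, 2.000, 3.000),
    pdb_line("ATOM", 3, "C",  "ALA", "A", 1, 3.250, 3.300, 3.000),
    "END")
}

# Random coordinates for every atom named by a template, as a ligand_pose.
# Used by the symmetry-RMSD tests; chemistry is irrelevant there.
random_pose_for_template <- function(template, pose_id = 1L, sd = 2) {
  labels <- unique(c(unlist(template$carboxyls), unlist(template$backbones),
                     template$abstraction, template$amino_nitrogens,
                     template$apolar_carbons))
  elem <- ifelse(grepl("^O", labels), "O",
                 ifelse(grepl("^N", labels), "N", "C"))
  tab <- data.frame(record = "HETATM", name = labels, alt = "",
                    resid = "LIG", chain = "", resno = 1L, insert = "",
                    x = rnorm(length(labels), sd = sd),
                    y = rnorm(length(labels), sd = sd),
                    z = rnorm(length(labels), sd = sd),
                    element = elem, stringsAsFactors = FALSE)
  ligand_pose(tab, pose_id = pose_id, ligand_name = template$ligand_name)
}

# Independent brute-force oracle for the symmetry-corrected scaffold RMSD:
# enumerate every mapping (pose carboxyl choice x pose oxygen order x
# reference oxygen order) and take the minimum plain positional RMSD.
brute_force_scaffold_rmsd <- function(pose, reference, template,
                                      reference_template, ref_choice = 1L) {
  xyz_of <- function(p, label) {
    i <- which(p$atoms$name == label)
    as.numeric(p$atoms[i, c("x", "y", "z")])
  }
  coords <- function(p, tmpl, choice, oxy) {
    cx <- tmpl$carboxyls[[choice]]
    labs <- c(cx[1], cx[1 + oxy], tmpl$backbones[[choice]])
    t(sapply(labs, xyz_of, p = p))
  }
  best <- Inf
  for (choice in seq_along(template$carboxyls))
    for (oxy_pose in list(c(1, 2), c(2, 1)))
      for (oxy_ref in list(c(1, 2), c(2, 1))) {
        a <- coords(pose, template, choice, oxy_pose)
        b <- coords(reference, reference_template, ref_choice, oxy_ref)
        best <- min(best, sqrt(mean(rowSums((a - b)^2))))
      }
  best
}
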