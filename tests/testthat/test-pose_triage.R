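fx <- make_pocket_fixture()

test_that("reference geometry reproduces the four anchor distances", {
  d <- measure_distances(fx$reference, fx$template, fx$anchors)
  expect_equal(as.numeric(d[1, 1:4]), c(4.16, 3.08, 2.75, 2.2),
               tolerance = 1e-9)
  expect_equal(d$carboxyl_choice, 1L)
})

test_that("oxygen symmetry takes the shorter distance, always", {
  # constructed pose: every anchor exactly 1 A from its reference atom
  atoms <- fx$reference$atoms
  place <- function(name, xyz) {
    atoms[atoms$name == name, c("x", "y", "z")] <<- rbind(xyz)
  }
  place("O4A", fx$anchors$mg + c(1, 0, 0))
  place("O4B", fx$anchors$mg + c(8, 0, 0))          # partner oxygen far
  pose <- ligand_pose(atoms, 2L, "3MA")
  d <- measure_distances(pose, fx$template, fx$anchors)
  # min over the two oxygens never exceeds either individual distance
  o4a <- as.numeric(atoms[atoms$name == "O4A", c("x", "y", "z")])
  expect_equal(d$d_mg_o, 1)
  expect_lte(d$d_mg_o, sqrt(sum((o4a - fx$anchors$mg)^2)))

  # equidistant oxygens: the minimum equals either distance
  place("O4B", fx$anchors$mg + c(-1, 0, 0))
  pose_tie <- ligand_pose(atoms, 3L, "3MA")
  expect_equal(measure_distances(pose_tie, fx$template, fx$anchors)$d_mg_o, 1)
})

test_that("unresolvable template labels are named in the error", {
  atoms <- fx$reference$atoms
  atoms$name[atoms$name == "CM"] <- "CX"
  pose <- ligand_pose(atoms, 9L, "3MA")
  tmpl <- ligand_template("broken",
                          carboxyls = list(c("C4", "O4A", "OZZ")),
                          backbones = list(c("C3", "C2", "C1")),
                          abstraction = "C3")
  expect_error(measure_distances(pose, tmpl, fx$anchors), "OZZ")
})

test_that("pocket criterion counts strict inequalities", {
  mk <- function(d) data.frame(d_k331_c3 = d[1], d_q329_o = d[2],
                               d_h194_o = d[3], d_mg_o = d[4])
  # the printed reference distances themselves: 4.16 is not below 4
  r <- pose_in_pocket(mk(c(4.16, 3.08, 2.75, 2.2)), fx$anchors)
  expect_equal(r$n_below_cutoff, 3L)
  expect_true(r$in_pocket)
  expect_equal(pose_in_pocket(mk(c(10, 10, 10, 3)), fx$anchors)$n_below_cutoff, 1L)
  expect_false(pose_in_pocket(mk(c(10, 10, 10, 3)), fx$anchors)$in_pocket)
  expect_true(pose_in_pocket(mk(c(3.9, 3.9, 3.9, 3.9)), fx$anchors)$in_pocket)
  # exactly at the cutoff does not count
  expect_equal(pose_in_pocket(mk(c(4, 4, 4, 4)), fx$anchors)$n_below_cutoff, 0L)
})

test_that("raising the cutoff never decreases the pass count", {
  set.seed(11)
  for (i in 1:50) {
    d <- data.frame(d_k331_c3 = runif(1, 0, 8), d_q329_o = runif(1, 0, 8),
                    d_h194_o = runif(1, 0, 8), d_mg_o = runif(1, 0, 8))
    counts <- vapply(seq(1, 8, by = 0.5), function(cut) {
      a <- fx$anchors; a$cutoff <- cut
      pose_in_pocket(d, a)$n_below_cutoff
    }, 0L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("scaffold RMSD is zero on identity and exact on translation", {
  r <- scaffold_rmsd(fx$reference, fx$reference, fx$template)
  expect_equal(r$rmsd, 0)
  expect_equal(r$mapping, "carboxyl=1;oxygens=direct")

  p <- fx$reference
  p$atoms$x <- p$atoms$x + 3
  expect_equal(scaffold_rmsd(p, fx$reference, fx$template)$rmsd, 3,
               tolerance = 1e-12)
})

test_that("symmetry minimisation equals the brute-force oracle on all templates", {
  set.seed(101)
  ref_template <- mal_template("3MA")
  reference <- random_pose_for_template(ref_template)
  for (name in mal_template_names()) {
    tmpl <- mal_template(name)
    for (i in 1:25) {
      pose <- random_pose_for_template(tmpl, pose_id = i)
      got <- scaffold_rmsd(pose, reference, tmpl, ref_template)
      oracle <- brute_force_scaffold_rmsd(pose, reference, tmpl, ref_template)
      expect_equal(got$rmsd, oracle, tolerance = 1e-12)
    }
  }
})

test_that("symmetry-minimised RMSD never exceeds any fixed mapping", {
  set.seed(202)
  tmpl <- mal_template("BGL")           # dicarboxylic, both orientations live
  reference <- random_pose_for_template(mal_template("3MA"))
  for (i in 1:20) {
    pose <- random_pose_for_template(tmpl, pose_id = i)
    sym <- scaffold_rmsd(pose, reference, tmpl)$rmsd
    fixed <- maltriage:::.scaffold_coords(pose, tmpl, 1L, c(1L, 2L))
    refc <- maltriage:::.scaffold_coords(reference, mal_template("3MA"), 1L)
    expect_lte(sym, sqrt(mean(rowSums((fixed - refc)^2))) + 1e-12)
  }
})

test_that("pose selection picks the lowest-RMSD in-pocket pose", {
  results <- data.frame(pose_id = 1:3,
                        docking_score = c(-6, -6, -8),
                        in_pocket = c(TRUE, TRUE, FALSE),
                        scaffold_rmsd = c(2.1, 1.5, 1.2))
  sel <- select_pose(results)
  expect_equal(sel$selected$pose_id, 2L)

  # single in-pocket pose selects itself
  one <- results[2, , drop = FALSE]
  expect_equal(select_pose(one)$selected$pose_id, 2L)

  # all out of pocket: explicit no-selection outcome, not an error
  none <- results; none$in_pocket <- FALSE
  out <- select_pose(none)
  expect_null(out$selected)
  expect_match(out$reason, "no pose")

  # RMSD tie broken by better (lower) score, then pose id
  tie <- data.frame(pose_id = 1:2, docking_score = c(-5, -7),
                    in_pocket = TRUE, scaffold_rmsd = 1.5)
  expect_equal(select_pose(tie)$selected$pose_id, 2L)
  tie$docking_score <- NA_real_
  expect_equal(select_pose(tie)$selected$pose_id, 1L)

  expect_error(select_pose(results[0, ]), "at least one")
})

test_that("percent in pocket is a simple fraction, invariant to order", {
  results <- data.frame(pose_id = 1:10, in_pocket = rep(c(TRUE, FALSE), 5))
  expect_equal(percent_in_pocket(results), 0.5)
  set.seed(7)
  expect_equal(percent_in_pocket(results[sample(10), ]), 0.5)
  expect_error(percent_in_pocket(results[0, ]), "at least one")
})

test_that("a far-displaced pose is never in the pocket", {
  set.seed(303)
  for (i in 1:20) {
    offset <- (fx$anchors$cutoff + max(fx$anchors$reference_distances) + 1) *
      runif(1, 1, 3)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    p <- fx$reference
    p$atoms$x <- p$atoms$x + offset * dir[1]
    p$atoms$y <- p$atoms$y + offset * dir[2]
    p$atoms$z <- p$atoms$z + offset * dir[3]
    d <- measure_distances(p, fx$template, fx$anchors)
    expect_false(pose_in_pocket(d, fx$anchors)$in_pocket)
  }
})

test_that("the full triage report is consistent with the component operations", {
  sim <- generate_poses(fx$reference, n_in_pocket = 5, n_decoys = 5, seed = 9)
  report <- triage_ligand(fx$receptor, sim$poses, fx$template, fx$reference,
                          anchors = fx$anchors)
  expect_s3_class(report, "mal_triage")
  expect_equal(nrow(report$results), 10L)
  for (i in c(1L, 6L)) {
    p <- sim$poses[[i]]
    row <- report$results[report$results$pose_id == p$pose_id, ]
    d <- measure_distances(p, fx$template, fx$anchors)
    expect_equal(row$d_mg_o, d$d_mg_o)
    expect_equal(row$n_below_cutoff, pose_in_pocket(d, fx$anchors)$n_below_cutoff)
    expect_equal(row$scaffold_rmsd,
                 scaffold_rmsd(p, fx$reference, fx$template)$rmsd)
  }
  expect_equal(report$percent_in_pocket, mean(report$results$in_pocket))
  expect_error(triage_ligand(fx$receptor, list(), fx$template, fx$reference),
               "empty pose set")

  # reference ligand as sole pose: selected with RMSD 0
  solo <- triage_ligand(fx$receptor, list(fx$reference), fx$template,
                        fx$reference, anchors = fx$anchors)
  expect_equal(solo$selection$selected$pose_id, 1L)
  expect_equal(solo$selection$selected$scaffold_rmsd, 0)
})

test_that("triage reports serialise to TSV and JSON", {
  sim <- generate_poses(fx$reference, n_in_pocket = 3, n_decoys = 2, seed = 5)
  report <- triage_ligand(fx$receptor, sim$poses, fx$template, fx$reference,
                          anchors = fx$anchors)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_triage(report, tsv = tsv, json = json)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 5L)
  expect_equal(back$scaffold_rmsd, report$results$scaffold_rmsd)
  summary <- jsonlite::read_json(json)
  expect_equal(summary$percent_in_pocket, report$percent_in_pocket)
  expect_equal(summary$selected_pose$pose_id,
               report$selection$selected$pose_id)
})
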