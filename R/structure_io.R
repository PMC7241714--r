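#' @title Coordinate model for receptors and ligand poses
#'
#' @description
#' Macromolecular coordinates are held in a plain atom table with one row per
#' atom and PDB v3 addressing (chain, residue number, atom name). Receptors
#' are `mal_structure` objects, docked ligand conformations are
#' `ligand_pose` objects; both carry the same atom-table layout so that the
#' geometry code downstream never cares where the coordinates came from.
#'
#' Atom-table columns: `record` ("ATOM"/"HETATM"), `name`, `alt`, `resid`
#' (3-letter residue code), `chain`, `resno`, `insert`, `x`, `y`, `z` (Å),
#' `element`.
#' @name structure-model
NULL

.atom_cols <- c("record", "name", "alt", "resid", "chain", "resno",
                "insert", "x", "y", "z", "element")

# Common atom-name variants seen in 1KKR-era files and docking output.
.atom_aliases <- list(
  MG  = c("MG", "MG2", "MG2+", "MG+2"),
  NZ  = c("NZ"),
  NE2 = c("NE2"),
  OXT = c("OXT", "OT2")
)

new_atom_table <- function(record = character(), name = character(),
                           alt = character(), resid = character(),
                           chain = character(), resno = integer(),
                           insert = character(), x = numeric(),
                           y = numeric(), z = numeric(),
                           element = character()) {
  data.frame(record = record, name = name, alt = alt, resid = resid,
             chain = chain, resno = as.integer(resno), insert = insert,
             x = x, y = y, z = z, element = element,
             stringsAsFactors = FALSE)
}

#' Construct a structure object from an atom table
#'
#' @param atoms atom table (see [structure-model])
#' @param id free-text identifier (e.g. a PDB id)
#' @return an object of class `mal_structure`
#' @export
mal_structure <- function(atoms, id = "") {
  stopifnot(is.data.frame(atoms), all(.atom_cols %in% names(atoms)))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite coordinates in atom table", call. = FALSE)
  structure(list(atoms = atoms[, .atom_cols], id = id),
            class = "mal_structure")
}

#' Construct a ligand pose
#'
#' A pose is one conformation of a ligand in the receptor coordinate frame;
#' no re-superposition is ever applied.
#'
#' @param atoms atom table
#' @param pose_id integer pose identifier
#' @param ligand_name free-text ligand name
#' @param docking_score optional score from the docking program
#'   (program-specific units; more negative is better)
#' @return an object of class `ligand_pose`
#' @export
ligand_pose <- function(atoms, pose_id = 1L, ligand_name = "",
                        docking_score = NA_real_) {
  stopifnot(is.data.frame(atoms), all(.atom_cols %in% names(atoms)))
  if (anyDuplicated(atoms$name))
    stop("pose atom names must be unique", call. = FALSE)
  structure(list(pose_id = as.integer(pose_id), ligand_name = ligand_name,
                 atoms = atoms[, .atom_cols],
                 docking_score = as.numeric(docking_score)),
            class = "ligand_pose")
}

#' @export
print.mal_structure <- function(x, ...) {
  cat(sprintf("<mal_structure '%s': %d atoms, chains %s>\n", x$id,
              nrow(x$atoms), paste(sort(unique(x$atoms$chain)), collapse = ",")))
  invisible(x)
}

#' @export
print.ligand_pose <- function(x, ...) {
  cat(sprintf("<ligand_pose %d '%s': %d atoms%s>\n", x$pose_id,
              x$ligand_name, nrow(x$atoms),
              if (is.na(x$docking_score)) "" else
                sprintf(", score %.2f", x$docking_score)))
  invisible(x)
}

# Accept either a file path or raw file content; always return lines.
.as_lines <- function(text) {
  if (length(text) == 1L && !grepl("\n", text, fixed = TRUE) &&
      file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
}

.substr_trim <- function(line, from, to) {
  trimws(substr(line, from, min(to, nchar(line))))
}

# Parse ATOM/HETATM records from PDB fixed-width lines. `lineno` carries the
# original line numbers so format errors can name the offending line.
.parse_pdb_atom_lines <- function(lines, lineno = seq_along(lines)) {
  rec <- substr(lines, 1, 6)
  keep <- grepl("^(ATOM|HETATM)", rec)
  lines <- lines[keep]; lineno <- lineno[keep]
  if (!length(lines)) return(new_atom_table())
  num <- function(from, to, what) {
    raw <- vapply(lines, .substr_trim, "", from = from, to = to,
                  USE.NAMES = FALSE)
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | raw == "")
    if (length(bad))
      stop(sprintf("unparseable %s field at line %d: '%s'", what,
                   lineno[bad[1]], lines[bad[1]]), call. = FALSE)
    val
  }
  name  <- vapply(lines, .substr_trim, "", from = 13, to = 16, USE.NAMES = FALSE)
  alt   <- vapply(lines, .substr_trim, "", from = 17, to = 17, USE.NAMES = FALSE)
  resid <- vapply(lines, .substr_trim, "", from = 18, to = 21, USE.NAMES = FALSE)
  chain <- vapply(lines, .substr_trim, "", from = 22, to = 22, USE.NAMES = FALSE)
  resno <- as.integer(num(23, 26, "residue-number"))
  insert <- vapply(lines, .substr_trim, "", from = 27, to = 27, USE.NAMES = FALSE)
  x <- num(31, 38, "x-coordinate")
  y <- num(39, 46, "y-coordinate")
  z <- num(47, 54, "z-coordinate")
  elem <- vapply(lines, .substr_trim, "", from = 77, to = 78, USE.NAMES = FALSE)
  guess <- toupper(sub("^[0-9']*", "", name))
  two_letter <- c("MG", "FE", "ZN", "MN", "CA", "NA", "CL", "BR", "SE", "CU")
  guess <- ifelse(substr(guess, 1, 2) %in% two_letter & nchar(guess) <= 3 &
                    resid %in% c(two_letter, "MG2"),
                  substr(guess, 1, 2), substr(guess, 1, 1))
  elem <- toupper(ifelse(elem == "", guess, elem))
  tab <- new_atom_table(sub("\\s+$", "", rec[keep]), name, alt, resid, chain,
                        resno, insert, x, y, z, elem)
  .filter_altloc(tab)
}

# Keep blank/'A' altlocs only; where duplicates remain, the first record wins.
.filter_altloc <- function(atoms) {
  atoms <- atoms[atoms$alt %in% c("", "A"), , drop = FALSE]
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$resid)
  atoms <- atoms[!duplicated(key), , drop = FALSE]
  rownames(atoms) <- NULL
  atoms
}

#' Read a PDB-format receptor structure
#'
#' Parses ATOM/HETATM records into an atom table. Only the blank and 'A'
#' alternate-location indicators are retained (first record wins); insertion
#' codes are kept. Multi-model files are read as their first model — use
#' [read_poses()] for pose sets.
#'
#' @param text PDB file path or file content (single string or character
#'   vector of lines)
#' @param id identifier stored on the structure
#' @return a [mal_structure()]
#' @export
read_structure <- function(text, id = "") {
  lines <- .as_lines(text)
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  atoms <- .parse_pdb_atom_lines(lines)
  if (!nrow(atoms))
    stop("no ATOM/HETATM records found: empty structure", call. = FALSE)
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name, atoms$resid)
  if (anyDuplicated(key))
    stop("duplicate (chain, residue, atom-name) address after altloc filtering",
         call. = FALSE)
  mal_structure(atoms, id = id)
}

#' Look up one atom by chain / residue number / atom name
#'
#' Atom names are matched after trimming, with a small alias table for common
#' variants (e.g. "MG2" for the magnesium ion).
#'
#' @param structure a [mal_structure()]
#' @param chain chain identifier
#' @param resno residue number
#' @param name PDB v3 atom name
#' @return a one-row atom table
#' @export
get_atom <- function(structure, chain, resno, name) {
  stopifnot(inherits(structure, "mal_structure"))
  names_ok <- toupper(name)
  for (canon in names(.atom_aliases))
    if (toupper(name) %in% .atom_aliases[[canon]])
      names_ok <- .atom_aliases[[canon]]
  a <- structure$atoms
  hit <- a$chain == chain & a$resno == as.integer(resno) &
    toupper(a$name) %in% names_ok
  if (!any(hit))
    stop(sprintf("atom not found: chain %s, residue %d, name %s",
                 chain, as.integer(resno), name), call. = FALSE)
  if (sum(hit) > 1L)
    stop(sprintf("ambiguous atom address: chain %s, residue %d, name %s",
                 chain, as.integer(resno), name), call. = FALSE)
  a[hit, , drop = FALSE]
}

.coords <- function(atom_row) as.numeric(atom_row[1, c("x", "y", "z")])

#' Extract a HETATM ligand residue as a pose
#'
#' Water residues (HOH/WAT/H2O) are never returned as ligands. The receptor
#' structure is left untouched.
#'
#' @param structure a [mal_structure()]
#' @param resid 3-letter residue name of the ligand
#' @param chain chain to take the copy from (`NULL`: require a unique copy)
#' @return a [ligand_pose()] in the receptor frame
#' @export
extract_ligand <- function(structure, resid, chain = NULL) {
  stopifnot(inherits(structure, "mal_structure"))
  if (toupper(resid) %in% c("HOH", "WAT", "H2O"))
    stop("water is not extractable as a ligand", call. = FALSE)
  a <- structure$atoms
  hit <- a$record == "HETATM" & toupper(a$resid) == toupper(resid)
  if (!is.null(chain)) hit <- hit & a$chain == chain
  if (!any(hit))
    stop(sprintf("ligand residue '%s'%s not found", resid,
                 if (is.null(chain)) "" else paste0(" in chain ", chain)),
         call. = FALSE)
  sel <- a[hit, , drop = FALSE]
  if (length(unique(paste(sel$chain, sel$resno))) > 1L)
    stop(sprintf("ligand residue '%s' present in several copies; give a chain",
                 resid), call. = FALSE)
  rownames(sel) <- NULL
  ligand_pose(sel, pose_id = 1L, ligand_name = resid)
}

.score_from_header <- function(header_lines) {
  hit <- grep("score", header_lines, ignore.case = TRUE, value = TRUE)
  if (!length(hit)) return(NA_real_)
  tail_part <- sub(".*score", "", hit[1], ignore.case = TRUE)
  m <- regmatches(tail_part, regexpr("-?[0-9]+\\.?[0-9]*", tail_part))
  if (!length(m)) NA_real_ else as.numeric(m)
}

.parse_poses_pdb_multi <- function(lines, ligand_name) {
  starts <- grep("^MODEL", lines)
  if (!length(starts)) {                       # single implicit model
    atoms <- .parse_pdb_atom_lines(lines)
    if (!nrow(atoms)) return(list())
    return(list(ligand_pose(atoms, 1L, ligand_name,
                            .score_from_header(grep("^REMARK", lines, value = TRUE)))))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) {
    block_idx <- seq(starts[i], ends[i])
    block <- lines[block_idx]
    atoms <- .parse_pdb_atom_lines(block, lineno = block_idx)
    ligand_pose(atoms, i, ligand_name,
                .score_from_header(grep("^REMARK", block, value = TRUE)))
  })
}

# LeDock .dok output: pose blocks of ATOM records, each preceded by REMARK
# lines carrying the cluster/score annotation, terminated by END.
.parse_poses_dok <- function(lines, ligand_name) {
  ends <- grep("^END", lines)
  if (!length(ends)) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  poses <- list()
  for (i in seq_along(starts)) {
    block_idx <- seq(starts[i], ends[i])
    block <- lines[block_idx]
    atoms <- .parse_pdb_atom_lines(block, lineno = block_idx)
    if (!nrow(atoms)) next
    poses[[length(poses) + 1L]] <-
      ligand_pose(atoms, length(poses) + 1L, ligand_name,
                  .score_from_header(grep("^REMARK", block, value = TRUE)))
  }
  poses
}

.parse_poses_mol2 <- function(lines, ligand_name) {
  mol_at <- grep("^@<TRIPOS>MOLECULE", lines)
  if (!length(mol_at)) return(list())
  bounds <- c(mol_at, length(lines) + 1L)
  lapply(seq_along(mol_at), function(i) {
    block <- lines[seq(bounds[i], bounds[i + 1L] - 1L)]
    name <- if (length(block) >= 2L && nzchar(trimws(block[2])))
      trimws(block[2]) else ligand_name
    atom_at <- grep("^@<TRIPOS>ATOM", block)
    if (!length(atom_at))
      stop("mol2 molecule block without @<TRIPOS>ATOM section", call. = FALSE)
    next_sec <- grep("^@<TRIPOS>", block)
    next_sec <- next_sec[next_sec > atom_at[1]]
    last <- if (length(next_sec)) next_sec[1] - 1L else length(block)
    rows <- block[seq(atom_at[1] + 1L, last)]
    rows <- rows[nzchar(trimws(rows))]
    fields <- strsplit(trimws(rows), "\\s+")
    parse_row <- function(f) {
      if (length(f) < 6L)
        stop("malformed mol2 ATOM row: ", paste(f, collapse = " "),
             call. = FALSE)
      xyz <- suppressWarnings(as.numeric(f[3:5]))
      if (any(is.na(xyz)))
        stop("unparseable mol2 coordinates in row: ",
             paste(f, collapse = " "), call. = FALSE)
      c(name = f[2], x = xyz[1], y = xyz[2], z = xyz[3],
        type = f[6],
        resid = if (length(f) >= 8L) f[8] else "LIG")
    }
    parsed <- t(vapply(fields, parse_row, character(6)))
    atoms <- new_atom_table(
      record = rep("HETATM", nrow(parsed)),
      name = parsed[, "name"], alt = "",
      resid = substr(gsub("[0-9]+$", "", parsed[, "resid"]), 1, 3),
      chain = "", resno = 1L, insert = "",
      x = as.numeric(parsed[, "x"]), y = as.numeric(parsed[, "y"]),
      z = as.numeric(parsed[, "z"]),
      element = toupper(sub("\\..*$", "", parsed[, "type"])))
    ligand_pose(atoms, i, name,
                .score_from_header(grep("^#", block, value = TRUE)))
  })
}

#' Read a docked pose set
#'
#' The dialect is declared explicitly — no format sniffing. Supported:
#' `"pdb-multi-model"` (MODEL/ENDMDL blocks, score taken from a REMARK line
#' containing "score"), `"dok"` (LeDock output blocks) and `"mol2"`
#' (`@<TRIPOS>MOLECULE` blocks, score from a `#` comment containing "score").
#'
#' @param text file path or file content
#' @param dialect one of `"pdb-multi-model"`, `"mol2"`, `"dok"`
#' @param ligand_name name stored on the poses
#' @return list of [ligand_pose()] with ids `1..N`
#' @export
read_poses <- function(text, dialect = c("pdb-multi-model", "mol2", "dok"),
                       ligand_name = "LIG") {
  dialect <- match.arg(dialect)
  lines <- .as_lines(text)
  poses <- switch(dialect,
                  "pdb-multi-model" = .parse_poses_pdb_multi(lines, ligand_name),
                  "dok"  = .parse_poses_dok(lines, ligand_name),
                  "mol2" = .parse_poses_mol2(lines, ligand_name))
  if (!length(poses))
    stop("no poses parsed from input (dialect: ", dialect, ")", call. = FALSE)
  poses
}

.format_pdb_line <- function(a, serial) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$record, serial,
          ifelse(nchar(a$name) < 4L, paste0(" ", a$name), a$name),
          ifelse(a$alt == "", " ", a$alt), a$resid,
          ifelse(a$chain == "", " ", a$chain), a$resno,
          ifelse(a$insert == "", " ", a$insert),
          a$x, a$y, a$z, 1, 0, a$element)
}

#' Write a structure or pose set as PDB text
#'
#' Pose lists are written as multi-model files; a pose's docking score is
#' recorded as `REMARK SCORE` inside its MODEL block so [read_poses()]
#' round-trips it.
#'
#' @param x a [mal_structure()], a [ligand_pose()] or a list of poses
#' @param path output file; `NULL` returns the lines invisibly
#' @return the PDB lines, invisibly
#' @export
write_pdb <- function(x, path = NULL) {
  if (inherits(x, "ligand_pose")) x <- list(x)
  lines <- if (inherits(x, "mal_structure")) {
    a <- x$atoms
    c(vapply(seq_len(nrow(a)), function(i)
      .format_pdb_line(a[i, ], i), ""), "END")
  } else {
    unlist(lapply(x, function(p) {
      a <- p$atoms
      c(sprintf("MODEL %8d", p$pose_id),
        if (!is.na(p$docking_score))
          sprintf("REMARK SCORE %.4f", p$docking_score),
        vapply(seq_len(nrow(a)), function(i)
          .format_pdb_line(a[i, ], i), ""),
        "ENDMDL")
    }))
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Fetch the reference crystal structure from the PDB
#'
#' Convenience downloader for PDB entry 1KKR (MAL in complex with
#' 3-methylaspartate and the catalytic magnesium). Requires network access;
#' never called by the package's tests, which run against the analytic
#' synthetic pocket fixture instead (see [make_pocket_fixture()]).
#'
#' @param pdb_id 4-character PDB identifier
#' @param dest_dir cache directory
#' @return path to the downloaded file
#' @export
fetch_reference <- function(pdb_id = "1KKR", dest_dir = tempdir()) {
  dest <- file.path(dest_dir, paste0(tolower(pdb_id), ".pdb"))
  if (!file.exists(dest)) {
    url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(pdb_id))
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
  }
  dest
}
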