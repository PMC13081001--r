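## structure_io: topologies, trajectories, selections and file formats.
##
## Coordinates are stored in angstrom as an n_frames x n_atoms x 3 array;
## frame times, when present, are in nanoseconds and strictly increasing.
## Atom order is the identity mapping across frames: readers never re-match
## atoms by name, so a mismatch is an error, not a silent realignment.

#' Construct a topology
#'
#' A topology records per-atom metadata (serial, name, element, residue name,
#' residue index, chain) and, optionally, per-atom force-field style
#' parameters: partial charges (elementary charge units), Lennard-Jones
#' parameters (epsilon in kcal/mol, rmin/2 in angstrom) and intrinsic radii
#' (angstrom).
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resid`, `chain`.
#' @param charges Optional numeric vector of per-atom partial charges.
#' @param lj Optional data.frame with columns `epsilon` (kcal/mol) and
#'   `rmin_half` (angstrom), one row per atom.
#' @param radii Optional numeric vector of per-atom intrinsic radii
#'   (angstrom).
#' @return An object of class `topology`.
#' @examples
#' top <- topology(data.frame(
#'   serial = 1:2, name = c("N", "CA"), element = c("N", "C"),
#'   resname = "ALA", resid = 1L, chain = "A"))
#' n_atoms(top)
#' @export
topology <- function(atoms, charges = NULL, lj = NULL, radii = NULL) {
  req <- c("serial", "name", "element", "resname", "resid", "chain")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0)
    stop("topology: atoms table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(atoms)
  if (n < 1) stop("topology: atom count must be > 0")
  atoms$serial <- as.integer(atoms$serial)
  atoms$resid <- as.integer(atoms$resid)
  if (any(atoms$resid < 1)) stop("topology: residue indices must be >= 1")
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r))
      stop("topology: residue indices must be non-decreasing within chain ",
           ch)
  }
  check_len <- function(x, what) {
    if (!is.null(x) && NROW(x) != n)
      stop("topology: ", what, " length (", NROW(x),
           ") does not match atom count (", n, ")")
  }
  check_len(charges, "charges")
  check_len(lj, "lj")
  check_len(radii, "radii")
  structure(list(atoms = atoms, charges = charges, lj = lj, radii = radii),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology> ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), " residues, ",
      length(unique(x$atoms$chain)), " chain(s)\n", sep = "")
  cat("  optional fields:",
      paste(c("charges", "lj", "radii")[!vapply(
        list(x$charges, x$lj, x$radii), is.null, logical(1))],
        collapse = ", "), "\n")
  invisible(x)
}

#' Number of atoms in a topology or trajectory
#' @param x A `topology` or `trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "topology")) return(nrow(x$atoms))
  if (inherits(x, "trajectory")) return(dim(x$coords)[2])
  stop("n_atoms: unsupported object")
}

#' Construct a trajectory
#'
#' @param coords Numeric array `n_frames x n_atoms x 3` (angstrom), or a
#'   single `n_atoms x 3` matrix for a one-frame trajectory.
#' @param times Optional numeric vector of per-frame times in nanoseconds,
#'   strictly increasing.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, times = NULL) {
  if (is.matrix(coords)) {
    coords <- array(coords, dim = c(1, nrow(coords), ncol(coords)))
  }
  d <- dim(coords)
  if (length(d) != 3 || d[3] != 3)
    stop("trajectory: coords must be n_frames x n_atoms x 3")
  if (d[1] < 1) stop("trajectory: need at least one frame")
  if (!all(is.finite(coords))) stop("trajectory: non-finite coordinates")
  if (!is.null(times)) {
    if (length(times) != d[1])
      stop("trajectory: times length does not match frame count")
    if (any(diff(times) <= 0))
      stop("trajectory: frame times must be strictly increasing")
  }
  structure(list(coords = coords, times = times), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat("<trajectory> ", d[1], " frames x ", d[2], " atoms",
      if (!is.null(x$times))
        sprintf(", %.4g-%.4g ns", x$times[1], x$times[d[1]]) else "",
      "\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[1]
}

#' Extract one frame as an atom x 3 coordinate matrix
#' @param traj A `trajectory`.
#' @param i Frame index (1-based).
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(inherits(traj, "trajectory"))
  if (i < 1 || i > n_frames(traj)) stop("frame_coords: frame index out of range")
  matrix(traj$coords[i, , ], ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

## ---------------------------------------------------------------------------
## Atom selections

#' Select atoms by name, residue and/or preset
#'
#' Resolves a selection expressed as atom names, residue index ranges and/or a
#' named preset into a sorted, unique index vector. The `"backbone"` preset
#' selects atoms named N, CA, C and O (the protein backbone). Selections are
#' deterministic and idempotent. An empty result raises a warning, not an
#' error.
#'
#' @param topology A [topology].
#' @param names Optional character vector of atom names to keep.
#' @param resid Optional integer vector of residue indices to keep (use
#'   `seq(lo, hi)` for a range).
#' @param chain Optional character vector of chains to keep.
#' @param preset One of `"none"` or `"backbone"`.
#' @return Object of class `atom_selection`: a list with `indices` (sorted,
#'   unique, 1-based) and the criteria used.
#' @examples
#' top <- topology(data.frame(
#'   serial = 1:5, name = c("N", "CA", "C", "O", "CB"),
#'   element = c("N", "C", "C", "O", "C"),
#'   resname = "ALA", resid = 1L, chain = "A"))
#' length(select_atoms(top, preset = "backbone")$indices)  # 4
#' @export
select_atoms <- function(topology, names = NULL, resid = NULL, chain = NULL,
                         preset = c("none", "backbone")) {
  stopifnot(inherits(topology, "topology"))
  preset <- match.arg(preset)
  at <- topology$atoms
  keep <- rep(TRUE, nrow(at))
  if (preset == "backbone") keep <- keep & at$name %in% c("N", "CA", "C", "O")
  if (!is.null(names)) keep <- keep & at$name %in% names
  if (!is.null(resid)) keep <- keep & at$resid %in% resid
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  idx <- sort(unique(which(keep)))
  if (length(idx) == 0)
    warning("select_atoms: selection is empty", call. = FALSE)
  structure(list(indices = idx,
                 criteria = list(names = names, resid = resid, chain = chain,
                                 preset = preset)),
            class = "atom_selection")
}

## Accepts an atom_selection, an integer index vector, or NULL (all atoms)
## and returns a validated index vector.
resolve_selection <- function(selection, n) {
  if (is.null(selection)) return(seq_len(n))
  idx <- if (inherits(selection, "atom_selection")) selection$indices
         else as.integer(selection)
  if (any(idx < 1 | idx > n)) stop("selection index out of range")
  if (anyDuplicated(idx)) stop("selection indices must be unique")
  sort(idx)
}

## ---------------------------------------------------------------------------
## Multi-model PDB

#' Read a multi-model PDB file as a topology and trajectory
#'
#' Interprets ATOM/HETATM/MODEL/ENDMDL/TER records only (fixed PDB columns).
#' Each MODEL becomes one trajectory frame; a file without MODEL records is
#' read as a single frame. Atom order must be identical across models: an
#' atom-count mismatch is a format error naming the offending MODEL.
#' Insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @return List with elements `topology` and `trajectory`.
#' @seealso [write_pdb_models()]
#' @export
read_pdb_models <- function(path) {
  if (!file.exists(path)) stop("read_pdb_models: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_end <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("read_pdb_models: no ATOM/HETATM records in ", path)

  ## assign a model id to every atom line
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id <- rep(1L, length(lines))
  model_id[model_id == 0L] <- 1L
  atom_lines <- which(is_atom)
  grp <- model_id[atom_lines]
  models <- split(atom_lines, grp)

  parse_block <- function(idx) {
    ln <- lines[idx]
    icode <- substr(ln, 27, 27)
    if (any(icode != " ")) {
      bad <- idx[which(icode != " ")[1]]
      stop("read_pdb_models: insertion code at line ", bad,
           " is not supported")
    }
    num <- function(from, to, what) {
      s <- trimws(substr(ln, from, to))
      v <- suppressWarnings(as.numeric(s))
      if (any(is.na(v))) {
        bad <- idx[which(is.na(v))[1]]
        stop("read_pdb_models: unparseable ", what, " field at line ", bad)
      }
      v
    }
    data.frame(
      serial = as.integer(num(7, 11, "serial")),
      name = trimws(substr(ln, 13, 16)),
      resname = trimws(substr(ln, 18, 20)),
      chain = substr(ln, 22, 22),
      resid = as.integer(num(23, 26, "residue number")),
      x = num(31, 38, "x coordinate"),
      y = num(39, 46, "y coordinate"),
      z = num(47, 54, "z coordinate"),
      element = trimws(substr(ln, 77, 78)),
      stringsAsFactors = FALSE)
  }

  first <- parse_block(models[[1]])
  n_at <- nrow(first)
  nm <- length(models)
  coords <- array(NA_real_, dim = c(nm, n_at, 3))
  coords[1, , ] <- as.matrix(first[, c("x", "y", "z")])
  if (nm > 1) {
    for (m in 2:nm) {
      blk <- parse_block(models[[m]])
      if (nrow(blk) != n_at)
        stop("read_pdb_models: MODEL ", names(models)[m], " has ",
             nrow(blk), " atoms but MODEL ", names(models)[1],
             " has ", n_at)
      coords[m, , ] <- as.matrix(blk[, c("x", "y", "z")])
    }
  }
  el <- first$element
  ## fall back to the first letter of the atom name when the element
  ## column is blank (common in minimal files)
  blank <- el == ""
  el[blank] <- substr(gsub("[^A-Za-z].*$", "", first$name[blank]), 1, 1)
  top <- topology(data.frame(
    serial = first$serial, name = first$name, element = el,
    resname = first$resname, resid = first$resid, chain = first$chain,
    stringsAsFactors = FALSE))
  list(topology = top, trajectory = trajectory(coords))
}

#' Write a trajectory as a multi-model PDB file
#'
#' @param path Output path.
#' @param topology A [topology].
#' @param traj A [trajectory] with matching atom count.
#' @return Invisibly, `path`.
#' @export
write_pdb_models <- function(path, topology, traj) {
  stopifnot(inherits(topology, "topology"), inherits(traj, "trajectory"))
  if (n_atoms(topology) != n_atoms(traj))
    stop("write_pdb_models: atom count mismatch between topology and trajectory")
  at <- topology$atoms
  ## PDB name column: names of 1-3 characters start in column 14
  fmt_name <- ifelse(nchar(at$name) >= 4, sprintf("%-4s", at$name),
                     sprintf(" %-3s", at$name))
  con <- file(path, "w")
  on.exit(close(con))
  nf <- n_frames(traj)
  for (m in seq_len(nf)) {
    writeLines(sprintf("MODEL     %4d", m), con)
    xyz <- frame_coords(traj, m)
    writeLines(sprintf(
      "ATOM  %5d %s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial, fmt_name, at$resname, at$chain, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1.00, 0.00,
      toupper(substr(at$element, 1, 2))), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## ---------------------------------------------------------------------------
## XYZ

#' Read a multi-frame XYZ trajectory
#'
#' Standard XYZ layout: atom count line, comment line, then one
#' `element x y z` line per atom, repeated per frame. Element symbols are
#' retained as atom names.
#'
#' @param path Path to an XYZ file.
#' @return A [trajectory]; atom names are stored in attribute `"elements"`.
#' @export
read_xyz_traj <- function(path) {
  if (!file.exists(path)) stop("read_xyz_traj: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) > length(lines))]
  if (length(lines) == 0 || all(!nzchar(trimws(lines))))
    stop("read_xyz_traj: empty file")
  pos <- 1L
  frames <- list()
  elements <- NULL
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 1)
      stop("read_xyz_traj: invalid atom count at line ", pos)
    if (pos + 1L + n > length(lines))
      stop("read_xyz_traj: truncated frame starting at line ", pos)
    block <- lines[(pos + 2L):(pos + 1L + n)]
    parts <- strsplit(trimws(block), "[[:space:]]+")
    if (any(lengths(parts) < 4))
      stop("read_xyz_traj: malformed atom line in frame starting at line ", pos)
    el <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(is.na(xyz)))
      stop("read_xyz_traj: unparseable coordinate in frame starting at line ",
           pos)
    if (is.null(elements)) elements <- el
    else if (length(el) != length(elements))
      stop("read_xyz_traj: inconsistent atom counts across frames (frame ",
           length(frames) + 1L, ")")
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  coords <- array(NA_real_, dim = c(length(frames), length(elements), 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  traj <- trajectory(coords)
  attr(traj, "elements") <- elements
  traj
}

#' Write a trajectory in multi-frame XYZ format
#'
#' @param path Output path.
#' @param traj A [trajectory].
#' @param elements Character vector of element symbols (defaults to the
#'   trajectory's `"elements"` attribute, then to `"C"`).
#' @return Invisibly, `path`.
#' @export
write_xyz_traj <- function(path, traj, elements = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  na <- n_atoms(traj)
  if (is.null(elements)) elements <- attr(traj, "elements")
  if (is.null(elements)) elements <- rep("C", na)
  if (length(elements) != na)
    stop("write_xyz_traj: elements length does not match atom count")
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_len(n_frames(traj))) {
    writeLines(as.character(na), con)
    writeLines(sprintf("frame %d", m), con)
    xyz <- frame_coords(traj, m)
    writeLines(sprintf("%-2s %14.6f %14.6f %14.6f",
                       elements, xyz[, 1], xyz[, 2], xyz[, 3]), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Energy component tables

## Header vocabulary accepted for SIE component tables. The canonical
## internal names are E_vdw, E_coul, E_rf, E_cav.
.energy_aliases <- list(
  E_vdw = c("E_vdw", "Evdw", "Inter vdW", "Inter.vdW", "vdw"),
  E_coul = c("E_coul", "Ecoul", "Inter Coulomb", "Inter.Coulomb", "coulomb"),
  E_rf = c("E_rf", "Erf", "Reaction Field", "Reaction.Field", "rf"),
  E_cav = c("E_cav", "Ecav", "Cavity", "cavity"))

#' Read a delimited SIE energy-component table
#'
#' Reads a comma- or tab-delimited table with a header naming the four
#' interaction-energy component columns. Both canonical names (`E_vdw`,
#' `E_coul`, `E_rf`, `E_cav`) and table vocabulary (`Inter vdW`,
#' `Inter Coulomb`, `Reaction Field`, `Cavity`) are accepted. All other
#' columns (system labels, replicate ids, reference `dG`) pass through
#' unchanged. Energies are in kcal/mol.
#'
#' @param path Path to the delimited file.
#' @return A data.frame of class `energy_table` with canonical component
#'   column names, rows in file order.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("read_energy_table: file not found: ", path)
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  for (canon in names(.energy_aliases)) {
    hit <- which(names(df) %in% .energy_aliases[[canon]])
    if (length(hit) == 0)
      stop("read_energy_table: missing component column '", canon,
           "' (accepted headers: ",
           paste(.energy_aliases[[canon]], collapse = ", "), ")")
    names(df)[hit[1]] <- canon
  }
  for (canon in names(.energy_aliases)) {
    v <- df[[canon]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      if (any(is.na(parsed) & !is.na(v)))
        stop("read_energy_table: non-numeric value in column '", canon,
             "' at row ", which(is.na(parsed) & !is.na(v))[1])
      df[[canon]] <- parsed
    }
    if (nrow(df) > 0 && any(!is.finite(df[[canon]])))
      stop("read_energy_table: non-finite energy in column '", canon, "'")
  }
  class(df) <- c("energy_table", class(df))
  df
}

#' Write an SIE energy-component table
#'
#' @param path Output path.
#' @param table data.frame carrying at least the four component columns.
#' @param sep Field separator (default tab).
#' @return Invisibly, `path`.
#' @export
write_energy_table <- function(path, table, sep = "\t") {
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Config

#' Read a pipeline configuration file
#'
#' Accepts YAML or JSON; the format is chosen by extension (`.json` for
#' JSON, anything else parsed as YAML, of which JSON is a subset).
#'
#' @param path Path to the config file.
#' @return A named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("read_config: file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
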