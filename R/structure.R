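# Structure model: atom tables, PDB I/O, trajectories, force-field assignment.
#
# Internal length unit is nm throughout the package; PDB files carry Angstrom
# and are converted on read/write.

#' Construct a structure from an atom table
#'
#' A structure is a plain atom table (one row per atom) plus an entity map
#' labelling each chain as `"toxin"` or `"channel"`. Interface operations
#' (contacts, energies, grafting) require at least one chain of each entity.
#'
#' @param atoms data frame with columns `serial`, `name`, `element`,
#'   `resname`, `chain`, `resno`, `x`, `y`, `z` (coordinates in nm). Optional
#'   columns `charge` (e), `sigma` (nm), `epsilon` (kJ/mol) are added as `NA`
#'   if absent.
#' @param entity_map named character vector mapping chain id to `"toxin"` or
#'   `"channel"`; may be `NULL` and assigned later with [set_entities()].
#' @return an object of class `toxsel_structure`.
#' @export
new_structure <- function(atoms, entity_map = NULL) {
  required <- c("serial", "name", "element", "resname", "chain", "resno",
                "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in c("charge", "sigma", "epsilon")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite atom coordinates")
  }
  atoms$chain <- as.character(atoms$chain)
  atoms$name <- as.character(atoms$name)
  atoms$resname <- as.character(atoms$resname)
  rownames(atoms) <- NULL
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue number, atom name): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  s <- structure(list(atoms = atoms, entity_map = NULL),
                 class = "toxsel_structure")
  if (!is.null(entity_map)) s <- set_entities(s, entity_map)
  s
}

#' Label chains as toxin or channel
#'
#' @param s a `toxsel_structure`.
#' @param entity_map named character vector, e.g.
#'   `c(A = "toxin", B = "channel")`. Every chain present in the structure
#'   must be covered.
#' @return the structure with its entity map set.
#' @export
set_entities <- function(s, entity_map) {
  stopifnot(inherits(s, "toxsel_structure"))
  chains <- unique(s$atoms$chain)
  if (!all(chains %in% names(entity_map))) {
    stop("entity_map does not cover chain(s): ",
         paste(setdiff(chains, names(entity_map)), collapse = ", "))
  }
  bad <- setdiff(unique(unname(entity_map)), c("toxin", "channel"))
  if (length(bad) > 0L) stop("entities must be 'toxin' or 'channel'")
  s$entity_map <- entity_map[chains]
  s
}

#' @export
print.toxsel_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno")]))
  cat(sprintf("<toxsel_structure> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), nres,
              paste(unique(x$atoms$chain), collapse = ",")))
  if (!is.null(x$entity_map)) {
    cat("  entities:",
        paste(sprintf("%s=%s", names(x$entity_map), x$entity_map),
              collapse = " "), "\n")
  }
  invisible(x)
}

# n x 3 coordinate matrix of a structure (nm)
#' @export
coords_matrix <- function(s) {
  stopifnot(inherits(s, "toxsel_structure"))
  as.matrix(s$atoms[, c("x", "y", "z")])
}

#' @export
set_coords <- function(s, coords) {
  stopifnot(inherits(s, "toxsel_structure"),
            nrow(coords) == nrow(s$atoms), ncol(coords) == 3L)
  s$atoms$x <- coords[, 1]
  s$atoms$y <- coords[, 2]
  s$atoms$z <- coords[, 3]
  s
}

# "chain:resno" keys, one per atom or unique per residue
residue_keys <- function(s, unique = FALSE) {
  k <- paste(s$atoms$chain, s$atoms$resno, sep = ":")
  if (unique) unique(k) else k
}

# entity of every atom, from the chain entity map
atom_entities <- function(s) {
  if (is.null(s$entity_map)) stop("structure has no entity map")
  unname(s$entity_map[s$atoms$chain])
}

is_hydrogen <- function(element) toupper(element) == "H"

guess_element <- function(name) {
  core <- gsub("[0-9']", "", trimws(name))
  ifelse(nchar(core) == 0L, "X", substr(core, 1L, 1L))
}

#' Read a PDB structure
#'
#' Parses ATOM/HETATM records of a PDB v3.3 file. Coordinates are converted
#' from Angstrom to nm; chain ids, residue names and author residue numbers
#' are preserved in file order (channel-specific numbering such as Glu353
#' survives the round trip).
#'
#' @param text a file path, or a character vector of PDB lines.
#' @param entity_map optional chain entity map, passed to [set_entities()].
#' @return a `toxsel_structure`.
#' @export
read_pdb <- function(text, entity_map = NULL) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text) else text
  rec <- substr(lines, 1L, 6L)
  sel <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(sel) == 0L) stop("no ATOM/HETATM records found")
  parse_atom_lines(lines[sel], sel, entity_map = entity_map)
}

parse_atom_lines <- function(lines, line_numbers, entity_map = NULL) {
  num <- function(str, what, i) {
    v <- suppressWarnings(as.numeric(str))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      stop(sprintf("malformed PDB record at line %d: bad %s field '%s'",
                   line_numbers[bad[1L]], what, str[bad[1L]]))
    }
    v
  }
  short <- which(nchar(lines) < 54L)
  if (length(short) > 0L) {
    stop(sprintf("malformed PDB record at line %d: line shorter than 54 columns",
                 line_numbers[short[1L]]))
  }
  name <- trimws(substr(lines, 13L, 16L))
  element <- trimws(substr(lines, 77L, 78L))
  element[element == ""] <- guess_element(name[element == ""])
  atoms <- data.frame(
    serial = as.integer(num(substr(lines, 7L, 11L), "serial", seq_along(lines))),
    name = name,
    element = element,
    resname = trimws(substr(lines, 18L, 20L)),
    chain = substr(lines, 22L, 22L),
    resno = as.integer(num(substr(lines, 23L, 26L), "residue number",
                           seq_along(lines))),
    x = num(substr(lines, 31L, 38L), "x", seq_along(lines)) / 10,
    y = num(substr(lines, 39L, 46L), "y", seq_along(lines)) / 10,
    z = num(substr(lines, 47L, 54L), "z", seq_along(lines)) / 10,
    stringsAsFactors = FALSE
  )
  new_structure(atoms, entity_map = entity_map)
}

#' Write a structure as PDB text
#'
#' Inverse of [read_pdb()]: nm coordinates are written in Angstrom at the
#' standard `%8.3f` precision.
#'
#' @param s a `toxsel_structure`.
#' @param path optional output file; when `NULL` the text is returned only.
#' @return character vector of PDB lines, invisibly when `path` is given.
#' @export
write_pdb <- function(s, path = NULL) {
  lines <- c(format_atom_lines(s), "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

format_atom_lines <- function(s) {
  a <- s$atoms
  # atom name placement: names < 4 chars start in column 14
  nm <- ifelse(nchar(a$name) >= 4L, substr(a$name, 1L, 4L),
               sprintf(" %-3s", a$name))
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          a$serial %% 100000L, nm, a$resname, a$chain, a$resno,
          a$x * 10, a$y * 10, a$z * 10, 1, 0, substr(a$element, 1L, 2L))
}

#' Construct a trajectory
#'
#' @param topology a `toxsel_structure` supplying atoms, residues and entity
#'   labels.
#' @param frames list of n x 3 coordinate matrices (nm), each with exactly the
#'   topology's atom count.
#' @param times optional numeric vector of frame times (ns).
#' @return an object of class `toxsel_trajectory`.
#' @export
new_trajectory <- function(topology, frames, times = NULL) {
  stopifnot(inherits(topology, "toxsel_structure"))
  n_atoms <- nrow(topology$atoms)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr) || nrow(fr) != n_atoms || ncol(fr) != 3L) {
      stop(sprintf("frame %d does not match topology atom count (%d)",
                   i, n_atoms))
    }
  }
  if (length(frames) == 0L) stop("trajectory must contain at least one frame")
  if (!is.null(times) && length(times) != length(frames)) {
    stop("times length must equal frame count")
  }
  structure(list(topology = topology, frames = frames, times = times),
            class = "toxsel_trajectory")
}

#' @export
print.toxsel_trajectory <- function(x, ...) {
  cat(sprintf("<toxsel_trajectory> %d frames x %d atoms\n",
              length(x$frames), nrow(x$topology$atoms)))
  invisible(x)
}

#' @export
n_frames <- function(traj) length(traj$frames)

#' Read a multi-model PDB as a trajectory
#'
#' Each `MODEL`/`ENDMDL` block becomes one frame; the topology is taken from
#' the first model. All models must share an identical atom roster (same
#' chain / residue number / atom name sequence).
#'
#' @param text file path or character vector of PDB lines.
#' @param entity_map optional chain entity map.
#' @return a `toxsel_trajectory`. A file without MODEL records yields a
#'   single-frame trajectory.
#' @export
read_multimodel_pdb <- function(text, entity_map = NULL) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text) else text
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0L) {
    topo <- read_pdb(lines, entity_map = entity_map)
    return(new_trajectory(topo, list(coords_matrix(topo))))
  }
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records")
  }
  topo <- NULL
  roster <- NULL
  frames <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    blk <- lines[(model_starts[m] + 1L):(model_ends[m] - 1L)]
    keep <- grepl("^(ATOM  |HETATM)", blk)
    st <- parse_atom_lines(blk[keep], model_starts[m] + which(keep))
    this_roster <- paste(st$atoms$chain, st$atoms$resno, st$atoms$name)
    if (m == 1L) {
      topo <- st
      roster <- this_roster
    } else if (!identical(this_roster, roster)) {
      stop(sprintf("model %d atom roster differs from model 1", m))
    }
    frames[[m]] <- coords_matrix(st)
  }
  if (!is.null(entity_map)) topo <- set_entities(topo, entity_map)
  new_trajectory(topo, frames)
}

#' Write a trajectory as multi-model PDB text
#'
#' @param traj a `toxsel_trajectory`.
#' @param path optional output file.
#' @return character vector of PDB lines, invisibly when `path` is given.
#' @export
write_multimodel_pdb <- function(traj, path = NULL) {
  stopifnot(inherits(traj, "toxsel_trajectory"))
  out <- character(0)
  s <- traj$topology
  for (m in seq_along(traj$frames)) {
    s <- set_coords(s, traj$frames[[m]])
    out <- c(out, sprintf("MODEL     %4d", m), format_atom_lines(s), "ENDMDL")
  }
  out <- c(out, "END")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---- force-field table ----------------------------------------------------

#' Coulomb constant in kJ mol-1 nm e-2
#' @export
COULOMB_CONSTANT <- 138.935458

#' Read a force-field parameter table
#'
#' The table is a TSV with columns `resname`, `atomname`, `charge` (e),
#' `sigma_nm`, `epsilon_kJmol`, keyed by (residue name, atom name). Lookup
#' must be total over any structure it is applied to.
#'
#' @param path TSV file.
#' @return an object of class `toxsel_forcefield`.
#' @seealso [default_forcefield()] for the bundled reduced table.
#' @export
read_forcefield <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  required <- c("resname", "atomname", "charge", "sigma_nm", "epsilon_kJmol")
  if (!all(required %in% names(tab))) {
    stop("force-field table lacks column(s): ",
         paste(setdiff(required, names(tab)), collapse = ", "))
  }
  if (any(tab$sigma_nm < 0) || any(tab$epsilon_kJmol < 0)) {
    stop("sigma and epsilon must be non-negative")
  }
  key <- paste(tab$resname, tab$atomname)
  if (anyDuplicated(key)) {
    stop("duplicate force-field entries: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  structure(list(table = tab, coulomb_constant = COULOMB_CONSTANT,
                 combination_rule = "lorentz-berthelot"),
            class = "toxsel_forcefield")
}

#' Bundled reduced force-field table
#'
#' A small parameter table for the residue types emitted by the synthetic
#' generator, with deliberately round values (|q| in 0/0.5/1 e, sigma in
#' 0.30/0.35 nm) so that every energy assertion is analytically checkable.
#' It is a stand-in for a full biomolecular force field, not a port of one.
#'
#' @return a `toxsel_forcefield`.
#' @export
default_forcefield <- function() {
  read_forcefield(system.file("extdata", "forcefield_reduced.tsv",
                              package = "toxsel", mustWork = TRUE))
}

#' Assign per-atom non-bonded parameters
#'
#' Copies partial charge, LJ sigma and epsilon onto every atom from a
#' force-field table. The assignment is total: a single missing
#' (residue, atom) entry aborts with the full list of unmatched atoms.
#'
#' @param s a `toxsel_structure`.
#' @param ff a `toxsel_forcefield`.
#' @return the structure with `charge`, `sigma`, `epsilon` columns filled;
#'   also carries class `toxsel_parameterized`.
#' @export
assign_parameters <- function(s, ff) {
  stopifnot(inherits(s, "toxsel_structure"), inherits(ff, "toxsel_forcefield"))
  if (nrow(s$atoms) == 0L) {
    class(s) <- unique(c("toxsel_parameterized", class(s)))
    return(s)
  }
  key <- paste(s$atoms$resname, s$atoms$name)
  idx <- match(key, paste(ff$table$resname, ff$table$atomname))
  if (anyNA(idx)) {
    stop("no force-field entry for atom(s): ",
         paste(unique(key[is.na(idx)]), collapse = "; "))
  }
  s$atoms$charge <- ff$table$charge[idx]
  s$atoms$sigma <- ff$table$sigma_nm[idx]
  s$atoms$epsilon <- ff$table$epsilon_kJmol[idx]
  attr(s, "coulomb_constant") <- ff$coulomb_constant
  class(s) <- unique(c("toxsel_parameterized", class(s)))
  s
}

is_parameterized <- function(s) {
  inherits(s, "toxsel_parameterized") && !anyNA(s$atoms$charge)
}
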