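#' Construct a trajectory object
#'
#' A trajectory couples an atom table to an ordered set of coordinate
#' frames.  Coordinates are stored as a frames-by-3N matrix in Angstrom,
#' each row laid out `x1, y1, z1, x2, ...` (the bio3d `xyz` convention),
#' and every frame carries a system tag so that frames retain their
#' provenance through splitting and concatenation.
#'
#' @param atoms Data frame with columns `chain`, `resid` (1-based residue
#'   id) and `name` (atom name, e.g. `"CA"`).
#' @param xyz Numeric matrix, one row per frame, `3 * nrow(atoms)` columns.
#' @param system Character vector of per-frame system tags (recycled if
#'   length 1).
#' @param aligned Logical flag recording whether the frames have been
#'   superposed onto a common reference (see [align_to_mean()]).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, system = "system", aligned = FALSE) {
  atoms <- as.data.frame(atoms)
  req <- c("chain", "resid", "name")
  if (!all(req %in% names(atoms))) {
    abort_invalid("`atoms` must have columns chain, resid, name")
  }
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    abort_structural(sprintf(
      "coordinate width %d does not match 3 x %d atoms", ncol(xyz), nrow(atoms)
    ))
  }
  if (length(system) == 1L) system <- rep(system, nrow(xyz))
  if (length(system) != nrow(xyz)) {
    abort_invalid("`system` must have one tag per frame")
  }
  structure(
    list(atoms = atoms, xyz = xyz, system = as.character(system),
         aligned = isTRUE(aligned)),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d frames x %d atoms (%d chains), systems: %s%s\n",
    n_frames(x), n_atoms(x), length(unique(x$atoms$chain)),
    paste(unique(x$system), collapse = ", "),
    if (x$aligned) " [aligned]" else ""
  ))
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj A [trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(traj) nrow(traj$atoms)

# Light structural validation of a multi-model PDB text file.  bio3d's
# reader is deliberately permissive (it recycles coordinates when models
# disagree and accepts empty files), so the error contract lives here.
validate_pdb_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  atom_line <- rec %in% c("ATOM  ", "HETATM")
  if (!any(atom_line)) {
    abort_parse(sprintf("no ATOM records found in '%s'", path))
  }
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0L) return(invisible(1L))
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_ends) != length(model_starts)) {
    abort_parse(sprintf(
      "unbalanced MODEL/ENDMDL records in '%s' (%d MODEL, %d ENDMDL)",
      path, length(model_starts), length(model_ends)
    ))
  }
  counts <- vapply(seq_along(model_starts), function(i) {
    sum(atom_line[model_starts[i]:model_ends[i]])
  }, integer(1))
  if (length(unique(counts)) != 1L) {
    bad <- which(counts != counts[1L])[1L]
    abort_structural(sprintf(
      "MODEL %d in '%s' has %d atoms; MODEL 1 has %d",
      bad, path, counts[bad], counts[1L]
    ))
  }
  invisible(length(model_starts))
}

#' Read a trajectory from a multi-model PDB file
#'
#' MODEL records become frames in file order; coordinates are taken in
#' Angstrom.  The file is validated first: every model must contain the
#' same number of atoms and at least one ATOM record must be present.
#'
#' @param path Path to a PDB file (single- or multi-model).
#' @param system System tag attached to every frame; defaults to the file
#'   name without extension.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, system = NULL) {
  if (!file.exists(path)) abort_invalid(sprintf("file '%s' does not exist", path))
  validate_pdb_text(path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atoms <- data.frame(
    chain = pdb$atom$chain,
    resid = pdb$atom$resno,
    name = pdb$atom$elety,
    stringsAsFactors = FALSE
  )
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1L)
  trajectory(atoms, unclass(xyz),
             system = system %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Write a trajectory to a multi-model PDB file
#'
#' One MODEL/ENDMDL block is written per frame.  Per-residue scalar
#' annotations (e.g. mode r.m.s.f. values) can be written into the
#' B-factor column for downstream colour-gradient rendering.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param b Optional numeric vector of per-atom B-factor values.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path, b = NULL) {
  if (n_frames(traj) == 0L) abort_invalid("cannot write a zero-frame trajectory")
  bio3d::write.pdb(
    file = path,
    xyz = traj$xyz,
    resno = traj$atoms$resid,
    chain = traj$atoms$chain,
    resid = rep("GLY", n_atoms(traj)),
    elety = traj$atoms$name,
    b = if (is.null(b)) rep(0, n_atoms(traj)) else b
  )
  # one MODEL/ENDMDL block per frame, even for a single frame
  if (n_frames(traj) == 1L) {
    lines <- readLines(path, warn = FALSE)
    first <- which(grepl("^(ATOM|HETATM)", lines))[1L]
    last <- max(which(grepl("^(ATOM|HETATM|TER)", lines)))
    lines <- append(lines, "ENDMDL", after = last)
    lines <- append(lines, "MODEL        1", after = first - 1L)
    writeLines(lines, path)
  }
  invisible(path)
}

#' Restrict a trajectory to its C-alpha atoms
#'
#' @param traj A [trajectory()].
#' @return A [trajectory()] containing only atoms named `CA`, in the
#'   original order.
#' @export
select_calpha <- function(traj) {
  keep <- which(traj$atoms$name == "CA")
  if (length(keep) == 0L) abort_selection("trajectory contains no CA atoms")
  cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
  trajectory(traj$atoms[keep, , drop = FALSE],
             traj$xyz[, cols, drop = FALSE],
             system = traj$system, aligned = traj$aligned)
}

#' Split a trajectory into one trajectory per chain
#'
#' Every output trajectory keeps all frames (and their system tags); only
#' the atom dimension is partitioned, so total atom count is conserved.
#' Chains are emitted in chain-id order.
#'
#' @param traj A [trajectory()].
#' @return Named list of [trajectory()] objects, one per chain id.
#' @export
split_chains <- function(traj) {
  chains <- sort(unique(traj$atoms$chain))
  out <- lapply(chains, function(ch) {
    keep <- which(traj$atoms$chain == ch)
    cols <- as.vector(rbind(3L * keep - 2L, 3L * keep - 1L, 3L * keep))
    trajectory(traj$atoms[keep, , drop = FALSE],
               traj$xyz[, cols, drop = FALSE],
               system = traj$system, aligned = traj$aligned)
  })
  names(out) <- chains
  out
}

#' Read a residue correspondence map
#'
#' Two-column tab-separated text (`from`, `to`) giving a bijective residue
#' id correspondence between homologous systems of equal construct length.
#'
#' @param path Path to the map file.
#' @return Data frame with integer columns `from` and `to`.
#' @export
read_residue_map <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t")
  names(m)[1:2] <- c("from", "to")
  if (anyDuplicated(m$from) || anyDuplicated(m$to)) {
    abort_mapping("residue map is not bijective")
  }
  m
}

#' Concatenate trajectories into one combined trajectory
#'
#' Frames are appended in input order and retain their source system tag;
#' the atom table is taken from the first input.  By default residues are
#' matched by position under the identity map (equal-length constructs);
#' a `map` reorders/filters later inputs so residue `from` lines up with
#' residue `to` of the first input.
#'
#' @param trajs List of [trajectory()] objects with a single chain each
#'   (or identical atom layouts).
#' @param map Optional residue map (`data.frame(from, to)`) applied to
#'   inputs after the first; `NULL` means the identity map.
#' @return A combined [trajectory()].
#' @export
concatenate_trajectories <- function(trajs, map = NULL) {
  if (length(trajs) == 0L) abort_invalid("no trajectories to concatenate")
  first <- trajs[[1L]]
  if (is.null(map)) {
    n <- vapply(trajs, n_atoms, integer(1))
    if (length(unique(n)) != 1L) {
      abort_mapping(sprintf(
        "atom counts differ across inputs (%s); supply a residue map",
        paste(unique(n), collapse = ", ")
      ))
    }
    pieces <- trajs
  } else {
    ref_idx <- match(map$to, first$atoms$resid)
    if (anyNA(ref_idx)) {
      abort_mapping(sprintf(
        "map targets not present in first input: %s",
        paste(map$to[is.na(ref_idx)], collapse = ", ")
      ))
    }
    first <- subset_atoms(first, ref_idx)
    pieces <- c(list(first), lapply(trajs[-1L], function(tr) {
      idx <- match(map$from, tr$atoms$resid)
      if (anyNA(idx)) {
        abort_mapping(sprintf(
          "unmappable residues: %s", paste(map$from[is.na(idx)], collapse = ", ")
        ))
      }
      subset_atoms(tr, idx)
    }))
    n <- vapply(pieces, n_atoms, integer(1))
    if (length(unique(n)) != 1L) {
      abort_mapping("mapped atom counts still differ across inputs")
    }
  }
  trajectory(
    first$atoms,
    do.call(rbind, lapply(pieces, function(tr) tr$xyz)),
    system = unlist(lapply(pieces, function(tr) tr$system), use.names = FALSE),
    aligned = FALSE
  )
}

subset_atoms <- function(traj, idx) {
  cols <- as.vector(rbind(3L * idx - 2L, 3L * idx - 1L, 3L * idx))
  trajectory(traj$atoms[idx, , drop = FALSE], traj$xyz[, cols, drop = FALSE],
             system = traj$system, aligned = traj$aligned)
}
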