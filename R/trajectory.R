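#' Trajectory container
#'
#' A `trajectory` holds the atom roster of a protein-ligand complex plus
#' per-frame coordinates. Atoms carry PDB author numbering (1-based
#' residue numbers, no renumbering) so residue labels such as Phe141 or
#' Asp184 can be addressed directly. Coordinates are stored in Angstrom
#' as an `n_atoms x 3 x n_frames` array.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno`, `chain`.
#' @param xyz numeric array `n_atoms x 3 x n_frames` (a plain
#'   `n_atoms x 3` matrix is promoted to a single frame).
#' @param frame_labels optional numeric time stamps (ns), one per frame.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(atoms, xyz, frame_labels = NULL) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("serial", "name", "element", "resname", "resno", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop_input("trajectory: atoms table lacks column(s) %s",
               paste(miss, collapse = ", "))
  if (any(!nzchar(atoms$element)))
    stop_input("trajectory: every atom needs a non-empty element symbol")
  if (is.matrix(xyz)) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  if (length(dim(xyz)) != 3L || dim(xyz)[2] != 3L)
    stop_input("trajectory: xyz must be an n_atoms x 3 x n_frames array")
  if (dim(xyz)[1] != nrow(atoms))
    stop_input("trajectory: %d atoms but coordinates for %d",
               nrow(atoms), dim(xyz)[1])
  if (dim(xyz)[3] < 1L) stop_input("trajectory: need at least one frame")
  if (!is.null(frame_labels) && length(frame_labels) != dim(xyz)[3])
    stop_input("trajectory: %d frame labels for %d frames",
               length(frame_labels), dim(xyz)[3])
  structure(list(atoms = atoms, xyz = xyz, frame_labels = frame_labels),
            class = "trajectory")
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$xyz)[3]

#' @rdname trajectory
#' @export
n_atoms <- function(traj) dim(traj$xyz)[1]

#' Coordinates of one frame
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `n_atoms x 3` matrix.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj))
    stop_input("frame_coords: frame %d out of range 1..%d", i, n_frames(traj))
  traj$xyz[, , i, drop = TRUE]
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms x %d frame(s)\n", n_atoms(x), n_frames(x)))
  res <- unique(paste(x$atoms$resname, x$atoms$resno))
  cat(sprintf("  residues: %s\n",
              paste(utils::head(res, 8L), collapse = ", ")))
  if (length(res) > 8L) cat(sprintf("  ... and %d more\n", length(res) - 8L))
  invisible(x)
}

# ---- multi-model PDB I/O ---------------------------------------------------

# Count ATOM/HETATM records per MODEL block; used both to pre-validate
# (consistent atom counts across models, with the offending model named)
# and to detect the single-block (no MODEL record) dialect.
scan_model_counts <- function(lines) {
  starts <- grep("^MODEL", lines)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (length(starts) == 0L) return(sum(is_atom))
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  vapply(seq_along(starts), function(k) {
    sum(is_atom[starts[k]:ends[k]])
  }, integer(1))
}

#' Read a multi-model PDB file as a trajectory
#'
#' Parses a fixed-column PDB file whose MODEL/ENDMDL blocks are the
#' trajectory frames (a file without MODEL records is a single frame).
#' All models must contain the same atoms; author residue numbering is
#' kept as-is. When alternate locations are present, the
#' highest-occupancy altloc is kept (ties: first encountered) and a
#' message notes the choice. Hydrogens are ordinary atoms; none are
#' inferred.
#'
#' @param path PDB file path.
#' @return a [trajectory()].
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop_input("read_multimodel_pdb: no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  counts <- scan_model_counts(lines)
  if (length(counts) == 0L || sum(counts) == 0L)
    stop_input("read_multimodel_pdb: no ATOM/HETATM records in %s", path)
  if (length(counts) > 1L && length(unique(counts)) > 1L) {
    bad <- which(counts != counts[1L])[1L]
    stop_input("read_multimodel_pdb: model %d: %d atoms, expected %d",
               bad, counts[bad], counts[1L])
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e)
      stop_input("read_multimodel_pdb: cannot parse %s: %s",
                 path, conditionMessage(e)))

  atom <- pdb$atom
  keep <- seq_len(nrow(atom))
  alt <- atom$alt
  if (any(!is.na(alt) & nzchar(alt))) {
    key <- paste(atom$resid, atom$resno, atom$chain, atom$elety)
    occ <- atom$o
    occ[is.na(occ)] <- 1
    keep <- unlist(lapply(split(seq_len(nrow(atom)), key), function(idx) {
      idx[which.max(occ[idx])]   # ties -> first encountered
    }), use.names = FALSE)
    keep <- sort(keep)
    if (length(keep) < nrow(atom))
      message(sprintf("read_multimodel_pdb: kept highest-occupancy altloc for %d atom site(s)",
                      nrow(atom) - length(keep)))
  }

  nfr <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  xyzmat <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1L)
  nat_all <- ncol(xyzmat) / 3L
  arr <- array(NA_real_, dim = c(length(keep), 3L, nfr))
  for (f in seq_len(nfr)) {
    m <- matrix(xyzmat[f, ], ncol = 3L, byrow = TRUE)
    arr[, , f] <- m[keep, , drop = FALSE]
  }
  elem <- atom$elesy[keep]
  blank <- is.na(elem) | !nzchar(trimws(elem))
  # element column absent in minimal files: fall back to first letter of name
  elem[blank] <- substr(gsub("[0-9]", "", trimws(atom$elety[keep][blank])), 1L, 1L)
  atoms <- data.frame(serial = atom$eleno[keep],
                      name = trimws(atom$elety[keep]),
                      element = trimws(elem),
                      resname = trimws(atom$resid[keep]),
                      resno = atom$resno[keep],
                      chain = ifelse(is.na(atom$chain[keep]), "A", atom$chain[keep]),
                      stringsAsFactors = FALSE)
  trajectory(atoms, arr)
}

#' Write a trajectory as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-column dialect, coordinates
#' printed to 3 decimals (PDB precision).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  a <- traj$atoms
  nf <- n_frames(traj)
  xyzmat <- matrix(NA_real_, nrow = nf, ncol = 3L * n_atoms(traj))
  for (f in seq_len(nf)) xyzmat[f, ] <- as.vector(t(traj$xyz[, , f]))
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     xyz = if (nf == 1L) xyzmat[1L, ] else xyzmat,
                     type = rep("ATOM", nrow(a)),
                     eleno = a$serial, elety = a$name, resid = a$resname,
                     chain = a$chain, resno = a$resno, elesy = a$element)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_input("write_multimodel_pdb: cannot write %s", path)
  invisible(path)
}

# ---- atom selection --------------------------------------------------------

#' Resolve an atom selector to atom indices
#'
#' Selector grammar: one or more clauses separated by `";"`, each clause
#' `"RESNAME RESNO NAMES"` where `RESNAME` is a residue name or `*`,
#' `RESNO` a residue number or `*`, and `NAMES` a comma-separated list of
#' atom names or `*`. Examples: `"ASP 184 OD1,OD2"`, `"LIG * NP"`,
#' `"* * N,CA,C,O"`. The result is ordered by atom serial; an empty
#' result is an error because every declared interaction participant
#' must exist.
#'
#' @param traj a [trajectory()].
#' @param selector selector string.
#' @return integer vector of atom indices (rows of `traj$atoms`).
#' @export
resolve_selection <- function(traj, selector) {
  if (!is.character(selector) || length(selector) != 1L || !nzchar(trimws(selector)))
    stop_config("resolve_selection: selector must be a non-empty string")
  a <- traj$atoms
  hits <- logical(nrow(a))
  for (clause in strsplit(selector, ";", fixed = TRUE)[[1L]]) {
    parts <- strsplit(trimws(clause), "[[:space:]]+")[[1L]]
    if (length(parts) != 3L)
      stop_config("resolve_selection: bad clause '%s' (want 'RESNAME RESNO NAMES')",
                  trimws(clause))
    ok <- rep(TRUE, nrow(a))
    if (parts[1L] != "*") ok <- ok & a$resname == parts[1L]
    if (parts[2L] != "*") {
      rn <- suppressWarnings(as.integer(parts[2L]))
      if (is.na(rn))
        stop_config("resolve_selection: residue number '%s' is not an integer", parts[2L])
      ok <- ok & a$resno == rn
    }
    if (parts[3L] != "*") {
      nms <- strsplit(parts[3L], ",", fixed = TRUE)[[1L]]
      ok <- ok & a$name %in% trimws(nms)
    }
    hits <- hits | ok
  }
  idx <- which(hits)
  if (length(idx) == 0L)
    stop_config("resolve_selection: selector '%s' matches no atom", selector)
  idx[order(a$serial[idx])]
}
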