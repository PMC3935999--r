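# Average and monoisotopic atomic masses (Da) for the elements that occur in
# the charged groups handled here.
.MASS_AVERAGE <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.973762, S = 32.06)
.MASS_MONO <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
                O = 15.9949146196, P = 30.97376163, S = 31.972071)

#' Atomic mass lookup
#'
#' @param element Character vector of element symbols.
#' @param scale `"average"` or `"monoisotopic"`.
#' @return Numeric vector of masses in Da.
#' @export
atomic_mass <- function(element, scale = c("average", "monoisotopic")) {
  scale <- match.arg(scale)
  tab <- if (scale == "average") .MASS_AVERAGE else .MASS_MONO
  m <- tab[toupper(element)]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Mass change upon succinimide ring formation
#'
#' Cyclization of an Asp (or Asn) side chain into a succinimide ring is a
#' condensation that expels one water molecule, so the protein loses the
#' mass of H2O. This loss (about 18 Da) is the mass-spectrometric signature
#' used to follow succinimide formation and relaxation.
#'
#' @param mass_scale `"average"` (default) or `"monoisotopic"`.
#' @return Mass of one water molecule in Da (positive number; the protein
#'   mass *decreases* by this amount).
#' @examples
#' round(mass_delta_cyclization())               # 18
#' round(mass_delta_cyclization("monoisotopic"), 3)
#' @export
mass_delta_cyclization <- function(mass_scale = c("average", "monoisotopic")) {
  mass_scale <- match.arg(mass_scale)
  2 * atomic_mass("H", mass_scale) + atomic_mass("O", mass_scale)
}

# Element symbol from a PDB atom name when the element column is blank:
# first alphabetic character works for the C/N/O/P/S names used here.
.infer_element <- function(name) {
  sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name)
}

#' Construct a structure object
#'
#' A structure is an ordered table of atoms grouped into residues by
#' `(chain, resi)`. By convention chain `"A"` holds the protein (PSD-95
#' numbering 302-403) and chain `"B"` the hexapeptide ligand (numbered
#' -5..0, residue 0 being the C-terminal Val).
#'
#' @param atoms `data.frame` with columns `chain`, `resi` (integer),
#'   `resn` (3-letter code), `atom` (atom name), `element`, `x`, `y`, `z`
#'   (Angstrom).
#' @param title Free-text title.
#' @param modifications Optional named character vector of residue
#'   modification tags, names of the form `"A:332"`; values are one of
#'   `"phospho-Tyr"` or `"succinimide"`. Modified residues keep their
#'   standard residue code so plain PDB readers still work.
#' @return An object of class `pdz_structure`.
#' @export
structure_model <- function(atoms, title = "", modifications = NULL) {
  req <- c("chain", "resi", "resn", "atom", "element", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss)) stop("atoms table missing column(s): ",
                         paste(miss, collapse = ", "))
  atoms$resi <- as.integer(atoms$resi)
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (any(!nzchar(atoms$atom))) stop("empty atom name")
  key <- paste(atoms$chain, atoms$resi, atoms$atom, sep = ":")
  if (anyDuplicated(key)) {
    stop("duplicate atom within residue: ", key[duplicated(key)][1])
  }
  rownames(atoms) <- NULL
  x <- list(atoms = atoms, title = title,
            modifications = modifications %||% character())
  class(x) <- "pdz_structure"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pdz_structure <- function(x, ...) {
  rk <- unique(paste(x$atoms$chain, x$atoms$resi, sep = ":"))
  cat("<pdz_structure> ", length(rk), " residues, ", nrow(x$atoms),
      " atoms", if (nzchar(x$title)) paste0(" - ", x$title), "\n", sep = "")
  invisible(x)
}

#' Extract one residue from a structure
#'
#' @param structure A `pdz_structure`.
#' @param chain Chain tag.
#' @param resi Integer residue index (verbatim input numbering).
#' @return List with `code`, `chain`, `index`, `atoms` (data.frame) and
#'   `modification` (`"none"` when untagged).
#' @export
get_residue <- function(structure, chain, resi) {
  sel <- structure$atoms$chain == chain & structure$atoms$resi == resi
  if (!any(sel)) stop("residue ", chain, ":", resi, " not found")
  at <- structure$atoms[sel, , drop = FALSE]
  mod <- structure$modifications[paste(chain, resi, sep = ":")]
  list(code = at$resn[1], chain = chain, index = as.integer(resi),
       atoms = at,
       modification = if (is.na(mod) || length(mod) == 0) "none"
                      else unname(mod))
}

# ---------------------------------------------------------------------------
# PDB I/O. No R PDB reader ships with the supported stack, so the small
# fixed-width ATOM/HETATM + MODEL/ENDMDL subset is implemented here.
# ---------------------------------------------------------------------------

.parse_atom_line <- function(line, lineno) {
  line <- formatC(line, width = -80)   # right-pad to full record width
  f <- function(a, b) substr(line, a, b)
  xyz <- suppressWarnings(as.numeric(c(f(31, 38), f(39, 46), f(47, 54))))
  if (anyNA(xyz)) {
    stop("malformed coordinate field on line ", lineno, ": ",
         trimws(substr(line, 1, 54)))
  }
  resi <- suppressWarnings(as.integer(trimws(f(23, 26))))
  if (is.na(resi)) stop("malformed residue number on line ", lineno)
  el <- trimws(f(77, 78))
  nm <- trimws(f(13, 16))
  if (!nzchar(el)) el <- .infer_element(nm)
  data.frame(chain = trimws(f(22, 22)), resi = resi,
             resn = trimws(f(18, 20)), atom = nm, element = el,
             x = xyz[1], y = xyz[2], z = xyz[3],
             stringsAsFactors = FALSE)
}

#' Parse a PDB document into a structure
#'
#' Reads ATOM/HETATM records; residue numbering is preserved verbatim
#' (negative ligand indices included). Duplicate atom names within a
#' residue are rejected.
#'
#' @param text Character vector of PDB lines, or a single string with
#'   embedded newlines, or a file path (existing file).
#' @return A [structure_model()] object.
#' @export
parse_structure <- function(text) {
  lines <- .as_lines(text)
  sel <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(sel)) stop("no ATOM/HETATM records found")
  idx <- which(sel)
  rows <- lapply(seq_along(idx),
                 function(i) .parse_atom_line(lines[idx[i]], idx[i]))
  at <- do.call(rbind, rows)
  ttl <- sub("^TITLE\\s+", "", grep("^TITLE", lines, value = TRUE)[1])
  structure_model(at, title = if (is.na(ttl)) "" else trimws(ttl))
}

.as_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    return(readLines(text, warn = FALSE))
  }
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

#' Serialize a structure to PDB lines
#'
#' @param structure A `pdz_structure`.
#' @return Character vector of PDB lines (no trailing END).
#' @export
write_structure <- function(structure) {
  at <- structure$atoms
  name4 <- ifelse(nchar(at$atom) >= 4, substr(at$atom, 1, 4),
                  paste0(" ", formatC(at$atom, width = -3)))
  sprintf("ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          seq_len(nrow(at)) %% 100000, name4, at$resn, at$chain, at$resi,
          at$x, at$y, at$z, at$element)
}

#' Construct a trajectory object
#'
#' Frames share one topology; coordinates live in an `n_atoms x 3 x
#' n_frames` array so per-frame contact analysis can be vectorized.
#'
#' @param topology Atom table as in [structure_model()] minus coordinates
#'   (coordinate columns are ignored if present).
#' @param coords Numeric array `c(n_atoms, 3, n_frames)`, Angstrom.
#' @param frame_interval Time per frame in ps (> 0; trajectories in the
#'   underlying study were recorded every 2 ps).
#' @param modifications As in [structure_model()].
#' @return Object of class `pdz_trajectory`.
#' @export
trajectory_model <- function(topology, coords, frame_interval = 2,
                             modifications = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  if (dim(coords)[1] != nrow(topology)) {
    stop("coords first dimension must match topology rows")
  }
  if (dim(coords)[3] < 1) stop("trajectory needs at least one frame")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be > 0")
  }
  topology <- topology[setdiff(names(topology), c("x", "y", "z"))]
  x <- list(topology = topology, coords = coords,
            frame_interval = frame_interval,
            modifications = modifications %||% character())
  class(x) <- "pdz_trajectory"
  x
}

#' @export
print.pdz_trajectory <- function(x, ...) {
  cat("<pdz_trajectory> ", dim(x$coords)[3], " frames x ",
      nrow(x$topology), " atoms, dt = ", x$frame_interval, " ps\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `pdz_trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a structure
#' @param traj A `pdz_trajectory`.
#' @param i Frame index (1-based).
#' @export
frame_structure <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  at <- traj$topology
  at$x <- traj$coords[, 1, i]
  at$y <- traj$coords[, 2, i]
  at$z <- traj$coords[, 3, i]
  structure_model(at, modifications = traj$modifications)
}

#' Parse a multi-model PDB into a trajectory
#'
#' MODEL/ENDMDL blocks must share topology (same chain/residue/atom
#' sequence); a frame missing an atom relative to frame 1 is a topology
#' error. A file without MODEL records parses as a single-frame trajectory.
#'
#' @inheritParams parse_structure
#' @param frame_interval Time per frame, ps.
#' @return A [trajectory_model()] object.
#' @export
parse_trajectory <- function(text, frame_interval = 2) {
  lines <- .as_lines(text)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0) {
    s <- parse_structure(lines)
    return(trajectory_model(s$atoms,
                            array(as.matrix(s$atoms[c("x", "y", "z")]),
                                  dim = c(nrow(s$atoms), 3, 1)),
                            frame_interval))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL records")
  frames <- lapply(seq_along(starts), function(k) {
    parse_structure(lines[(starts[k] + 1):(ends[k] - 1)])
  })
  ref <- frames[[1]]$atoms
  key <- function(a) paste(a$chain, a$resi, a$atom, sep = ":")
  refkey <- key(ref)
  coords <- array(NA_real_, dim = c(nrow(ref), 3, length(frames)))
  for (k in seq_along(frames)) {
    a <- frames[[k]]$atoms
    if (nrow(a) != nrow(ref) || !all(key(a) == refkey)) {
      stop("topology error: frame ", k,
           " does not match frame 1 atom list")
    }
    coords[, , k] <- as.matrix(a[c("x", "y", "z")])
  }
  trajectory_model(ref, coords, frame_interval)
}

#' Serialize a trajectory as a multi-model PDB
#' @param traj A `pdz_trajectory`.
#' @return Character vector of PDB lines.
#' @export
write_trajectory <- function(traj) {
  out <- vector("list", n_frames(traj))
  for (k in seq_len(n_frames(traj))) {
    out[[k]] <- c(sprintf("MODEL     %4d", k),
                  write_structure(frame_structure(traj, k)),
                  "ENDMDL")
  }
  c(unlist(out), "END")
}

#' Check study-specific residue numbering conventions
#'
#' Protein chain indices must lie in 302..403 (numbering relative to
#' full-length PSD-95) and ligand chain indices in -5..0 (hexapeptide,
#' 0 = C-terminal Val).
#'
#' @param structure A `pdz_structure` or `pdz_trajectory`.
#' @param protein_chain,ligand_chain Chain tags (defaults `"A"`, `"B"`).
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
check_pdz_numbering <- function(structure, protein_chain = "A",
                                ligand_chain = "B") {
  at <- if (inherits(structure, "pdz_trajectory")) structure$topology
        else structure$atoms
  p <- unique(at$resi[at$chain == protein_chain])
  l <- unique(at$resi[at$chain == ligand_chain])
  bad_p <- p[p < 302 | p > 403]
  bad_l <- l[l < -5 | l > 0]
  if (length(bad_p)) stop("protein residue index outside 302..403: ",
                          paste(bad_p, collapse = ", "))
  if (length(bad_l)) stop("ligand residue index outside -5..0: ",
                          paste(bad_l, collapse = ", "))
  invisible(TRUE)
}
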