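# Charged-group chemistry used by the salt-bridge criteria. A "group" is a
# formal-charge-carrying set of atoms plus the two carbons that immediately
# precede it along the covalent chain ("anchor carbons"). The geometric
# criteria measure either anchor-carbon distances or the mass centers of the
# charged atoms themselves.

#' Default charged-group scheme
#'
#' Side-chain groups: Lys (NZ; anchors CD,CE, +), Arg (guanidinium
#' NE/NH1/NH2; anchors CD,CZ, +), Glu (OE1/OE2; anchors CG,CD, -),
#' Asp (OD1/OD2; anchors CB,CG, -). Terminal groups: the N-terminal
#' ammonium (N; anchors CA,CB, or CA,C for Gly, +) and the C-terminal
#' carboxylate (O/OXT; anchors CA,C, -). A `phospho-Tyr` modification tag
#' adds a phosphate group (O1P/O2P/O3P; ring anchors CE1,CE2, -). The
#' chain is never enumerated in structural terms by the geometric
#' definition itself, so this table is a documented, overridable choice.
#'
#' @return A list with elements `sidechain` (per residue code), `nterm`,
#'   `cterm`, and `phospho_tyr`, each holding `charged`, `anchors` and
#'   `sign`.
#' @export
default_charge_scheme <- function() {
  list(
    sidechain = list(
      LYS = list(charged = "NZ", anchors = c("CD", "CE"), sign = +1L),
      ARG = list(charged = c("NE", "NH1", "NH2"),
                 anchors = c("CD", "CZ"), sign = +1L),
      GLU = list(charged = c("OE1", "OE2"),
                 anchors = c("CG", "CD"), sign = -1L),
      ASP = list(charged = c("OD1", "OD2"),
                 anchors = c("CB", "CG"), sign = -1L)
    ),
    nterm = list(charged = "N", anchors = c("CA", "CB"),
                 anchors_gly = c("CA", "C"), sign = +1L),
    cterm = list(charged = c("O", "OXT"), anchors = c("CA", "C"),
                 sign = -1L),
    phospho_tyr = list(charged = c("O1P", "O2P", "O3P"),
                       anchors = c("CE1", "CE2"), sign = -1L)
  )
}

# Resolve which charged group a residue carries under `group = "auto"`:
# a phospho-Tyr tag wins; then a charged side chain; then the ligand
# C-terminal carboxylate (index 0); then the ligand N-terminal ammonium
# (index -5). Anything else has no charge under the scheme.
.resolve_group <- function(residue, scheme, group = "auto") {
  if (group == "auto") {
    if (identical(residue$modification, "phospho-Tyr")) {
      group <- "phospho_tyr"
    } else if (residue$code %in% names(scheme$sidechain) &&
               !identical(residue$modification, "succinimide")) {
      group <- "sidechain"
    } else if (residue$index == 0L) {
      group <- "cterm"
    } else if (residue$index == -5L) {
      group <- "nterm"
    } else {
      stop("residue ", residue$chain, ":", residue$index, " (",
           residue$code, ") carries no charged group under the scheme")
    }
  }
  g <- switch(group,
              sidechain = scheme$sidechain[[residue$code]],
              nterm = scheme$nterm,
              cterm = scheme$cterm,
              phospho_tyr = scheme$phospho_tyr,
              stop("unknown group kind: ", group))
  if (is.null(g)) {
    stop("residue type ", residue$code, " has no ", group,
         " charged group in the scheme")
  }
  if (group == "nterm" && residue$code == "GLY") {
    g$anchors <- g$anchors_gly
  }
  g$anchors_gly <- NULL
  g
}

#' Anchor-carbon atom names of a residue's charged group
#'
#' Returns the two carbons immediately preceding the charged atoms along
#' the covalent chain; these are the atoms whose minimum cross-distance
#' defines the 5-Angstrom salt-bridge criterion.
#'
#' @param residue A residue as returned by [get_residue()].
#' @param scheme A charge scheme, see [default_charge_scheme()].
#' @param group `"auto"` (default), `"sidechain"`, `"nterm"`, `"cterm"` or
#'   `"phospho_tyr"`.
#' @return Character vector of exactly two atom names.
#' @examples
#' sch <- default_charge_scheme()
#' sch$sidechain$LYS$anchors  # CD, CE
#' @export
anchor_atoms <- function(residue, scheme = default_charge_scheme(),
                         group = "auto") {
  g <- .resolve_group(residue, scheme, group)
  stopifnot(length(g$anchors) == 2L)
  g$anchors
}

#' Charge sign of a residue under the scheme
#' @inheritParams anchor_atoms
#' @return `+1` or `-1`.
#' @export
charge_sign <- function(residue, scheme = default_charge_scheme(),
                        group = "auto") {
  .resolve_group(residue, scheme, group)$sign
}

#' Mass-weighted center of a residue's charged atoms
#'
#' @inheritParams anchor_atoms
#' @return Numeric 3-vector (Angstrom).
#' @export
charged_group_center <- function(residue, scheme = default_charge_scheme(),
                                 group = "auto") {
  g <- .resolve_group(residue, scheme, group)
  at <- residue$atoms
  sel <- match(g$charged, at$atom)
  if (anyNA(sel)) {
    stop("incomplete residue ", residue$chain, ":", residue$index,
         ": missing charged atom(s) ",
         paste(g$charged[is.na(sel)], collapse = ", "))
  }
  m <- atomic_mass(at$element[sel])
  xyz <- as.matrix(at[sel, c("x", "y", "z")])
  unname(colSums(xyz * m) / sum(m))
}

# Row indices (into an atom table) of a group's anchor or charged atoms,
# with an informative error naming the residue and atom when absent.
.atom_rows <- function(atoms, chain, resi, wanted) {
  sel <- which(atoms$chain == chain & atoms$resi == resi)
  if (!length(sel)) stop("residue ", chain, ":", resi, " not found")
  idx <- sel[match(wanted, atoms$atom[sel])]
  if (anyNA(idx)) {
    stop("incomplete residue ", chain, ":", resi, ": missing atom(s) ",
         paste(wanted[is.na(match(wanted, atoms$atom[sel]))],
               collapse = ", "))
  }
  idx
}
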