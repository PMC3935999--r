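# Per-frame salt-bridge detection and occupancy statistics.
#
# Two geometric criteria are supported:
#   * anchor_carbon (default, cutoff 5 A): a bridge is formed when the
#     minimum distance over the 2x2 cross pairs of anchor carbons is
#     strictly below the cutoff;
#   * charged_center (cutoff 4 A): formed when the mass centers of the two
#     charged-atom groups are strictly closer than the cutoff.
# On well-separated geometries the two give equivalent occupancies.

.PAIR_CATEGORIES <- c("ligand-b2b3loop", "ligand-a3helix", "ligand-other",
                      "a3helix-b2b3loop", "a3helix-domain")

#' Contact criterion for salt-bridge detection
#'
#' @param mode `"anchor_carbon"` or `"charged_center"`.
#' @param cutoff Distance cutoff in Angstrom; defaults to 5.0 for
#'   anchor-carbon mode and 4.0 for charged-center mode. Comparison is a
#'   strict `<`.
#' @return Object of class `contact_criterion`.
#' @export
contact_criterion <- function(mode = c("anchor_carbon", "charged_center"),
                              cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "anchor_carbon") 5.0 else 4.0
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  structure(list(mode = mode, cutoff = cutoff), class = "contact_criterion")
}

#' Specify a candidate salt-bridge pair
#'
#' @param a,b Residues as `c(chain, index)` character/integer pairs, e.g.
#'   `c("B", -5)` for ligand Lys(-5) or `c("A", 331)` for Glu331.
#' @param category Table category label, one of `"ligand-b2b3loop"`,
#'   `"ligand-a3helix"`, `"ligand-other"`, `"a3helix-b2b3loop"`,
#'   `"a3helix-domain"`.
#' @param label Optional display label; a default is built from the
#'   residues.
#' @param group_a,group_b Charged-group selector passed to
#'   [anchor_atoms()] (`"auto"` by default).
#' @return Object of class `pair_spec`.
#' @export
pair_spec <- function(a, b, category = "ligand-other", label = NULL,
                      group_a = "auto", group_b = "auto") {
  category <- match.arg(category, .PAIR_CATEGORIES)
  a <- list(chain = as.character(a[[1]]), resi = as.integer(a[[2]]))
  b <- list(chain = as.character(b[[1]]), resi = as.integer(b[[2]]))
  if (is.null(label)) {
    label <- paste0(a$chain, a$resi, "-", b$chain, b$resi)
  }
  structure(list(a = a, b = b, category = category, label = label,
                 group_a = group_a, group_b = group_b),
            class = "pair_spec")
}

# Validate that the two members carry opposite signs (when both resolve).
.check_pair_signs <- function(structure, pair,
                              scheme = default_charge_scheme()) {
  ra <- get_residue(structure, pair$a$chain, pair$a$resi)
  rb <- get_residue(structure, pair$b$chain, pair$b$resi)
  sa <- charge_sign(ra, scheme, pair$group_a)
  sb <- charge_sign(rb, scheme, pair$group_b)
  if (sa == sb) {
    stop("pair ", pair$label, " members carry the same charge sign")
  }
  invisible(TRUE)
}

# Per-pair distance over all frames, vectorized across the frame axis.
.pair_distance_frames <- function(traj, pair, scheme, metric) {
  at <- traj$topology
  res_of <- function(side, grp) {
    r <- list(code = at$resn[at$chain == side$chain &
                               at$resi == side$resi][1],
              chain = side$chain, index = side$resi,
              modification = {
                m <- traj$modifications[paste(side$chain, side$resi,
                                              sep = ":")]
                if (length(m) == 0 || is.na(m)) "none" else unname(m)
              })
    if (is.na(r$code)) stop("residue ", side$chain, ":", side$resi,
                            " not found")
    r
  }
  ra <- res_of(pair$a); rb <- res_of(pair$b)
  if (metric == "anchor_min") {
    ga <- anchor_atoms(ra, scheme, pair$group_a)
    gb <- anchor_atoms(rb, scheme, pair$group_b)
    ia <- .atom_rows(at, pair$a$chain, pair$a$resi, ga)
    ib <- .atom_rows(at, pair$b$chain, pair$b$resi, gb)
    nfr <- dim(traj$coords)[3]
    dmin <- rep(Inf, nfr)
    for (i in ia) for (j in ib) {
      dv <- traj$coords[i, , , drop = FALSE] - traj$coords[j, , , drop = FALSE]
      d <- sqrt(colSums(matrix(dv, nrow = 3)^2))
      dmin <- pmin(dmin, d)
    }
    dmin
  } else { # center
    center_frames <- function(side, grp, res) {
      g <- .resolve_group(res, scheme, grp)
      ii <- .atom_rows(at, side$chain, side$resi, g$charged)
      m <- atomic_mass(at$element[ii])
      cm <- matrix(0, nrow = 3, ncol = dim(traj$coords)[3])
      for (k in seq_along(ii)) {
        cm <- cm + m[k] * matrix(traj$coords[ii[k], , ], nrow = 3)
      }
      cm / sum(m)
    }
    ca <- center_frames(pair$a, pair$group_a, ra)
    cb <- center_frames(pair$b, pair$group_b, rb)
    sqrt(colSums((ca - cb)^2))
  }
}

#' Is a salt bridge formed in a single frame?
#'
#' @param frame A `pdz_structure` (one frame).
#' @param pair A [pair_spec()].
#' @param criterion A [contact_criterion()].
#' @param scheme A charge scheme.
#' @return Logical scalar; `TRUE` when the criterion distance is strictly
#'   below the cutoff.
#' @export
contact_state <- function(frame, pair, criterion = contact_criterion(),
                          scheme = default_charge_scheme()) {
  traj <- trajectory_model(frame$atoms,
                           array(as.matrix(frame$atoms[c("x", "y", "z")]),
                                 dim = c(nrow(frame$atoms), 3, 1)),
                           modifications = frame$modifications)
  metric <- if (criterion$mode == "anchor_carbon") "anchor_min" else "center"
  d <- .pair_distance_frames(traj, pair, scheme, metric)
  d < criterion$cutoff
}

#' Per-frame contact states of a pair along a trajectory
#'
#' @param traj A `pdz_trajectory`.
#' @inheritParams contact_state
#' @return Object of class `state_series`: list with `pair` and logical
#'   `states` (one per frame, frame order preserved).
#' @export
state_series <- function(traj, pair, criterion = contact_criterion(),
                         scheme = default_charge_scheme()) {
  metric <- if (criterion$mode == "anchor_carbon") "anchor_min" else "center"
  d <- .pair_distance_frames(traj, pair, scheme, metric)
  structure(list(pair = pair, states = d < criterion$cutoff),
            class = "state_series")
}

.states_of <- function(x) {
  if (inherits(x, "state_series")) x$states
  else if (is.logical(x)) x
  else stop("expected a state_series or logical vector")
}

#' Contact occupancy (frequency of formation)
#'
#' Fraction of frames in which the contact is formed.
#'
#' @param series A `state_series` or logical vector.
#' @return Fraction in `[0, 1]`.
#' @export
occupancy <- function(series) {
  s <- .states_of(series)
  if (length(s) == 0) stop("empty state series")
  mean(s)
}

#' Occupancy of "at least one of" a set of contacts
#'
#' @param series_set List of `state_series`/logical vectors of equal
#'   length.
#' @return Fraction of frames in which at least one member is formed.
#' @export
any_of_occupancy <- function(series_set) {
  ss <- lapply(series_set, .states_of)
  n <- lengths(ss)
  if (length(unique(n)) != 1) stop("state series length mismatch")
  if (n[1] == 0) stop("empty state series")
  mean(Reduce(`|`, ss))
}

#' Helix undocked fraction
#'
#' The C-terminal alpha-3 helix is taken to be docked onto the PDZ3 core
#' in a frame when at least one of the Glu334-Arg399 or Lys355-Glu401
#' salt bridges is formed, and undocked when neither is. (Published
#' tabulations of this quantity label the first bridge "Glu334-Asp399" in
#' one place and Arg399 elsewhere; residue 399 is an Arg and only
#' Glu334-Arg399 is supported.)
#'
#' @inheritParams state_series
#' @param protein_chain Chain tag of the protein (default `"A"`).
#' @return Fraction of frames with neither bridge formed; equals
#'   `1 - any_of_occupancy()` of the two bridges.
#' @export
helix_undocked_fraction <- function(traj, criterion = contact_criterion(),
                                    scheme = default_charge_scheme(),
                                    protein_chain = "A") {
  prs <- helix_bridge_pairs(protein_chain)
  ss <- lapply(prs, function(p) state_series(traj, p, criterion, scheme))
  1 - any_of_occupancy(ss)
}

#' The two helix-anchoring salt-bridge pairs
#' @param protein_chain Chain tag of the protein.
#' @return List of two [pair_spec()]s: Glu334-Arg399 and Lys355-Glu401.
#' @export
helix_bridge_pairs <- function(protein_chain = "A") {
  list(
    pair_spec(c(protein_chain, 334), c(protein_chain, 399),
              category = "a3helix-domain", label = "Glu334-Arg399"),
    pair_spec(c(protein_chain, 355), c(protein_chain, 401),
              category = "a3helix-domain", label = "Lys355-Glu401")
  )
}

#' Agreement between the two contact criteria
#'
#' @inheritParams state_series
#' @param anchor_criterion,center_criterion The two criteria to compare.
#' @return List with `agreement` (fraction of frames where both criteria
#'   give the same state), `occupancy_anchor` and `occupancy_center`.
#' @export
criterion_agreement <- function(traj, pair,
                                scheme = default_charge_scheme(),
                                anchor_criterion = contact_criterion("anchor_carbon"),
                                center_criterion = contact_criterion("charged_center")) {
  sa <- state_series(traj, pair, anchor_criterion, scheme)$states
  sc <- state_series(traj, pair, center_criterion, scheme)$states
  list(agreement = mean(sa == sc),
       occupancy_anchor = mean(sa),
       occupancy_center = mean(sc))
}

#' Distance time series between two charged residues
#'
#' @inheritParams state_series
#' @param a,b Residues as `c(chain, index)`.
#' @param metric `"anchor_min"` (minimum over anchor-carbon cross pairs)
#'   or `"center"` (charged-group mass centers).
#' @param group_a,group_b Charged-group selectors.
#' @return `data.frame` with columns `time_ps` and `distance` (Angstrom).
#' @export
distance_series <- function(traj, a, b, scheme = default_charge_scheme(),
                            metric = c("anchor_min", "center"),
                            group_a = "auto", group_b = "auto") {
  metric <- match.arg(metric)
  pair <- pair_spec(a, b, group_a = group_a, group_b = group_b)
  d <- .pair_distance_frames(traj, pair, scheme, metric)
  data.frame(time_ps = (seq_along(d) - 1) * traj$frame_interval,
             distance = d)
}

#' Occupancy table with per-pair and aggregate rows
#'
#' Reproduces the layout of published salt-bridge frequency tables:
#' per-pair percentages grouped by category, followed by named aggregate
#' rows ("at least one of" a set of pairs) and the helix undocked
#' fraction.
#'
#' @inheritParams state_series
#' @param pairs List of [pair_spec()]s.
#' @param aggregates Named list; each element is an integer vector of
#'   indices into `pairs`, aggregated with [any_of_occupancy()]. The
#'   special name prefix `"non-formation:"` reports `1 - any_of`.
#' @return Object of class `occupancy_table`: a `data.frame` with columns
#'   `category`, `label`, `frequency`, `percent`, plus attributes
#'   `n_frames` and `criterion`.
#' @export
occupancy_table <- function(traj, pairs, aggregates = list(),
                            criterion = contact_criterion(),
                            scheme = default_charge_scheme()) {
  series <- lapply(pairs, function(p) state_series(traj, p, criterion,
                                                   scheme))
  rows <- data.frame(
    category = vapply(pairs, function(p) p$category, ""),
    label = vapply(pairs, function(p) p$label, ""),
    frequency = vapply(series, occupancy, 0),
    stringsAsFactors = FALSE
  )
  if (length(aggregates)) {
    ag <- lapply(names(aggregates), function(nm) {
      idx <- aggregates[[nm]]
      f <- any_of_occupancy(series[idx])
      if (startsWith(nm, "non-formation:")) f <- 1 - f
      data.frame(category = "aggregate", label = nm, frequency = f,
                 stringsAsFactors = FALSE)
    })
    rows <- rbind(rows, do.call(rbind, ag))
  }
  rows$percent <- round(100 * rows$frequency, 1)
  attr(rows, "n_frames") <- n_frames(traj)
  attr(rows, "criterion") <- criterion
  class(rows) <- c("occupancy_table", "data.frame")
  rows
}

#' Write an occupancy table as tab-delimited text
#' @param x An `occupancy_table`.
#' @param path Output file path.
#' @export
write_occupancy_table <- function(x, path) {
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f%%", df$percent)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_frames=%d criterion=%s cutoff=%g",
                     attr(x, "n_frames"), attr(x, "criterion")$mode,
                     attr(x, "criterion")$cutoff), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
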