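# Seeded generators producing inputs with the statistical structure the
# analysis stages assume: two-state Markov contact trajectories (with
# competition between bridges sharing a partner), noisy one-site ITC
# titrations, and fast-exchange HSQC titration peak lists. Every generator
# emits a truth record sufficient to score downstream estimates.
#
# The trajectory generator reproduces occupancy statistics, not physics:
# residues are reduced to the atoms the contact criteria need, placed in
# tight clusters whose center-to-center distances are set exactly per
# frame (formed vs broken), plus sub-cutoff positional jitter.

#' Residue identities for the PDZ3/KKETAV system
#'
#' Protein chain "A" (full-length PSD-95 numbering) and ligand chain "B"
#' (KKETAV, 0 = C-terminal Val).
#'
#' @return Named character vector, names of the form `"A:331"`.
#' @export
pdz3_residue_codes <- function() {
  c("A:331" = "GLU", "A:332" = "ASP", "A:334" = "GLU", "A:355" = "LYS",
    "A:373" = "GLU", "A:397" = "TYR", "A:399" = "ARG", "A:401" = "GLU",
    "A:403" = "LYS",
    "B:-5" = "LYS", "B:-4" = "LYS", "B:-3" = "GLU", "B:-2" = "THR",
    "B:-1" = "ALA", "B:0" = "VAL")
}

#' Specification for a synthetic contact trajectory
#'
#' @param pairs List of [pair_spec()]s (one per candidate bridge).
#' @param pi Target stationary occupancies in `[0, 1]`, one per pair.
#' @param dwell Mean dwell time of the formed state, frames (>= 1); the
#'   default 50 frames is a placeholder (the emulated simulations publish
#'   no bridge autocorrelation data).
#' @param n_frames Number of frames.
#' @param competition_groups List of integer vectors indexing `pairs`;
#'   within a group at most one member is formed per frame and the
#'   stationary occupancies must sum to <= 1. Group members are sampled
#'   by a per-frame categorical draw (marginal occupancies are honoured;
#'   dwell times inside groups are not).
#' @param formed_distance,broken_distance Center-to-center distances (A)
#'   realized for formed / broken states; defaults 4.0 and 7.0.
#' @param jitter_sd Per-coordinate Gaussian jitter (A); validated so the
#'   geometry can never cross the 5-A anchor cutoff.
#' @param frame_interval ps per frame (default 2).
#' @param residue_codes Named map `"chain:resi" -> 3-letter code`
#'   ([pdz3_residue_codes()] by default).
#' @param seed Integer seed.
#' @return Object of class `trajectory_spec`.
#' @export
trajectory_spec <- function(pairs, pi, dwell = 50, n_frames = 1000,
                            competition_groups = list(),
                            formed_distance = 4.0, broken_distance = 7.0,
                            jitter_sd = 0.05, frame_interval = 2,
                            residue_codes = pdz3_residue_codes(),
                            seed = 1L) {
  if (length(pi) != length(pairs)) stop("pi must have one entry per pair")
  if (any(pi < 0 | pi > 1)) stop("occupancies must lie in [0, 1]")
  dwell <- rep_len(dwell, length(pairs))
  if (any(dwell < 1)) stop("mean dwell must be >= 1 frame")
  for (g in competition_groups) {
    if (sum(pi[g]) > 1 + 1e-12) {
      stop("competition group occupancies sum to > 1")
    }
  }
  # geometric margins: cluster extent + jitter must never cross the 5-A
  # anchor cutoff from either side
  extent <- 2 * 0.15 + 10 * jitter_sd
  if (formed_distance + extent >= 5) {
    stop("formed_distance + jitter can cross the 5-A cutoff")
  }
  if (broken_distance - extent <= 5) {
    stop("broken_distance - jitter can cross the 5-A cutoff")
  }
  structure(list(pairs = pairs, pi = pi, dwell = dwell,
                 n_frames = as.integer(n_frames),
                 competition_groups = competition_groups,
                 formed_distance = formed_distance,
                 broken_distance = broken_distance,
                 jitter_sd = jitter_sd, frame_interval = frame_interval,
                 residue_codes = residue_codes, seed = as.integer(seed)),
            class = "trajectory_spec")
}

# Two-state Markov chain with stationary occupancy pi and mean formed
# dwell d: leave-formed rate q10 = 1/d, enter rate q01 = pi q10 / (1-pi)
# (stationarity), initialized from the stationary distribution.
.sim_two_state <- function(n, pi, dwell) {
  if (pi <= 0) return(rep(FALSE, n))
  if (pi >= 1) return(rep(TRUE, n))
  q10 <- 1 / dwell
  q01 <- pi * q10 / (1 - pi)
  if (q01 > 1) {
    stop("dwell ", dwell, " too short for stationary occupancy ", pi)
  }
  s <- logical(n)
  u <- stats::runif(n)
  s[1] <- u[1] < pi
  for (t in 2:n) {
    s[t] <- if (s[t - 1]) u[t] >= q10 else u[t] < q01
  }
  s
}

#' Standard error of an occupancy estimate from a two-state chain
#'
#' Dwell-corrected: the lag-1 autocorrelation of the chain is
#' `rho = 1 - q01 - q10`, giving effective sample size
#' `n (1 - rho) / (1 + rho)`.
#'
#' @param pi Stationary occupancy.
#' @param dwell Mean formed dwell, frames.
#' @param n Number of frames.
#' @return Standard error of the frame-average occupancy.
#' @export
occupancy_se <- function(pi, dwell, n) {
  if (pi <= 0 || pi >= 1) return(0)
  q10 <- 1 / dwell
  q01 <- pi * q10 / (1 - pi)
  rho <- 1 - q01 - q10
  sqrt(pi * (1 - pi) / n * (1 + rho) / (1 - rho))
}

# Well-separated unit directions (icosahedron vertices) used to place
# sibling edges at a node.
.DIRS <- {
  phi <- (1 + sqrt(5)) / 2
  m <- rbind(c(0, 1, phi), c(0, -1, phi), c(0, 1, -phi), c(0, -1, -phi),
             c(1, phi, 0), c(-1, phi, 0), c(1, -phi, 0), c(-1, -phi, 0),
             c(phi, 0, 1), c(-phi, 0, 1), c(phi, 0, -1), c(-phi, 0, -1))
  m / sqrt(rowSums(m^2))
}

# Union-find cycle detection; the pair graph must be a forest so every
# configured distance can be realized exactly as a tree-edge length.
.check_forest <- function(edges, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in seq_len(nrow(edges))) {
    a <- find(edges[e, 1]); b <- find(edges[e, 2])
    if (a == b) {
      stop("pair constraint graph contains a cycle; drop one pair of ",
           "the cycle (distances on a cycle cannot all be set exactly)")
    }
    parent[a] <- b
  }
  invisible(TRUE)
}

#' Generate a synthetic contact trajectory with per-frame truth
#'
#' Each pair outside a competition group follows an independent two-state
#' Markov chain with the prescribed stationary occupancy and mean dwell;
#' competition groups are sampled per frame so at most one member forms.
#' Coordinates realize formed/broken states as exact center distances
#' along a spanning tree of the pair graph (which must be acyclic), plus
#' Gaussian jitter small enough never to cross the 5-A anchor cutoff.
#'
#' @param spec A [trajectory_spec()].
#' @return List with `trajectory` (a `pdz_trajectory`), `truth` (list:
#'   `states` logical matrix frames x pairs, `pi`, `dwell`, `labels`,
#'   `seed`) and `spec`.
#' @export
gen_contact_trajectory <- function(spec) {
  stopifnot(inherits(spec, "trajectory_spec"))
  set.seed(spec$seed)
  np <- length(spec$pairs)
  n <- spec$n_frames

  # --- states ---------------------------------------------------------
  states <- matrix(FALSE, nrow = n, ncol = np)
  grouped <- unlist(spec$competition_groups)
  for (g in spec$competition_groups) {
    probs <- c(spec$pi[g], 1 - sum(spec$pi[g]))
    draw <- sample.int(length(g) + 1L, n, replace = TRUE, prob = probs)
    for (k in seq_along(g)) states[, g[k]] <- draw == k
  }
  for (j in setdiff(seq_len(np), grouped)) {
    states[, j] <- .sim_two_state(n, spec$pi[j], spec$dwell[j])
  }

  # --- geometry -------------------------------------------------------
  node_key <- unique(unlist(lapply(spec$pairs, function(p) {
    c(paste(p$a$chain, p$a$resi, sep = ":"),
      paste(p$b$chain, p$b$resi, sep = ":"))
  })))
  nid <- stats::setNames(seq_along(node_key), node_key)
  edges <- t(vapply(spec$pairs, function(p) {
    c(nid[[paste(p$a$chain, p$a$resi, sep = ":")]],
      nid[[paste(p$b$chain, p$b$resi, sep = ":")]])
  }, integer(2)))
  .check_forest(edges, length(node_key))

  # BFS forest: centers[[node]] is a 3 x n matrix of per-frame positions
  adj <- lapply(seq_along(node_key), function(i) {
    which(edges[, 1] == i | edges[, 2] == i)
  })
  centers <- vector("list", length(node_key))
  dist_per_edge <- function(j) {
    ifelse(states[, j], spec$formed_distance, spec$broken_distance)
  }
  comp_id <- 0
  placed <- rep(FALSE, length(node_key))
  for (root in seq_along(node_key)) {
    if (placed[root]) next
    comp_id <- comp_id + 1
    centers[[root]] <- matrix(c(60 * comp_id, 0, 0), nrow = 3, ncol = n)
    placed[root] <- TRUE
    queue <- root
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      kdir <- 0
      for (j in adj[[v]]) {
        w <- if (edges[j, 1] == v) edges[j, 2] else edges[j, 1]
        if (placed[w]) next
        kdir <- kdir + 1
        u <- .DIRS[(sum(edges[, 1] < v) + kdir - 1) %% nrow(.DIRS) + 1, ]
        d <- dist_per_edge(j)
        centers[[w]] <- centers[[v]] + outer(u, d)
        placed[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }

  # --- atoms ----------------------------------------------------------
  scheme <- default_charge_scheme()
  atom_rows <- list()
  offsets <- list()
  for (key in node_key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    chain <- parts[1]; resi <- as.integer(parts[2])
    code <- spec$residue_codes[[key]]
    if (is.null(code)) stop("no residue code configured for ", key)
    res <- list(code = code, chain = chain, index = resi,
                modification = "none")
    g <- .resolve_group(res, scheme, "auto")
    nm <- unique(c(g$anchors, g$charged, "CA"))
    # fixed intra-cluster offsets: anchors at +/-0.15 A, others <= 0.05 A
    off <- matrix(0, nrow = length(nm), ncol = 3)
    axis <- .DIRS[(nid[[key]] - 1) %% nrow(.DIRS) + 1, ]
    off[match(g$anchors[1], nm), ] <- 0.15 * axis
    off[match(g$anchors[2], nm), ] <- -0.15 * axis
    others <- setdiff(nm, g$anchors)
    for (k in seq_along(others)) {
      off[match(others[k], nm), ] <-
        0.05 * .DIRS[(k - 1) %% nrow(.DIRS) + 1, ]
    }
    atom_rows[[key]] <- data.frame(
      chain = chain, resi = resi, resn = code, atom = nm,
      element = .infer_element(nm), stringsAsFactors = FALSE)
    offsets[[key]] <- off
  }
  topo <- do.call(rbind, atom_rows)
  rownames(topo) <- NULL
  natoms <- nrow(topo)
  coords <- array(0, dim = c(natoms, 3, n))
  row0 <- 0
  for (key in node_key) {
    nr <- nrow(atom_rows[[key]])
    ctr <- centers[[nid[[key]]]]             # 3 x n
    off <- offsets[[key]]                    # nr x 3
    for (k in seq_len(nr)) {
      coords[row0 + k, , ] <- ctr + off[k, ]
    }
    row0 <- row0 + nr
  }
  if (spec$jitter_sd > 0) {
    coords <- coords + stats::rnorm(length(coords), sd = spec$jitter_sd)
  }

  traj <- trajectory_model(topo, coords, spec$frame_interval)
  labels <- vapply(spec$pairs, function(p) p$label, "")
  colnames(states) <- labels
  list(trajectory = traj,
       truth = list(states = states, pi = spec$pi, dwell = spec$dwell,
                    labels = labels, seed = spec$seed),
       spec = spec)
}

#' Write a trajectory truth record as tab-delimited text
#' @param truth The `truth` element of [gen_contact_trajectory()] output.
#' @param path Output path.
#' @export
write_truth_record <- function(truth, path) {
  df <- as.data.frame(truth$states * 1L)
  df <- cbind(frame = seq_len(nrow(df)), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Specification for a synthetic ITC experiment
#'
#' @param true_params A [one_site_params()].
#' @param schedule An [injection_schedule()].
#' @param noise_sd Gaussian heat noise, ucal (>= 0).
#' @param dilution_heat Constant dilution heat per injection, ucal.
#' @param seed Integer seed.
#' @return Object of class `itc_spec`.
#' @export
itc_spec <- function(true_params, schedule, noise_sd = 0,
                     dilution_heat = 0, seed = 1L) {
  stopifnot(inherits(true_params, "one_site_params"),
            inherits(schedule, "injection_schedule"), noise_sd >= 0)
  structure(list(true_params = true_params, schedule = schedule,
                 noise_sd = noise_sd, dilution_heat = dilution_heat,
                 seed = as.integer(seed)), class = "itc_spec")
}

#' Generate a synthetic ITC experiment with truth
#'
#' `heats = model_heats(truth) + dilution + noise`; the blank carries the
#' same dilution heat with independent noise.
#'
#' @param spec An [itc_spec()].
#' @return List with `isotherm` (an [itc_isotherm()] with blank attached)
#'   and `truth` (`params`, `clean_heats`, `dilution_heat`, `seed`).
#' @export
gen_itc_experiment <- function(spec) {
  stopifnot(inherits(spec, "itc_spec"))
  set.seed(spec$seed)
  clean <- model_heats(spec$true_params, spec$schedule)
  k <- length(clean)
  heats <- clean + spec$dilution_heat + stats::rnorm(k, 0, spec$noise_sd)
  blank <- spec$dilution_heat + stats::rnorm(k, 0, spec$noise_sd)
  list(isotherm = itc_isotherm(heats, spec$schedule, blank_heats = blank),
       truth = list(params = spec$true_params, clean_heats = clean,
                    dilution_heat = spec$dilution_heat, seed = spec$seed))
}

#' Fraction of macromolecule bound at a single titration point
#'
#' Exact single-site quadratic solution of the binding equilibrium.
#'
#' @param protein_conc,ligand_conc Total concentrations, M.
#' @param Kd Dissociation constant, M.
#' @return Fraction bound in `[0, 1]` (vectorized over `ligand_conc`).
#' @export
fraction_bound <- function(protein_conc, ligand_conc, Kd) {
  .bound_conc(protein_conc, ligand_conc, Kd) / protein_conc
}

#' Specification for a synthetic fast-exchange titration
#'
#' @param Kd Dissociation constant, M.
#' @param dd_max `data.frame` with columns `resi`, `ddH_max`, `ddN_max`
#'   (ppm): per-residue saturation shift changes.
#' @param protein_conc Protein concentration, M (study conditions: 100 uM).
#' @param ligand_concs Ligand concentrations, M (first point 0 = free).
#' @param noise_sd Shift noise, ppm.
#' @param free_shifts Optional `data.frame(resi, dH, dN)`; a deterministic
#'   synthetic baseline is derived from `resi` otherwise.
#' @param seed Integer seed.
#' @return Object of class `titration_spec`.
#' @export
titration_spec <- function(Kd, dd_max, protein_conc = 100e-6,
                           ligand_concs = c(0, 25e-6, 50e-6, 100e-6,
                                            200e-6, 400e-6),
                           noise_sd = 0, free_shifts = NULL, seed = 1L) {
  stopifnot(Kd > 0, protein_conc > 0, all(ligand_concs >= 0),
            noise_sd >= 0,
            all(c("resi", "ddH_max", "ddN_max") %in% names(dd_max)))
  if (is.null(free_shifts)) {
    free_shifts <- data.frame(resi = dd_max$resi,
                              dH = 8.0 + 0.5 * sin(dd_max$resi),
                              dN = 118 + 6 * cos(dd_max$resi))
  }
  structure(list(Kd = Kd, dd_max = dd_max, protein_conc = protein_conc,
                 ligand_concs = ligand_concs, noise_sd = noise_sd,
                 free_shifts = free_shifts, seed = as.integer(seed)),
            class = "titration_spec")
}

#' Generate fast-exchange titration peak lists with truth
#'
#' Observed shifts are population-weighted averages (fast exchange):
#' `free + fraction_bound * dd_max + noise`, with the fraction bound from
#' the exact single-site quadratic at each ligand concentration.
#'
#' @param spec A [titration_spec()].
#' @return List with `peak_lists` (one [peak_list()] per ligand
#'   concentration) and `truth` (`fraction_bound` per point, `dd_max`,
#'   `free_shifts`, `seed`).
#' @export
gen_titration_peaklists <- function(spec) {
  stopifnot(inherits(spec, "titration_spec"))
  set.seed(spec$seed)
  fb <- vapply(spec$ligand_concs, function(L) {
    if (L == 0) 0 else fraction_bound(spec$protein_conc, L, spec$Kd)
  }, 0)
  nres <- nrow(spec$dd_max)
  pls <- lapply(seq_along(spec$ligand_concs), function(i) {
    dH <- spec$free_shifts$dH + fb[i] * spec$dd_max$ddH_max +
      stats::rnorm(nres, 0, spec$noise_sd)
    dN <- spec$free_shifts$dN + fb[i] * spec$dd_max$ddN_max +
      stats::rnorm(nres, 0, spec$noise_sd)
    peak_list(spec$dd_max$resi, dH, dN,
              label = if (i == 1) "free" else
                sprintf("titration-%g", spec$ligand_concs[i]),
              ligand_conc = spec$ligand_concs[i])
  })
  list(peak_lists = pls,
       truth = list(fraction_bound = fb, dd_max = spec$dd_max,
                    free_shifts = spec$free_shifts, seed = spec$seed))
}

#' Build a minimal KKETAV hexapeptide structure
#'
#' Ligand chain "B", residues -5 (N-terminal Lys) to 0 (C-terminal Val),
#' backbone plus the side-chain atoms the charge scheme needs. Useful as
#' a parsing/round-trip fixture and for numbering checks.
#'
#' @return A `pdz_structure`.
#' @export
demo_kketav_structure <- function() {
  seqs <- list(
    `-5` = list("LYS", c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")),
    `-4` = list("LYS", c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ")),
    `-3` = list("GLU", c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2")),
    `-2` = list("THR", c("N", "CA", "C", "O", "CB", "OG1", "CG2")),
    `-1` = list("ALA", c("N", "CA", "C", "O", "CB")),
    `0`  = list("VAL", c("N", "CA", "C", "O", "CB", "CG1", "CG2", "OXT"))
  )
  rows <- list()
  for (i in seq_along(seqs)) {
    resi <- as.integer(names(seqs)[i])
    nm <- seqs[[i]][[2]]
    rows[[i]] <- data.frame(
      chain = "B", resi = resi, resn = seqs[[i]][[1]], atom = nm,
      element = .infer_element(nm),
      x = 3.8 * i + 0.4 * seq_along(nm), y = (seq_along(nm) %% 3) * 1.1,
      z = (seq_along(nm) %% 2) * 0.9, stringsAsFactors = FALSE)
  }
  structure_model(do.call(rbind, rows), title = "KKETAV hexapeptide")
}

#' Demo trajectory specification mirroring the wild-type complex
#'
#' Candidate bridges of the PDZ3/KKETAV system with stationary
#' occupancies set to the published wild-type 400-ns contact frequencies
#' (the Lys403-Glu334 row, 0.0% in the wild type, is omitted: it closes
#' the only cycle in the pair graph and tree geometry requires a forest).
#' The Glu334 competition - the helix bridge Glu334-Arg399 forming only
#' when Glu334 is not engaged by ligand Lys(-5) - is encoded as a
#' competition group over those two pairs.
#'
#' @param n_frames Number of frames.
#' @param seed Integer seed.
#' @param dwell Mean formed dwell, frames.
#' @return A [trajectory_spec()]. The paired aggregate definitions are
#'   attached as attribute `"aggregates"` (see [occupancy_table()]).
#' @export
demo_wt_trajectory_spec <- function(n_frames = 1000, seed = 1L,
                                    dwell = 50) {
  pairs <- list(
    pair_spec(c("B", -5), c("A", 331), "ligand-b2b3loop",
              "Lys(-5)-Glu331"),
    pair_spec(c("B", -5), c("A", 334), "ligand-b2b3loop",
              "Lys(-5)-Glu334"),
    pair_spec(c("B", -4), c("A", 331), "ligand-b2b3loop",
              "Lys(-4)-Glu331"),
    pair_spec(c("B", -5), c("A", 401), "ligand-a3helix",
              "Lys(-5)-Glu401"),
    pair_spec(c("B", -3), c("A", 403), "ligand-a3helix",
              "Glu(-3)-Lys403"),
    pair_spec(c("B", -4), c("A", 373), "ligand-other",
              "Lys(-4)-Glu373"),
    pair_spec(c("A", 403), c("A", 331), "a3helix-b2b3loop",
              "Lys403-Glu331"),
    pair_spec(c("A", 403), c("A", 332), "a3helix-b2b3loop",
              "Lys403-Asp332"),
    pair_spec(c("A", 334), c("A", 399), "a3helix-domain",
              "Glu334-Arg399"),
    pair_spec(c("A", 355), c("A", 401), "a3helix-domain",
              "Lys355-Glu401")
  )
  pi <- c(0.200, 0.362, 0.372, 0.019, 0.001, 0.198, 0.027, 0.007,
          0.397, 0.443)
  sp <- trajectory_spec(pairs, pi, dwell = dwell, n_frames = n_frames,
                        competition_groups = list(c(2L, 9L)),
                        seed = seed)
  attr(sp, "aggregates") <- list(
    "PDZ3-Lys(-4)(-5)" = c(1L, 2L, 3L, 4L, 6L),
    "non-formation:helix-bridges" = c(9L, 10L)
  )
  sp
}
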