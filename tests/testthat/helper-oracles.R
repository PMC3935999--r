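# Independent oracles, deliberately implemented by a different route than
# the package code they check.

# Binding equilibrium by bisection on the free-ligand concentration:
# f(Xf) = Xf + S Xf / (Kd + Xf) - X is monotone on [0, X].
bisect_bound <- function(S, X, Kd, tol = 1e-15) {
  if (X <= 0 || S <= 0) return(0)
  lo <- 0; hi <- X
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid + S * mid / (Kd + mid) - X > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * X) break
  }
  X - (lo + hi) / 2   # bound ligand
}

# Per-injection heats using the same perfusion bookkeeping written out
# longhand, but with the equilibrium solved by bisection instead of the
# closed-form quadratic.
oracle_heats <- function(n, Kd, dH, schedule) {
  V0 <- schedule$cell_volume
  m <- schedule$cell_conc_initial; x <- 0
  Qprev <- 0
  q <- numeric(length(schedule$injection_volumes))
  for (i in seq_along(q)) {
    dV <- schedule$injection_volumes[i]
    m <- m * (V0 - dV / 2) / (V0 + dV / 2)
    x <- (x * (V0 - dV / 2) + schedule$syringe_conc * dV) / (V0 + dV / 2)
    PL <- bisect_bound(n * m, x, Kd)
    Q <- PL * (V0 * 1e-6) * dH * 1000
    q[i] <- (Q - Qprev + (dV / V0) * (Q + Qprev) / 2) * 1e6
    Qprev <- Q
  }
  q
}

# Frame-by-frame brute-force contact states via single-frame calls.
brute_state_series <- function(traj, pair, criterion = contact_criterion(),
                               scheme = default_charge_scheme()) {
  vapply(seq_len(n_frames(traj)), function(i) {
    contact_state(frame_structure(traj, i), pair, criterion, scheme)
  }, logical(1))
}

# Tiny hand-built two-residue structure: a Lys and a Glu whose anchor
# carbons sit at controllable separation d along x (all four anchors and
# charged atoms near-collinear so the minimum cross distance is d).
two_residue_frame <- function(d, extra = 0) {
  at <- rbind(
    data.frame(chain = "A", resi = 355, resn = "LYS",
               atom = c("CD", "CE", "NZ"), element = c("C", "C", "N"),
               x = c(0, 0, 0), y = c(0, 0.9, 1.8), z = 0),
    data.frame(chain = "A", resi = 401, resn = "GLU",
               atom = c("CG", "CD", "OE1", "OE2"),
               element = c("C", "C", "O", "O"),
               x = d + c(0, 0, extra, extra), y = c(0, 0.9, 1.6, 2.0),
               z = 0)
  )
  structure_model(at)
}

lys_glu_pair <- function() {
  pair_spec(c("A", 355), c("A", 401), category = "a3helix-domain",
            label = "Lys355-Glu401")
}

# Stack single frames into a trajectory.
frames_to_traj <- function(frames, dt = 2) {
  topo <- frames[[1]]$atoms
  co <- array(0, dim = c(nrow(topo), 3, length(frames)))
  for (k in seq_along(frames)) {
    co[, , k] <- as.matrix(frames[[k]]$atoms[c("x", "y", "z")])
  }
  trajectory_model(topo, co, dt)
}
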