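test_that("contact_state applies a strict cutoff on the anchor minimum", {
  crit <- contact_criterion("anchor_carbon", 5.0)
  pair <- lys_glu_pair()
  expect_true(contact_state(two_residue_frame(4.0), pair, crit))
  expect_false(contact_state(two_residue_frame(6.0), pair, crit))
  expect_false(contact_state(two_residue_frame(5.0), pair, crit))  # strict
  # missing required atom is identified
  f <- two_residue_frame(4.0)
  f$atoms <- f$atoms[f$atoms$atom != "CG", ]
  expect_error(contact_state(f, pair, crit), "A:401.*CG")
})

test_that("state_series matches the per-frame brute-force oracle", {
  # alternating 4/6 A -> T,F,T,F,T
  tr <- frames_to_traj(lapply(c(4, 6, 4, 6, 4), two_residue_frame))
  ss <- state_series(tr, lys_glu_pair())
  expect_equal(ss$states, c(TRUE, FALSE, TRUE, FALSE, TRUE))
  # constant geometry -> constant series
  trc <- frames_to_traj(lapply(rep(4.2, 4), two_residue_frame))
  expect_equal(state_series(trc, lys_glu_pair())$states, rep(TRUE, 4))

  # synthetic 1000-frame trajectory equals frame-by-frame recomputation
  sp <- demo_wt_trajectory_spec(n_frames = 1000, seed = 21)
  g <- gen_contact_trajectory(sp)
  for (j in c(1, 3, 9)) {
    fast <- state_series(g$trajectory, sp$pairs[[j]])$states
    expect_equal(fast, brute_state_series(g$trajectory, sp$pairs[[j]]))
  }
})

test_that("occupancy and any_of match direct frame counts", {
  expect_equal(occupancy(rep(TRUE, 100)), 1.0)
  expect_equal(occupancy(c(rep(TRUE, 37), rep(FALSE, 63))), 0.37)
  expect_error(occupancy(logical(0)), "empty")

  # disjoint formed sets add
  a <- c(rep(TRUE, 20), rep(FALSE, 80))
  b <- c(rep(FALSE, 50), rep(TRUE, 30), rep(FALSE, 20))
  expect_equal(any_of_occupancy(list(a, b)), 0.5)
  expect_equal(any_of_occupancy(list(a)), occupancy(a))
  expect_error(any_of_occupancy(list(a, b[1:10])), "length mismatch")

  # random series vs frame-wise OR count
  set.seed(4)
  ss <- replicate(3, runif(500) < runif(1), simplify = FALSE)
  expect_equal(any_of_occupancy(ss),
               sum(ss[[1]] | ss[[2]] | ss[[3]]) / 500)
})

test_that("occupancy bounds and reordering invariance hold", {
  set.seed(9)
  for (rep in 1:20) {
    ss <- replicate(sample(2:4, 1), runif(200) < runif(1),
                    simplify = FALSE)
    any_of <- any_of_occupancy(ss)
    occs <- vapply(ss, occupancy, 0)
    expect_gte(any_of, max(occs))
    expect_lte(any_of, min(1, sum(occs)) + 1e-12)
    perm <- sample(length(ss))
    expect_equal(any_of_occupancy(ss[perm]), any_of)
    shuf <- sample(200)
    expect_equal(occupancy(ss[[1]][shuf]), occs[1])
  }
})

test_that("helix undocked fraction complements the bridge union exactly", {
  sp <- demo_wt_trajectory_spec(n_frames = 800, seed = 31)
  g <- gen_contact_trajectory(sp)
  und <- helix_undocked_fraction(g$trajectory)
  bridges <- lapply(helix_bridge_pairs(), function(p)
    state_series(g$trajectory, p))
  expect_equal(und + any_of_occupancy(bridges), 1.0)
  # generator truth for the same two pairs (exact frame-wise OR oracle)
  expect_equal(und,
               mean(!(g$truth$states[, "Glu334-Arg399"] |
                        g$truth$states[, "Lys355-Glu401"])))

  # degenerate cases
  both <- frames_to_traj(lapply(rep(4, 3), two_residue_frame))
  # only one bridge's residues present -> error
  expect_error(helix_undocked_fraction(both), "A:334|334")
})

test_that("the two criteria agree away from their cutoffs", {
  # constant geometry -> agreement in {0, 1}
  tr <- frames_to_traj(lapply(rep(3.5, 5), two_residue_frame))
  ca <- criterion_agreement(tr, lys_glu_pair())
  expect_true(ca$agreement %in% c(0, 1))
  # 3.5 A centers: formed under both criteria
  expect_equal(ca$occupancy_anchor, 1)
  expect_equal(ca$occupancy_center, 1)
  tr2 <- frames_to_traj(lapply(rep(6.5, 5), two_residue_frame))
  ca2 <- criterion_agreement(tr2, lys_glu_pair())
  expect_equal(ca2$agreement, 1)
  expect_equal(ca2$occupancy_anchor, 0)
})

test_that("distance_series is consistent with contact_state", {
  sp <- demo_wt_trajectory_spec(n_frames = 400, seed = 13)
  g <- gen_contact_trajectory(sp)
  p <- sp$pairs[[9]]
  ds <- distance_series(g$trajectory, c("A", 334), c("A", 399))
  ss <- state_series(g$trajectory, p)
  expect_equal(ds$distance < 5.0, ss$states)
  expect_equal(ds$time_ps, (0:399) * 2)
  # constant geometry -> constant series
  trc <- frames_to_traj(lapply(rep(4.4, 3), two_residue_frame))
  dc <- distance_series(trc, c("A", 355), c("A", 401))
  expect_equal(diff(range(dc$distance)), 0)
})

test_that("competition partners of Glu334 are anti-correlated", {
  sp <- demo_wt_trajectory_spec(n_frames = 3000, seed = 17)
  g <- gen_contact_trajectory(sp)
  d_lig <- distance_series(g$trajectory, c("A", 334), c("B", -5))$distance
  d_hel <- distance_series(g$trajectory, c("A", 334), c("A", 399))$distance
  expect_lt(stats::cor(d_lig, d_hel), 0)
  # competition is exclusive frame-wise
  expect_equal(sum(g$truth$states[, "Lys(-5)-Glu334"] &
                     g$truth$states[, "Glu334-Arg399"]), 0)
})

test_that("occupancy_table reports rows, aggregates and percents", {
  sp <- demo_wt_trajectory_spec(n_frames = 600, seed = 23)
  g <- gen_contact_trajectory(sp)
  tab <- occupancy_table(g$trajectory, sp$pairs,
                         aggregates = attr(sp, "aggregates"))
  expect_equal(nrow(tab), 12)
  expect_equal(attr(tab, "n_frames"), 600)
  expect_true(all(tab$frequency >= 0 & tab$frequency <= 1))
  expect_equal(tab$percent, round(100 * tab$frequency, 1))
  # every per-pair value matches the truth record (brute-force)
  expect_equal(tab$frequency[1:10], unname(colMeans(g$truth$states)))
  # aggregate = frame-wise OR over ligand Lys(-4)/(-5) pairs
  lig <- attr(sp, "aggregates")[["PDZ3-Lys(-4)(-5)"]]
  expect_equal(tab$frequency[tab$label == "PDZ3-Lys(-4)(-5)"],
               mean(rowSums(g$truth$states[, lig]) > 0))
  # empty pair list -> metadata only
  tab0 <- occupancy_table(g$trajectory, list())
  expect_equal(nrow(tab0), 0)
  expect_equal(attr(tab0, "n_frames"), 600)
  # serialization round trip of the percent column
  p <- tempfile(fileext = ".tsv")
  write_occupancy_table(tab, p)
  back <- utils::read.delim(p, comment.char = "#")
  expect_equal(as.numeric(sub("%", "", back$percent)), tab$percent)
})

test_that("same-sign pairs are rejected", {
  s <- demo_kketav_structure()
  p <- pair_spec(c("B", -5), c("B", -4))
  expect_error(pdz3kit:::.check_pair_signs(s, p), "same charge sign")
})
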