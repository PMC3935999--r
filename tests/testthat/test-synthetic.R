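simple_pairs <- function() {
  list(pair_spec(c("B", -4), c("A", 331), "ligand-b2b3loop",
                 "Lys(-4)-Glu331"),
       pair_spec(c("B", -5), c("A", 334), "ligand-b2b3loop",
                 "Lys(-5)-Glu334"),
       pair_spec(c("A", 355), c("A", 401), "a3helix-domain",
                 "Lys355-Glu401"))
}

test_that("degenerate occupancies generate constant state series", {
  sp <- trajectory_spec(simple_pairs(), pi = c(1, 0, 0.5),
                        n_frames = 200, seed = 5)
  g <- gen_contact_trajectory(sp)
  expect_true(all(g$truth$states[, 1]))
  expect_false(any(g$truth$states[, 2]))
  expect_equal(state_series(g$trajectory, sp$pairs[[1]])$states,
               rep(TRUE, 200))
  expect_equal(state_series(g$trajectory, sp$pairs[[2]])$states,
               rep(FALSE, 200))
})

test_that("spec validation rejects impossible worlds", {
  prs <- simple_pairs()
  expect_error(trajectory_spec(prs, pi = c(0.5, 0.2)), "one entry per pair")
  expect_error(trajectory_spec(prs, pi = c(1.2, 0, 0)), "\\[0, 1\\]")
  expect_error(trajectory_spec(prs, pi = c(0.6, 0.6, 0),
                               competition_groups = list(1:2)),
               "sum to > 1")
  expect_error(trajectory_spec(prs, pi = rep(0.2, 3), jitter_sd = 0.2),
               "cutoff")
  expect_error(trajectory_spec(prs, pi = rep(0.2, 3),
                               formed_distance = 4.9), "cutoff")
  # cycle in the pair graph
  cyc <- c(prs, list(pair_spec(c("B", -4), c("A", 334)),
                     pair_spec(c("B", -5), c("A", 331))))
  expect_error(gen_contact_trajectory(
    trajectory_spec(cyc, pi = rep(0.1, 5), seed = 1)), "cycle")
})

test_that("generated occupancies recover pi within 3 dwell-corrected sigma", {
  n <- 20000
  sp <- trajectory_spec(simple_pairs(), pi = c(0.372, 0.362, 0.200),
                        dwell = 50, n_frames = n, seed = 6)
  g <- gen_contact_trajectory(sp)
  for (j in 1:3) {
    se <- occupancy_se(sp$pi[j], sp$dwell[j], n)
    expect_lt(abs(mean(g$truth$states[, j]) - sp$pi[j]), 3 * se)
  }
  # detector sees exactly the truth states
  for (j in 1:3) {
    expect_equal(state_series(g$trajectory, sp$pairs[[j]])$states,
                 unname(g$truth$states[, j]))
  }
})

test_that("dwell times average to the configured mean", {
  n <- 50000
  sp <- trajectory_spec(simple_pairs()[1], pi = 0.4, dwell = 25,
                        n_frames = n, seed = 7)
  g <- gen_contact_trajectory(sp)
  s <- g$truth$states[, 1]
  r <- rle(s)
  dwells <- r$lengths[r$values]
  # drop censored first/last runs
  if (s[1]) dwells <- dwells[-1]
  if (s[n]) dwells <- dwells[-length(dwells)]
  expect_equal(mean(dwells), 25, tolerance = 0.15)
})

test_that("competition groups never co-form and keep marginals", {
  sp <- demo_wt_trajectory_spec(n_frames = 20000, seed = 8)
  g <- gen_contact_trajectory(sp)
  grp <- sp$competition_groups[[1]]
  expect_equal(sum(rowSums(g$truth$states[, grp]) > 1), 0)
  for (j in grp) {
    se <- sqrt(sp$pi[j] * (1 - sp$pi[j]) / 20000)  # iid draw per frame
    expect_lt(abs(mean(g$truth$states[, j]) - sp$pi[j]), 3 * se)
  }
})

test_that("generators are byte-deterministic under a fixed seed", {
  sp <- trajectory_spec(simple_pairs(), pi = c(0.3, 0.2, 0.5),
                        n_frames = 50, seed = 9)
  g1 <- gen_contact_trajectory(sp)
  g2 <- gen_contact_trajectory(sp)
  expect_identical(g1$truth$states, g2$truth$states)
  expect_identical(g1$trajectory$coords, g2$trajectory$coords)

  isp <- itc_spec(one_site_params(0.99, 1.5e-6, -9.8),
                  injection_schedule(rep(2, 19), 900e-6, 70e-6),
                  noise_sd = 0.5, dilution_heat = -1, seed = 4)
  expect_identical(gen_itc_experiment(isp)$isotherm$heats,
                   gen_itc_experiment(isp)$isotherm$heats)
  # different seeds differ
  isp2 <- isp; isp2$seed <- 5L
  expect_false(identical(gen_itc_experiment(isp)$isotherm$heats,
                         gen_itc_experiment(isp2)$isotherm$heats))
})

test_that("noise-free ITC generation equals the forward model", {
  sched <- injection_schedule(rep(2, 19), 900e-6, 70e-6)
  pr <- one_site_params(0.99, 1.5e-6, -9.8)
  g <- gen_itc_experiment(itc_spec(pr, sched, noise_sd = 0,
                                   dilution_heat = 0, seed = 1))
  expect_equal(g$isotherm$heats, model_heats(pr, sched))
  expect_equal(g$isotherm$blank_heats, rep(0, 19))
})

test_that("truth records serialize to plain tables", {
  sp <- trajectory_spec(simple_pairs(), pi = c(0.3, 0.2, 0.5),
                        n_frames = 40, seed = 10)
  g <- gen_contact_trajectory(sp)
  p <- tempfile(fileext = ".tsv")
  write_truth_record(g$truth, p)
  back <- utils::read.delim(p, check.names = FALSE)
  expect_equal(nrow(back), 40)
  expect_equal(as.matrix(back[, -1]) == 1, unname(g$truth$states),
               ignore_attr = TRUE)
})
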