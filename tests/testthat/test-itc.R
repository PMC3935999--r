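# Study conditions: 70 uM protein in the cell, 900 uM peptide in the
# syringe, 2-uL injections at 25 C.
wt_schedule <- function(n_inj = 19) {
  injection_schedule(rep(2, n_inj), syringe_conc = 900e-6,
                     cell_conc_initial = 70e-6)
}
wt_params <- function() one_site_params(n = 0.99, Kd = 1.5e-6, dH = -9.8)

test_that("model_heats obeys its limits", {
  sched <- wt_schedule()
  # dH = 0 -> all heats 0
  expect_equal(model_heats(one_site_params(1, 1e-6, 0), sched),
               rep(0, 19))
  # stoichiometric limit: Kd -> 0, first injection far below saturation:
  # heat = dH x moles injected (1.8 nmol) within 1%
  h <- model_heats(one_site_params(1, 1e-12, -9.8), sched)
  expect_equal(h[1], -9.8 * 1000 * 900e-6 * 2e-6 * 1e6, tolerance = 0.01)
  # saturation conservation: cumulative heat approaches n [cell]0 V0 dH
  # saturation conservation: in the tight-binding limit every site binds
  # before any complex is displaced, and the displaced-complex credit
  # makes the cumulative heat approach n [cell]0 V0 dH; at finite Kd a
  # small deficit remains (protein displaced before saturating), so the
  # limit is probed at Kd = 1 nM
  big <- injection_schedule(rep(2, 100), syringe_conc = 10e-3,
                            cell_conc_initial = 70e-6)
  htot <- sum(model_heats(one_site_params(0.99, 1e-9, -9.8), big))
  expect_equal(htot, 0.99 * 70e-6 * 200e-6 * -9.8 * 1000 * 1e6,
               tolerance = 0.01)
})

test_that("model_heats matches the bisection equilibrium oracle", {
  sched <- wt_schedule()
  for (par in list(c(0.99, 1.5e-6, -9.8), c(1.05, 16e-6, -7.9),
                   c(0.9, 3.6e-6, -8.8))) {
    h <- model_heats(one_site_params(par[1], par[2], par[3]), sched)
    ho <- oracle_heats(par[1], par[2], par[3], sched)
    expect_equal(h, ho, tolerance = 1e-6)
  }
})

test_that("dilution correction subtracts blanks or offsets", {
  sched <- wt_schedule(8)
  h <- model_heats(wt_params(), sched)
  iso0 <- itc_isotherm(h, sched, blank_heats = rep(0, 8))
  expect_equal(dilution_correct(iso0), h)
  isoc <- itc_isotherm(h + 1.3, sched, blank_heats = rep(1.3, 8))
  expect_equal(dilution_correct(isoc), h)
  expect_equal(dilution_correct(itc_isotherm(h, sched), offset = 0.5),
               h - 0.5)
  expect_error(dilution_correct(itc_isotherm(h, sched)), "no blank")
  # generator-known dilution recovers clean heats exactly
  g <- gen_itc_experiment(itc_spec(wt_params(), wt_schedule(),
                                   noise_sd = 0, dilution_heat = -2.5,
                                   seed = 3))
  expect_equal(dilution_correct(g$isotherm), g$truth$clean_heats)
})

test_that("fit_one_site recovers truth on noise-free data", {
  sched <- wt_schedule()
  h <- model_heats(wt_params(), sched)
  fit <- fit_one_site(itc_isotherm(h, sched))
  expect_true(fit$converged)
  expect_equal(fit$params$n, 0.99, tolerance = 1e-3)
  expect_equal(fit$params$Kd, 1.5e-6, tolerance = 1e-3)
  expect_equal(fit$params$dH, -9.8, tolerance = 1e-3)
  expect_lt(fit$ssr, 1e-8 * sum(h^2))
  # fixed point: refitting model output of arbitrary params returns them
  p2 <- one_site_params(1.1, 8e-6, -5.5)
  f2 <- fit_one_site(itc_isotherm(model_heats(p2, sched), sched))
  expect_equal(f2$params$Kd, 8e-6, tolerance = 1e-3)
  expect_equal(f2$params$n, 1.1, tolerance = 1e-3)
})

test_that("fit_one_site tolerates 1% noise (median Kd error < 10%)", {
  sched <- wt_schedule()
  clean <- model_heats(wt_params(), sched)
  noise_sd <- 0.01 * max(abs(clean))
  errs <- vapply(1:20, function(r) {
    g <- gen_itc_experiment(itc_spec(wt_params(), sched,
                                     noise_sd = noise_sd, seed = 100 + r))
    f <- fit_one_site(g$isotherm)
    abs(f$params$Kd - 1.5e-6) / 1.5e-6
  }, 0)
  expect_lt(stats::median(errs), 0.10)
})

test_that("free energy and entropy decomposition reproduce printed rows", {
  expect_equal(free_energy(1), 0)
  expect_equal(free_energy(1.5e-6), -8.0, tolerance = 0.1 / 8)
  expect_equal(free_energy(16.0e-6), -6.5, tolerance = 0.1 / 6.5)
  expect_equal(entropy_term(-8.0, -9.8), 1.8)
  expect_equal(entropy_term(-6.5, -7.9), 1.4)
  expect_equal(entropy_term(-5, -5), 0)
  # monotone in Kd
  kds <- 10^seq(-9, -3, length.out = 20)
  expect_true(all(diff(free_energy(kds)) > 0))
  # thermo_table identity dG = dH + (-TdS) is exact
  tt <- thermo_table(2.7e-6, -7.4)
  expect_equal(tt$dG, tt$dH + tt$minus_TdS)
  expect_equal(tt$dG, free_energy(2.7e-6), tolerance = 1e-12)
})

test_that("condition comparisons reproduce printed arithmetic", {
  ref <- reference_thermo_table()
  row <- function(l) {
    r <- ref[ref$label == l, ]
    thermo_table_printed(r$Kd_uM, r$dH, r$minus_TdS, r$T, l)
  }
  wt <- row("PDZ3/KKETAV_pH7.5")
  # identical tables -> (0, 0, 1)
  same <- compare_conditions(wt, wt)
  expect_equal(unlist(same), c(ddH = 0, minus_TddS = 0, Kd_fold = 1))
  # pH 6.0 vs 7.5: enthalpy 4.5 kcal/mol less favourable at pH 6.0, and
  # the entropy term 5.2 kcal/mol less favourable at pH 7.5
  expect_equal(compare_conditions(wt, row("PDZ3/KKETAV_pH6.0"))$ddH, 4.5)
  expect_equal(compare_conditions(row("PDZ3/KKETAV_pH6.0"),
                                  wt)$minus_TddS, 5.2)
  # Y397E enthalpic penalty 2.4 kcal/mol
  expect_equal(compare_conditions(wt, row("Y397E-PDZ3/KKETAV"))$ddH, 2.4)
  # fold-change strictly decreasing in Kd_b
  folds <- vapply(c(0.5, 1.5, 5, 20), function(k)
    compare_conditions(wt, thermo_table(k * 1e-6, -9))$Kd_fold, 0)
  expect_true(all(diff(folds) < 0))
  # temperature mismatch
  expect_error(compare_conditions(wt, thermo_table(1e-6, -9, T = 310)),
               "temperature")
})

test_that("isotherm I/O round-trips", {
  g <- gen_itc_experiment(itc_spec(wt_params(), wt_schedule(),
                                   noise_sd = 0.3, dilution_heat = -1,
                                   seed = 8))
  p <- tempfile(fileext = ".tsv")
  write_isotherm(g$isotherm, p)
  back <- read_isotherm(p, wt_schedule())
  expect_equal(back$heats, g$isotherm$heats, tolerance = 1e-12)
  expect_equal(back$blank_heats, g$isotherm$blank_heats,
               tolerance = 1e-12)
})
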