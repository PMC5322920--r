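test_that("infection probability follows the challenge-suppression model", {
  cfg <- tiny_preset("followup")
  expect_equal(infection_probability(cfg, "12", 0, 0), 0)
  expect_equal(infection_probability(cfg, "12", 0, 1), 0.90)  # s(0) = 1
  expect_equal(infection_probability(cfg, "47", 0, 1), 0.58)
  p1 <- infection_probability(cfg, "12", 0, 1)
  p2 <- infection_probability(cfg, "12", 0, 2)
  expect_equal(p2, 1 - (1 - p1)^2)
  expect_gt(p2, p1)
  # non-increasing in concentration, non-decreasing in challenge number
  grid <- c(0, 6.25, 12.5, 25, 50, 100)
  ps <- vapply(grid, function(c) infection_probability(cfg, "12", c, 1),
               numeric(1))
  expect_true(all(diff(ps) <= 0))
  expect_true(all(vapply(grid, function(c)
    infection_probability(cfg, "12", c, 2) >=
      infection_probability(cfg, "12", c, 1), logical(1))))
})

test_that("presets encode the three study designs", {
  expect_equal(nrow(expand_design(sim_preset("copper")$design)), 320L)
  expect_equal(nrow(expand_design(sim_preset("tebuconazole")$design)), 320L)
  fu <- sim_preset("followup")
  expect_equal(nrow(expand_design(fu$design)), 480L)
  expect_equal(fu$design$concentrations, c(0, 6.25, 12.5, 25.0, 50.0, 100.0))
  expect_equal(sim_preset("copper")$design$concentrations,
               c(0, 25.0, 28.8, 33.1))
  # fungicide suppression is essentially complete at the main-test doses
  teb <- sim_preset("tebuconazole")
  expect_lt(infection_probability(teb, "12", 154, 1) /
              infection_probability(teb, "12", 0, 1), 0.01)
  # copper does not suppress infection
  cu <- sim_preset("copper")
  expect_equal(infection_probability(cu, "12", 33.1, 1),
               infection_probability(cu, "12", 0, 1))
  expect_error(sim_preset("arsenic"))
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- tiny_preset(seed = 42L)
  t1 <- simulate_experiment(cfg)
  t2 <- simulate_experiment(cfg)
  expect_identical(t1$records, t2$records)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_records(t1, p1); write_records(t2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # a different seed changes the data
  cfg2 <- tiny_preset(seed = 43L)
  expect_false(identical(simulate_experiment(cfg2)$records, t1$records))
})

test_that("adding replicates does not perturb existing units", {
  small <- sim_preset("tebuconazole", seed = 9L, replicates = 2L)
  big <- sim_preset("tebuconazole", seed = 9L, replicates = 3L)
  ts <- simulate_experiment(small)
  tb <- simulate_experiment(big)
  keyed <- function(t) {
    k <- vapply(t$records, function(r)
      paste(r$clone, r$concentration, r$parasite_level, r$replicate, sep = "|"),
      character(1))
    stats::setNames(t$records, k)
  }
  ks <- keyed(ts); kb <- keyed(tb)
  expect_identical(kb[names(ks)], ks)
})

test_that("a hazard-free unchallenged individual is a deterministic skeleton", {
  d <- design_spec("12", c(0, 10), c("no-parasite", "parasite"), 2)
  cfg <- sim_config(d, seed = 1L, baseline_daily_death = 0,
                    early_death_prob = 0,
                    reproduction = list(AFR_mean = 8, AFR_sd = 0,
                                        AFR_delay = list(max_delay = 0, K = Inf,
                                                         hill = 2),
                                        interbrood = 3L, brood_mean = 10,
                                        fecundity_decline = list(EC50 = Inf,
                                                                 hill = 2),
                                        hormesis_bump = NULL,
                                        challenge_penalty = 1,
                                        infected_penalty = 1))
  r <- simulate_individual(cfg, "12", 0, "no-parasite", 1)
  expect_true(is_censored(r))
  expect_equal(which(r$offspring > 0), c(8, 11, 14, 17, 20))
  expect_true(is.na(r$infected))
})

test_that("infected hosts die within the parasite-kill window", {
  d <- design_spec("12", 0, c("no-parasite", "parasite"), 50)
  cfg <- sim_config(d, seed = 3L, baseline_daily_death = 0,
                    early_death_prob = 0,
                    infection = list(p_control = 1, suppression_EC50 = Inf,
                                     suppression_hill = 1))
  deaths <- vapply(1:50, function(i) {
    r <- simulate_individual(cfg, "12", 0, "parasite", i)
    expect_true(isTRUE(r$infected))
    r$death_day
  }, integer(1))
  expect_true(all(deaths %in% 14:17))
  expect_true(length(unique(deaths)) > 1)  # uniform draw, not a constant
})

test_that("brood sizes decline with dose and infection is monotone", {
  cfg <- sim_preset("tebuconazole", seed = 8L)
  mean_brood <- function(conc, n = 300) {
    mean(vapply(seq_len(n), function(i)
      sum(simulate_individual(cfg, "12", conc, "no-parasite", i)$offspring),
      numeric(1)))
  }
  m0 <- mean_brood(0); m240 <- mean_brood(240)
  expect_lt(m240, m0)

  # realised infection proportions non-increasing in dose (many individuals)
  inf_prop <- function(conc, n = 300) {
    mean(vapply(seq_len(n), function(i)
      isTRUE(simulate_individual(cfg, "12", conc, "parasite", i)$infected),
      logical(1)))
  }
  props <- vapply(c(0, 154, 240), inf_prop, numeric(1))
  expect_true(all(diff(props) <= 0))
  expect_gt(props[1], 0.85)
  expect_equal(props[2], 0)
})

test_that("unchallenged treatments never carry infections", {
  tab <- simulate_experiment(tiny_preset("copper", seed = 6L))
  lv <- vapply(tab$records, function(r) r$parasite_level, character(1))
  inf <- vapply(tab$records, function(r) r$infected, logical(1))
  expect_true(all(is.na(inf[lv == "no-parasite"])))
  expect_false(any(vapply(tab$records[lv == "no-parasite"],
                          function(r) isTRUE(r$infected), logical(1))))
})

test_that("the simulate method yields independent seeded experiments", {
  cfg <- tiny_preset(seed = 5L, replicates = 2L)
  sims <- simulate(cfg, nsim = 2, seed = 20L)
  expect_length(sims, 2)
  expect_false(identical(sims[[1]]$records, sims[[2]]$records))
  again <- simulate(cfg, nsim = 1, seed = 20L)
  expect_identical(again[[1]]$records, sims[[1]]$records)
})
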