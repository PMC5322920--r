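test_that("cohort schedules count survivors and mean broods", {
  r1 <- make_record(death_day = 10L, replicate = 1L)
  r2 <- make_record(death_day = 22L, replicate = 2L)
  s <- cohort_schedule(list(r1, r2))
  expect_equal(s$lx[s$x == 0], 1)
  expect_equal(s$lx[s$x == 5], 1)
  # death on day 10 means not surviving to age 10 or beyond
  expect_equal(s$lx[s$x == 10], 0.5)
  expect_equal(s$lx[s$x == 21], 0.5)
  expect_true(all(diff(s$lx) <= 0))

  cohort <- lapply(1:3, function(i)
    make_record(replicate = i, broods = list(`9` = 6)))
  s2 <- cohort_schedule(cohort)
  expect_equal(s2$mx[s2$x == 9], 6)
  expect_equal(sum(s2$mx), 6)

  # mean per survivor: one of two dies before the brood day
  s3 <- cohort_schedule(list(make_record(death_day = 5L, replicate = 1L),
                             make_record(replicate = 2L,
                                         broods = list(`9` = 6))))
  expect_equal(s3$mx[s3$x == 9], 6)  # 6 offspring / 1 survivor
  expect_equal(s3$lx[s3$x == 9], 0.5)

  s4 <- cohort_schedule(list(make_record()))
  expect_true(all(s4$mx == 0))
  expect_error(cohort_schedule(list()), "empty cohort")
})

test_that("Euler-Lotka solver matches closed forms on single-term schedules", {
  single <- function(x0, k, dur = 21) {
    s <- data.frame(x = 0:dur, lx = 1, mx = 0)
    s$mx[s$x == x0] <- k
    s
  }
  expect_equal(solve_euler_lotka(single(1, 1)), 0, tolerance = 1e-10)
  expect_equal(solve_euler_lotka(single(10, exp(2))), 0.2, tolerance = 1e-8)
  for (x0 in c(3, 8, 15)) {
    for (k in c(0.25, 1.5, 40)) {
      expect_equal(solve_euler_lotka(single(x0, k)), log(k) / x0,
                   tolerance = 1e-8)
    }
  }
})

test_that("solver agrees with the independent bisection oracle", {
  s <- data.frame(x = 0:21, lx = 1, mx = 0)
  s$mx[s$x %in% c(8, 11, 14)] <- 4
  r_oracle <- oracle_bisection_r(c(8, 11, 14), c(4, 4, 4))
  expect_equal(solve_euler_lotka(s), r_oracle, tolerance = 1e-8)

  set.seed(101)
  for (i in 1:200) {
    sch <- random_schedule()
    r <- solve_euler_lotka(sch)
    keep <- sch$lx * sch$mx > 0
    expect_lt(abs(sum(exp(-r * sch$x[keep]) * (sch$lx * sch$mx)[keep]) - 1),
              1e-10)
    expect_equal(r, oracle_bisection_r(sch$x[keep], (sch$lx * sch$mx)[keep]),
                 tolerance = 1e-8)
  }
})

test_that("rate of increase responds correctly to the schedule", {
  set.seed(7)
  for (i in 1:20) {
    sch <- random_schedule()
    r <- solve_euler_lotka(sch)
    up <- sch; up$mx <- up$mx * 1.5
    expect_gt(solve_euler_lotka(up), r)  # scaling fecundity up raises r
  }
  # lifetime reproduction below one gives a negative, unclipped rate
  low <- data.frame(x = 0:21, lx = 1, mx = 0)
  low$mx[10] <- 0.5  # sum lx mx = 0.5 < 1
  expect_lt(solve_euler_lotka(low), 0)
  # no reproduction at all: undefined
  none <- data.frame(x = 0:21, lx = 1, mx = 0)
  expect_true(is.na(solve_euler_lotka(none)))
})

test_that("jackknife pseudo-values collapse to r on identical cohorts", {
  cohort <- lapply(1:6, function(i)
    make_record(replicate = i, broods = list(`8` = 5, `11` = 5)))
  est <- jackknife_pseudovalues(cohort)
  expect_equal(est$n, 6L)
  expect_equal(est$pseudo_values, rep(est$r_full, 6))
  expect_equal(mean(est$pseudo_values), est$r_full)
})

test_that("jackknife matches an independently coded leave-one-out loop", {
  cohort <- list(
    make_record(replicate = 1L, broods = list(`7` = 3, `10` = 8)),
    make_record(replicate = 2L, death_day = 12L, broods = list(`8` = 6)),
    make_record(replicate = 3L, broods = list(`9` = 2, `12` = 2, `15` = 9)))
  est <- jackknife_pseudovalues(cohort)
  n <- 3
  full_s <- cohort_schedule(cohort)
  r_full <- oracle_bisection_r(full_s$x[full_s$lx * full_s$mx > 0],
                               (full_s$lx * full_s$mx)[full_s$lx * full_s$mx > 0])
  for (i in 1:3) {
    s <- cohort_schedule(cohort[-i])
    keep <- s$lx * s$mx > 0
    r_i <- oracle_bisection_r(s$x[keep], (s$lx * s$mx)[keep])
    expect_equal(est$pseudo_values[i], n * r_full - (n - 1) * r_i,
                 tolerance = 1e-8)
  }
})

test_that("jackknife handles undefined leave-one-out estimates", {
  cohort <- list(make_record(replicate = 1L, broods = list(`9` = 8)),
                 make_record(replicate = 2L),
                 make_record(replicate = 3L))
  est <- jackknife_pseudovalues(cohort)
  expect_true(is.na(est$pseudo_values[1]))  # sole reproducer removed
  expect_false(anyNA(est$pseudo_values[2:3]))
  expect_error(jackknife_pseudovalues(cohort[1]), "at least 2")

  barren <- lapply(1:3, function(i) make_record(replicate = i))
  est2 <- jackknife_pseudovalues(barren)
  expect_true(is.na(est2$r_full))
  expect_true(all(is.na(est2$pseudo_values)))
})

test_that("pseudovalue_table keys every cohort member by its factors", {
  cfg <- tiny_preset(seed = 2L, replicates = 3L)
  tab <- simulate_experiment(cfg)
  pv <- pseudovalue_table(tab)
  expect_equal(nrow(pv), 2 * 4 * 2 * 3)
  expect_equal(names(pv), c("clone", "concentration", "parasite_level",
                            "replicate", "pseudo_value", "r_full"))
  one <- pv[pv$clone == "12" & pv$concentration == 0 &
              pv$parasite_level == "no-parasite", ]
  est <- jackknife_pseudovalues(cell_records(tab, "12", 0, "no-parasite"))
  expect_equal(one$pseudo_value, est$pseudo_values)
})
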