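# Independent oracles and small fixture builders used across the suite.

# Pure-bisection root of sum(exp(-r x) terms) = 1, coded independently of
# solve_euler_lotka (no shared helpers).
oracle_bisection_r <- function(x, terms, lo = -10, hi = 10, tol = 1e-12) {
  f <- function(r) sum(exp(-r * x) * terms) - 1
  while (f(lo) < 0) lo <- lo * 2
  while (f(hi) > 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Definitional cell-means ANOVA decomposition for a balanced two-way layout:
# sums of squares from grand mean, marginal means and interaction deviations.
oracle_balanced_anova <- function(y, A, B) {
  A <- as.character(A); B <- as.character(B)
  grand <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, paste(A, B), mean)
  ss_A <- sum((mA[A] - grand)^2)
  ss_B <- sum((mB[B] - grand)^2)
  ss_AB <- sum((mAB[paste(A, B)] - mA[A] - mB[B] + grand)^2)
  ss_res <- sum((y - mAB[paste(A, B)])^2)
  a <- length(unique(A)); b <- length(unique(B)); n <- length(y)
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), n - a * b)
  ms_res <- ss_res / df[4]
  list(ss = unname(c(ss_A, ss_B, ss_AB, ss_res)), df = df,
       F = unname(c(ss_A, ss_B, ss_AB) / df[1:3] / ms_res))
}

# Random survivorship/fecundity schedule with guaranteed reproduction.
random_schedule <- function(duration = 21) {
  x <- 0:duration
  lx <- c(1, cumprod(stats::runif(duration, 0.7, 1)))
  mx <- c(0, round(stats::runif(duration, 0, 6) *
                     stats::rbinom(duration, 1, 0.4), 2))
  if (sum(lx * mx) == 0) mx[stats::sample(2:(duration + 1), 1)] <- 3
  data.frame(x = x, lx = lx, mx = mx)
}

# Individual record from a compact brood map, defaulting to a 21-day assay.
make_record <- function(death_day = 22L, broods = list(), infected = NA,
                        challenge_days = integer(0), clone = "12",
                        concentration = 0, parasite_level = "no-parasite",
                        replicate = 1L, duration = 21L) {
  off <- integer(duration)
  for (d in names(broods)) off[as.integer(d)] <- broods[[d]]
  individual_record(clone, concentration, parasite_level, replicate,
                    death_day, off, infected, challenge_days, duration)
}

# Small two-cohort design/table builders for fast pipeline tests.
tiny_preset <- function(name = "tebuconazole", seed = 1L, replicates = 4L) {
  sim_preset(name, seed = seed, replicates = replicates)
}
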