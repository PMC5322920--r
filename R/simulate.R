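#' Configuration of the individual-based life-history simulator
#'
#' The generator draws one daily trajectory per experimental unit:
#' accidental early mortality, daily Bernoulli survival with a baseline plus
#' a Hill-shaped toxicant hazard, infection drawn at each scheduled
#' challenge with toxicant-dependent suppression of parasite success,
#' parasite-induced death in a fixed day window for infected hosts, and
#' broods at the age at first reproduction and every interbrood interval
#' thereafter, with Poisson sizes whose mean declines with dose.
#'
#' @param design a [design_spec()] (its challenge schedule drives exposure).
#' @param seed master integer seed; per-unit substreams are derived from it
#'   deterministically, keyed by the unit's factor coordinates, so the same
#'   seed and configuration give a bit-identical experiment and adding
#'   replicates does not perturb existing units.
#' @param baseline_daily_death background daily death probability.
#' @param early_death_prob probability of accidental death on days 1-3.
#' @param toxicant_mortality list `EC50` (ug/L), `hill`, `max_added`: added
#'   daily death probability `max_added * c^h / (EC50^h + c^h)`.
#' @param infection list `p_control` (per-challenge infection probability at
#'   zero dose; scalar or named per clone), `suppression_EC50`,
#'   `suppression_hill`: parasite success is multiplied by
#'   `s(c) = 1 / (1 + (c/EC50)^h)`, with `s(0) = 1`.
#' @param infected_death_window integer range (default 14-17): infected
#'   hosts die on a day drawn uniformly from this window, unless an earlier
#'   hazard already killed them.
#' @param reproduction list: `AFR_mean` (days), `AFR_sd` (days),
#'   `AFR_delay` (`max_delay`, `K`, `hill`: Hill-shaped dose delay in days),
#'   `interbrood` (days), `brood_mean` (offspring per brood),
#'   `fecundity_decline` (`EC50`, `hill`), `hormesis_bump` (optional
#'   multiplier applied at intermediate doses, `NULL` for none),
#'   `challenge_penalty` (brood multiplier per experienced challenge, the
#'   small fitness cost of an unsuccessful challenge), `infected_penalty`
#'   (brood multiplier for infected hosts).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(design, seed = 1L,
                       baseline_daily_death = 0.003,
                       early_death_prob = 0.02,
                       toxicant_mortality = list(EC50 = Inf, hill = 1,
                                                 max_added = 0),
                       infection = list(p_control = 0.95,
                                        suppression_EC50 = Inf,
                                        suppression_hill = 1),
                       infected_death_window = c(14L, 17L),
                       reproduction = list(AFR_mean = 8, AFR_sd = 0.8,
                                           AFR_delay = list(max_delay = 0,
                                                            K = Inf, hill = 2),
                                           interbrood = 3L, brood_mean = 10,
                                           fecundity_decline = list(EC50 = Inf,
                                                                    hill = 2),
                                           hormesis_bump = NULL,
                                           challenge_penalty = 0.95,
                                           infected_penalty = 0.85)) {
  stopifnot(inherits(design, "design_spec"))
  probs <- c(baseline_daily_death, early_death_prob,
             toxicant_mortality$max_added, unlist(infection$p_control))
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  w <- as.integer(infected_death_window)
  if (length(w) != 2L || w[1] > w[2] || w[1] < 1L ||
      w[2] > design$duration_days)
    stop("infected_death_window must be an increasing day range within the assay",
         call. = FALSE)
  structure(list(design = design, seed = as.integer(seed),
                 baseline_daily_death = baseline_daily_death,
                 early_death_prob = early_death_prob,
                 toxicant_mortality = toxicant_mortality,
                 infection = infection,
                 infected_death_window = w,
                 reproduction = reproduction),
            class = "sim_config")
}

# Hill curves; both return 1 at c = 0 / EC50 = Inf, scaled by their asymptote.
hill_up <- function(conc, EC50, hill) {
  if (!is.finite(EC50) || conc <= 0) return(0)
  conc^hill / (EC50^hill + conc^hill)
}

hill_down <- function(conc, EC50, hill) {
  if (!is.finite(EC50) || conc <= 0) return(1)
  1 / (1 + (conc / EC50)^hill)
}

p_control_for <- function(infection, clone) {
  p <- infection$p_control
  if (!is.null(names(p)) && clone %in% names(p)) unname(p[[clone]])
  else unname(p[[1]])
}

#' Per-individual infection probability under the simulator's model
#'
#' Each experienced challenge succeeds independently with probability
#' `p_control(clone) * s(c)`, where `s(c) = 1 / (1 + (c/EC50)^hill)` is the
#' toxicant suppression of parasite success; an individual becomes infected
#' if any challenge succeeds: `p = 1 - (1 - p_single)^n_challenges`. Zero
#' challenges give probability zero.
#'
#' @param config a [sim_config()].
#' @param clone clone label.
#' @param concentration toxicant concentration, ug/L.
#' @param n_challenges number of experienced challenges.
#' @return probability of infection.
#' @export
infection_probability <- function(config, clone, concentration, n_challenges) {
  stopifnot(inherits(config, "sim_config"), n_challenges >= 0)
  if (n_challenges == 0) return(0)
  s <- hill_down(concentration, config$infection$suppression_EC50,
                 config$infection$suppression_hill)
  p_single <- p_control_for(config$infection, clone) * s
  1 - (1 - p_single)^n_challenges
}

# Deterministic 31-bit substream seed from the master seed and unit key.
substream_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  s <- ((seed %% 2147483647) * 16807 + h) %% 2147483647
  as.integer(max(s, 1))
}

#' Simulate one individual's daily trajectory
#'
#' Draws, in fixed order on the unit's private RNG substream: accidental
#' early death (uniform over days 1-3), a daily-hazard death day
#' (baseline + Hill toxicant term), infection at each challenge experienced
#' alive, a parasite-induced death day uniform on the infected death window
#' (overriding later hazards only), the individual age at first reproduction
#' (dose-delayed, rounded to days), and Poisson brood sizes every interbrood
#' interval while alive.
#'
#' @param config a [sim_config()].
#' @param clone,concentration,parasite_level,replicate unit coordinates.
#' @return An [individual_record()].
#' @export
simulate_individual <- function(config, clone, concentration, parasite_level,
                                replicate) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  dur <- design$duration_days
  set.seed(substream_seed(config$seed,
                          unit_key(clone, concentration, parasite_level,
                                   replicate)))
  # death by accident or daily hazard
  early <- stats::runif(1) < config$early_death_prob
  early_day <- sample(1:3, 1L)
  tox <- config$toxicant_mortality
  hazard <- config$baseline_daily_death +
    tox$max_added * hill_up(concentration, tox$EC50, tox$hill)
  u <- stats::runif(dur)
  hit <- which(u < hazard)
  death_day <- if (length(hit)) hit[1] else dur + 1L
  if (early) death_day <- min(death_day, early_day)
  # infection at challenges experienced alive
  cd <- design$challenge_days[[parasite_level]]
  experienced <- cd[cd < death_day]
  infected <- NA
  if (length(cd) > 0L) {
    infected <- FALSE
    if (length(experienced) > 0L) {
      s <- hill_down(concentration, config$infection$suppression_EC50,
                     config$infection$suppression_hill)
      p_single <- p_control_for(config$infection, clone) * s
      infected <- any(stats::runif(length(experienced)) < p_single)
    }
    if (infected) {
      w <- config$infected_death_window
      death_day <- min(death_day, sample(w[1]:w[2], 1L))
    }
  }
  # reproduction
  rep_par <- config$reproduction
  delay <- rep_par$AFR_delay$max_delay *
    hill_up(concentration, rep_par$AFR_delay$K, rep_par$AFR_delay$hill)
  afr <- max(5L, as.integer(round(rep_par$AFR_mean + delay +
                                    stats::rnorm(1, 0, rep_par$AFR_sd))))
  offspring <- integer(dur)
  if (afr <= dur) {
    brood_days <- seq.int(afr, dur, by = rep_par$interbrood)
    brood_days <- brood_days[brood_days < death_day]
    if (length(brood_days)) {
      mu <- rep_par$brood_mean *
        hill_down(concentration, rep_par$fecundity_decline$EC50,
                  rep_par$fecundity_decline$hill)
      if (!is.null(rep_par$hormesis_bump) && concentration > 0 &&
          concentration < max(design$concentrations))
        mu <- mu * rep_par$hormesis_bump
      mu <- mu * rep_par$challenge_penalty^length(experienced)
      if (isTRUE(infected)) mu <- mu * rep_par$infected_penalty
      offspring[brood_days] <- stats::rpois(length(brood_days), mu)
    }
  }
  individual_record(clone = clone, concentration = concentration,
                    parasite_level = parasite_level, replicate = replicate,
                    death_day = death_day, offspring = offspring,
                    infected = infected, challenge_days = cd, duration = dur)
}

#' Simulate a full factorial experiment
#'
#' One [simulate_individual()] per experimental unit of the design, each on
#' its own deterministic RNG substream. The result passes the same
#' validation as data read from file.
#'
#' @param config a [sim_config()].
#' @return An [experiment_table()].
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  units <- expand_design(config$design)
  recs <- lapply(seq_len(nrow(units)), function(i)
    simulate_individual(config, units$clone[i], units$concentration[i],
                        units$parasite_level[i], units$replicate[i]))
  experiment_table(config$design, recs)
}

#' @rdname simulate_experiment
#' @param object a [sim_config()].
#' @param nsim number of experiments to simulate.
#' @param seed optional master seed overriding `object$seed`; successive
#'   experiments use `seed, seed + 1, ...`.
#' @param ... ignored.
#' @return For the `simulate` method: a list of `nsim`
#'   [experiment_table()]s.
#' @export
simulate.sim_config <- function(object, nsim = 1, seed = NULL, ...) {
  base <- if (is.null(seed)) object$seed else as.integer(seed)
  lapply(seq_len(nsim) - 1L, function(k) {
    cfg <- object
    cfg$seed <- base + k
    simulate_experiment(cfg)
  })
}

#' Preset simulator configurations for the three study designs
#'
#' Three ready-made configurations emulating the study conditions of the
#' factorial experiments the pipeline targets:
#'
#' * `"copper"` — 2 clones x concentrations 0/25.0/28.8/33.1 ug/L x
#'   no-parasite/parasite x 20 replicates (320 units). Copper adds mortality
#'   only near the highest concentration, does not suppress infection
#'   (suppression EC50 infinite), and carries a slight hormetic brood bump
#'   at intermediate doses.
#' * `"tebuconazole"` — 2 clones x 0/154/192/240 ug/L x
#'   no-parasite/parasite x 20 (320 units). The fungicide suppresses
#'   parasite success steeply (EC50 5 ug/L, Hill slope 6: partial
#'   suppression at 6.25, essentially complete from 12.5 upward), declines
#'   fecundity monotonically and delays first reproduction, with no direct
#'   mortality.
#' * `"followup"` — 2 clones x 0/6.25/12.5/25.0/50.0/100.0 ug/L
#'   tebuconazole x single/double challenge (days 5 vs 3+5) x 20 (480
#'   units), with clone-specific control infectivity (about 0.90 for clone
#'   12 and 0.58 for clone 47 per single challenge).
#'
#' @param name `"copper"`, `"tebuconazole"` or `"followup"`.
#' @param seed master seed stored in the configuration.
#' @param replicates replicates per cell (default 20, the study condition).
#' @return A [sim_config()].
#' @export
sim_preset <- function(name = c("copper", "tebuconazole", "followup"),
                       seed = 1L, replicates = 20L) {
  name <- match.arg(name)
  clones <- c("12", "47")
  if (name == "copper") {
    design <- design_spec(clones, c(0, 25.0, 28.8, 33.1),
                          c("no-parasite", "parasite"), replicates,
                          contaminant = "copper",
                          challenge_days = list("no-parasite" = integer(0),
                                                "parasite" = 5L))
    sim_config(design, seed = seed,
               toxicant_mortality = list(EC50 = 32, hill = 20, max_added = 0.02),
               infection = list(p_control = c("12" = 0.95, "47" = 0.95),
                                suppression_EC50 = Inf, suppression_hill = 1),
               reproduction = list(AFR_mean = 8, AFR_sd = 0.8,
                                   AFR_delay = list(max_delay = 2, K = 40,
                                                    hill = 4),
                                   interbrood = 3L, brood_mean = 10,
                                   fecundity_decline = list(EC50 = 60, hill = 3),
                                   hormesis_bump = 1.1,
                                   challenge_penalty = 0.95,
                                   infected_penalty = 0.85))
  } else if (name == "tebuconazole") {
    design <- design_spec(clones, c(0, 154, 192, 240),
                          c("no-parasite", "parasite"), replicates,
                          contaminant = "tebuconazole",
                          challenge_days = list("no-parasite" = integer(0),
                                                "parasite" = 5L))
    sim_config(design, seed = seed,
               toxicant_mortality = list(EC50 = Inf, hill = 1, max_added = 0),
               infection = list(p_control = c("12" = 0.95, "47" = 0.95),
                                suppression_EC50 = 5, suppression_hill = 6),
               reproduction = list(AFR_mean = 8, AFR_sd = 0.8,
                                   AFR_delay = list(max_delay = 3, K = 220,
                                                    hill = 3),
                                   interbrood = 3L, brood_mean = 10,
                                   fecundity_decline = list(EC50 = 200, hill = 2),
                                   hormesis_bump = NULL,
                                   challenge_penalty = 0.95,
                                   infected_penalty = 0.85))
  } else {
    design <- design_spec(clones, c(0, 6.25, 12.5, 25.0, 50.0, 100.0),
                          c("single", "double"), replicates,
                          contaminant = "tebuconazole",
                          challenge_days = list("single" = 5L,
                                                "double" = c(3L, 5L)))
    sim_config(design, seed = seed,
               toxicant_mortality = list(EC50 = Inf, hill = 1, max_added = 0),
               infection = list(p_control = c("12" = 0.90, "47" = 0.58),
                                suppression_EC50 = 5, suppression_hill = 6),
               reproduction = list(AFR_mean = 8, AFR_sd = 0.8,
                                   AFR_delay = list(max_delay = 3, K = 220,
                                                    hill = 3),
                                   interbrood = 3L, brood_mean = 10,
                                   fecundity_decline = list(EC50 = 200, hill = 2),
                                   hormesis_bump = NULL,
                                   challenge_penalty = 0.95,
                                   infected_penalty = 0.85))
  }
}
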