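#' Age at first reproduction
#'
#' The first experiment day on which the individual released living
#' offspring; `NA` for an individual that never reproduced.
#'
#' @param record an [individual_record()].
#' @return integer day or `NA`.
#' @export
age_at_first_reproduction <- function(record) {
  d <- which(record$offspring > 0L)
  if (length(d)) d[1] else NA_integer_
}

#' Cumulative fecundity at day 14
#'
#' Cumulative number of living offspring released over days 1-14, defined
#' only for females surviving through day 14 (death day strictly after 14);
#' `NA` otherwise. A survivor with no broods scores an explicit zero.
#'
#' @param record an [individual_record()].
#' @return integer count or `NA`.
#' @export
fecundity_day14 <- function(record) {
  if (record$death_day <= 14L) return(NA_integer_)
  sum(record$offspring[seq_len(min(14L, record$duration))])
}

#' Cumulative reproductive output at day 21
#'
#' Cumulative living offspring over the whole assay. Individuals that died
#' during the test contribute their partial total, so the endpoint integrates
#' toxicant and parasite effects on both survival and fecundity. Individuals
#' that died before day 4 are excluded (`NA`): such early deaths are treated
#' as accidental or natural early-age mortality, not a treatment effect.
#'
#' @param record an [individual_record()].
#' @return integer count, or `NA` for an excluded individual.
#' @export
reproductive_output_day21 <- function(record) {
  if (record$death_day < 4L) return(NA_integer_)
  sum(record$offspring)
}

#' Proportion dead at test end in a treatment cell
#'
#' @param records non-empty list of [individual_record()]s from one cell.
#' @return list with `proportion`, `dead` (numerator) and `n` (denominator).
#' @export
mortality_proportion <- function(records) {
  if (length(records) == 0L) stop("empty treatment cell", call. = FALSE)
  dur <- records[[1]]$duration
  dead <- sum(vapply(records, function(r) r$death_day <= dur, logical(1)))
  list(proportion = dead / length(records), dead = dead, n = length(records))
}

#' Proportion infected in a challenged treatment cell
#'
#' Hosts are inspected for spores at time of death or at test end, so the
#' denominator is every individual with a known infection status, not only
#' survivors. Calling this on an unchallenged cell is an error.
#'
#' @param records non-empty list of [individual_record()]s from one
#'   challenged cell.
#' @return list with `proportion`, `infected` (numerator) and `inspected`
#'   (denominator).
#' @export
infection_proportion <- function(records) {
  if (length(records) == 0L) stop("empty treatment cell", call. = FALSE)
  challenged <- vapply(records, function(r) length(r$challenge_days) > 0L,
                       logical(1))
  if (!any(challenged))
    stop("infection proportion is undefined for an unchallenged cell",
         call. = FALSE)
  status <- vapply(records, function(r) r$infected, logical(1))
  inspected <- sum(!is.na(status))
  if (inspected == 0L)
    stop("no inspectable individuals in cell", call. = FALSE)
  list(proportion = sum(status, na.rm = TRUE) / inspected,
       infected = sum(status, na.rm = TRUE), inspected = inspected)
}

#' Derive all endpoints of an experiment
#'
#' Applies the per-individual endpoints (age at first reproduction, day-14
#' fecundity, day-21 reproductive output with the early-death exclusion) to
#' every individual and the cell-level mortality / infection proportions to
#' every treatment cell. Deterministic: row order follows the design
#' expansion.
#'
#' @param table an [experiment_table()].
#' @return Object of class `endpoint_table`: list with data.frames
#'   `individuals` (one row per individual) and `cells` (one row per
#'   clone x concentration x parasite level cell, with explicit numerators
#'   and denominators; infection columns are `NA` for unchallenged cells).
#' @export
endpoint_table <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  recs <- table$records
  dur <- table$design$duration_days
  ind <- cbind(table$units, data.frame(
    death_day = vapply(recs, function(r) r$death_day, integer(1)),
    censored = vapply(recs, is_censored, logical(1)),
    infected = vapply(recs, function(r) r$infected, logical(1)),
    afr = vapply(recs, age_at_first_reproduction, integer(1)),
    fecundity_day14 = vapply(recs, fecundity_day14, integer(1)),
    reproductive_output_day21 = vapply(recs, reproductive_output_day21,
                                       integer(1))))
  ind$excluded <- ind$death_day < 4L
  cells_key <- unique(table$units[c("clone", "concentration", "parasite_level")])
  rows <- lapply(seq_len(nrow(cells_key)), function(i) {
    ck <- cells_key[i, ]
    rs <- cell_records(table, ck$clone, ck$concentration, ck$parasite_level)
    m <- mortality_proportion(rs)
    challenged <- is_challenged(table$design, ck$parasite_level)
    if (challenged) {
      p <- infection_proportion(rs)
    } else {
      p <- list(proportion = NA_real_, infected = NA_integer_,
                inspected = NA_integer_)
    }
    data.frame(ck, mortality = m$proportion, n_dead = m$dead, n_total = m$n,
               infection = p$proportion, n_infected = p$infected,
               n_inspected = p$inspected, stringsAsFactors = FALSE)
  })
  structure(list(individuals = ind, cells = do.call(rbind, rows),
                 duration_days = dur),
            class = "endpoint_table")
}

#' @export
print.endpoint_table <- function(x, ...) {
  cat("Endpoint table: ", nrow(x$individuals), " individuals, ",
      nrow(x$cells), " treatment cells\n", sep = "")
  cat("  excluded from reproductive output (death before day 4): ",
      sum(x$individuals$excluded), "\n", sep = "")
  invisible(x)
}

#' Per-cell endpoint means with 95% confidence intervals
#'
#' Mean and two-sided t-based 95% confidence interval per treatment cell for
#' a chosen per-individual endpoint, the summary conventionally plotted for
#' factorial life-history assays.
#'
#' @param endpoints an [endpoint_table()].
#' @param endpoint one of `"afr"`, `"fecundity_day14"`,
#'   `"reproductive_output_day21"`.
#' @param level confidence level.
#' @return data.frame with cell keys, `n`, `mean`, `lower`, `upper`.
#' @export
endpoint_cell_summary <- function(endpoints, endpoint = "reproductive_output_day21",
                                  level = 0.95) {
  stopifnot(inherits(endpoints, "endpoint_table"))
  endpoint <- match.arg(endpoint,
                        c("afr", "fecundity_day14", "reproductive_output_day21"))
  ind <- endpoints$individuals
  f <- interaction(ind$clone, ind$concentration, ind$parasite_level, drop = TRUE)
  rows <- lapply(split(ind, f), function(g) {
    v <- g[[endpoint]]
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    half <- if (n >= 2L && stats::sd(v) > 0)
      stats::qt(1 - (1 - level) / 2, n - 1L) * stats::sd(v) / sqrt(n) else 0
    data.frame(clone = g$clone[1], concentration = g$concentration[1],
               parasite_level = g$parasite_level[1], n = n, mean = m,
               lower = m - half, upper = m + half, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$clone, out$concentration, out$parasite_level), ]
}
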