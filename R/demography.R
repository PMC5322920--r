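#' Age-specific survivorship and fecundity schedule of a cohort
#'
#' Builds the life-table schedule of a treatment cohort at daily resolution.
#' `lx` is the probability of surviving to age `x` (an individual with death
#' day `d` survives to ages strictly below `d`, so the daily census precedes
#' brood counting); `mx` is the mean number of living offspring released per
#' female alive at age `x`, and 0 at ages where nobody is alive (there
#' `lx = 0` makes the product vanish). With the mean-per-survivor convention
#' `lx * mx` is the per-capita expected offspring at age `x`, the standard
#' life-table identity.
#'
#' @param records non-empty list of [individual_record()]s (one cohort).
#' @return Object of class `cohort_schedule`: data.frame with columns `x`
#'   (age 0..duration), `lx`, `mx`, and attribute `n` (cohort size).
#' @export
cohort_schedule <- function(records) {
  if (length(records) == 0L) stop("empty cohort", call. = FALSE)
  dur <- records[[1]]$duration
  death <- vapply(records, function(r) r$death_day, integer(1))
  n <- length(records)
  x <- 0:dur
  alive_at <- vapply(x, function(a) sum(death > a), numeric(1))
  births <- rowSums(vapply(records, function(r) as.numeric(r$offspring),
                           numeric(dur)))
  mx <- c(0, ifelse(alive_at[-1] > 0, births / pmax(alive_at[-1], 1), 0))
  out <- data.frame(x = x, lx = alive_at / n, mx = mx)
  attr(out, "n") <- n
  class(out) <- c("cohort_schedule", "data.frame")
  out
}

euler_lotka_f <- function(r, x, terms) {
  sum(exp(-r * x) * terms) - 1
}

#' Solve the Euler-Lotka equation for the intrinsic rate of increase
#'
#' Finds the unique real root r of `sum_x exp(-r x) lx mx = 1`, the
#' per-capita intrinsic rate of population increase (day^-1) implied by the
#' cohort's survivorship and fecundity schedule. The left-hand side is
#' strictly decreasing in r whenever some reproduction occurs at a positive
#' age, so the root is unique; a cohort with no reproduction at all has no
#' root and yields `NA`. A cohort whose lifetime reproduction
#' `sum lx mx` falls below one has a negative rate, reported as such.
#'
#' The root is located by a bracketing search on `[-10, 10]` day^-1,
#' geometrically expanded while the function does not change sign, followed
#' by monotone-safe refinement to `|f(r)| <= 1e-10`.
#'
#' @param schedule a [cohort_schedule()] (or any data.frame with columns
#'   `x`, `lx`, `mx`).
#' @return rate of increase in day^-1, or `NA` if undefined.
#' @export
solve_euler_lotka <- function(schedule) {
  x <- schedule$x
  terms <- schedule$lx * schedule$mx
  if (any(terms < 0) || any(schedule$lx < 0 | schedule$lx > 1))
    stop("invalid schedule: negative terms or survivorship outside [0,1]",
         call. = FALSE)
  keep <- terms > 0
  if (!any(keep)) return(NA_real_)
  x <- x[keep]; terms <- terms[keep]
  if (all(x == 0)) return(NA_real_)  # reproduction only at age 0: no root
  lo <- -10; hi <- 10
  while (euler_lotka_f(lo, x, terms) < 0 && lo > -1e6) lo <- lo * 2
  while (euler_lotka_f(hi, x, terms) > 0 && hi < 1e6) hi <- hi * 2
  root <- stats::uniroot(euler_lotka_f, c(lo, hi), x = x, terms = terms,
                         tol = 1e-14, maxiter = 2000L)$root
  # bisection polish in the rare case uniroot's convergence test stops early
  flo <- euler_lotka_f(lo, x, terms); fhi <- euler_lotka_f(hi, x, terms)
  iter <- 0L
  while (abs(euler_lotka_f(root, x, terms)) > 1e-10 && iter < 200L) {
    if (euler_lotka_f(root, x, terms) > 0) lo <- root else hi <- root
    root <- (lo + hi) / 2
    iter <- iter + 1L
  }
  root
}

#' Jackknife pseudo-values for the intrinsic rate of increase
#'
#' Estimates r on the full cohort and on every leave-one-out cohort, and
#' forms per-individual pseudo-values `r_i = n r - (n-1) r_(-i)`, turning
#' the cohort-level demographic estimate into replicate values usable in
#' ANOVA. A leave-one-out cohort in which r is undefined (e.g. the only
#' reproducing member was removed) yields a missing pseudo-value; if r is
#' undefined on the full cohort all pseudo-values are missing.
#'
#' @param records list of at least two [individual_record()]s (one cohort).
#' @return Object of class `demographic_estimate`: list with `r_full`,
#'   `pseudo_values` (length n, `NA` where undefined), `loo` (the
#'   leave-one-out estimates) and `n`.
#' @export
jackknife_pseudovalues <- function(records) {
  n <- length(records)
  if (n < 2L) stop("jackknife needs a cohort of at least 2", call. = FALSE)
  r_full <- solve_euler_lotka(cohort_schedule(records))
  if (is.na(r_full)) {
    loo <- rep(NA_real_, n)
    pv <- rep(NA_real_, n)
  } else {
    loo <- vapply(seq_len(n), function(i)
      solve_euler_lotka(cohort_schedule(records[-i])), numeric(1))
    pv <- n * r_full - (n - 1) * loo
  }
  structure(list(r_full = r_full, pseudo_values = pv, loo = loo, n = n),
            class = "demographic_estimate")
}

#' @export
print.demographic_estimate <- function(x, ...) {
  cat("Intrinsic rate of increase (Euler-Lotka)\n")
  cat("  r (full cohort):    ",
      if (is.na(x$r_full)) "undefined" else format(x$r_full, digits = 6),
      " day^-1\n", sep = "")
  cat("  cohort size:        ", x$n, "\n", sep = "")
  ok <- sum(!is.na(x$pseudo_values))
  cat("  pseudo-values:      ", ok, " defined",
      if (ok < x$n) paste0(" (", x$n - ok, " missing)") else "", "\n", sep = "")
  if (ok)
    cat("  pseudo-value mean:  ",
        format(mean(x$pseudo_values, na.rm = TRUE), digits = 6),
        " day^-1\n", sep = "")
  invisible(x)
}

#' Jackknife pseudo-values for every treatment cell of an experiment
#'
#' Treats each clone x concentration x parasite level cell (all its
#' replicates) as one cohort, and emits one row per pseudo-value keyed by
#' the treatment factors — the replicate-level response used for the
#' rate-of-increase ANOVA. Missing pseudo-values are kept as `NA` rows so
#' the complete-case drop is visible downstream.
#'
#' @param table an [experiment_table()].
#' @return data.frame with columns `clone`, `concentration`,
#'   `parasite_level`, `replicate`, `pseudo_value`, `r_full`.
#' @export
pseudovalue_table <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  cells <- unique(table$units[c("clone", "concentration", "parasite_level")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ck <- cells[i, ]
    rs <- cell_records(table, ck$clone, ck$concentration, ck$parasite_level)
    est <- jackknife_pseudovalues(rs)
    data.frame(ck,
               replicate = vapply(rs, function(r) r$replicate, integer(1)),
               pseudo_value = est$pseudo_values,
               r_full = est$r_full, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
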