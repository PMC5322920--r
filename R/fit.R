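#' Fit the full factorial life-history analysis
#'
#' The package's main model fit. For every clone and every endpoint —
#' ln age at first reproduction, day-14 fecundity, day-21 reproductive
#' output and the intrinsic rate of increase (through its jackknife
#' pseudo-values) — a two-way fixed-effects ANOVA of toxicant concentration,
#' parasite treatment and their interaction is fitted on complete cases.
#' Analyses run separately per clone, so the working significance level is
#' Dunn-Sidak adjusted for the number of clones
#' (`1 - (1 - family_alpha)^(1/n_clones)`, i.e. 0.0253 for two clones at
#' family alpha 0.05).
#'
#' @param table a validated [experiment_table()].
#' @param family_alpha family-wise error rate (default 0.05).
#' @param ss_type sums-of-squares decomposition, `"II"` (default) or `"I"`;
#'   see [two_way_anova()].
#' @return Object of class `lifetable_fit`: list with `anovas` (nested list
#'   `[[clone]][[endpoint]]` of [two_way_anova()] tables), `alpha`
#'   (adjusted level), `endpoints` (the [endpoint_table()]), `pseudovalues`
#'   (the [pseudovalue_table()]), `design`, and `transformations`.
#' @seealso [summary.lifetable_fit()], [as.data.frame.lifetable_fit()],
#'   [write_anova()]
#' @export
fit_lifetable <- function(table, family_alpha = 0.05, ss_type = c("II", "I")) {
  stopifnot(inherits(table, "experiment_table"))
  ss_type <- match.arg(ss_type)
  eps <- endpoint_table(table)
  pv <- pseudovalue_table(table)
  alpha <- dunn_sidak_alpha(family_alpha, length(table$design$clones))
  ind <- eps$individuals
  endpoints <- c("ln_afr", "fecundity_day14", "reproductive_output_day21",
                 "rate_of_increase")
  transformations <- c(ln_afr = "natural log", fecundity_day14 = "none",
                       reproductive_output_day21 = "none",
                       rate_of_increase = "none")
  anovas <- lapply(table$design$clones, function(cl) {
    sub <- ind[ind$clone == cl, ]
    resp <- list(
      ln_afr = transform_endpoint(as.numeric(sub$afr), "afr"),
      fecundity_day14 = as.numeric(sub$fecundity_day14),
      reproductive_output_day21 = as.numeric(sub$reproductive_output_day21))
    fits <- lapply(endpoints, function(ep) {
      if (ep == "rate_of_increase") {
        d <- pv[pv$clone == cl, ]
        d$value <- d$pseudo_value
      } else {
        d <- sub
        d$value <- resp[[ep]]
      }
      two_way_anova(d, "value", alpha = alpha, ss_type = ss_type)
    })
    names(fits) <- endpoints
    fits
  })
  names(anovas) <- table$design$clones
  structure(list(anovas = anovas, alpha = alpha, family_alpha = family_alpha,
                 endpoints = eps, pseudovalues = pv, design = table$design,
                 transformations = transformations, ss_type = ss_type),
            class = "lifetable_fit")
}

#' @export
print.lifetable_fit <- function(x, digits = 3, ...) {
  cat("Factorial life-history analysis (", x$design$contaminant, ")\n",
      sep = "")
  cat("Two-way ANOVA per clone; Dunn-Sidak adjusted alpha = ",
      format(round(x$alpha, 4)), " (family alpha ", x$family_alpha, ", ",
      length(x$design$clones), " clones)\n\n", sep = "")
  for (cl in names(x$anovas)) {
    cat("Clone ", cl, ":\n", sep = "")
    for (ep in names(x$anovas[[cl]])) {
      a <- x$anovas[[cl]][[ep]]
      cat("  ", format(ep, width = 26), "\n", sep = "")
      for (i in 1:3) {
        star <- if (isTRUE(a$significant[i])) " *" else ""
        cat(sprintf("    %-14s F(%d, %d) = %s; P = %s%s\n", a$term[i],
                    a$df[i], a$df[4],
                    format(signif(a$F[i], digits)),
                    format.pval(a$P[i], digits = digits, eps = 1e-3), star))
      }
    }
  }
  cat("\n'*' marks P <= adjusted alpha\n")
  invisible(x)
}

#' Flatten a fitted analysis into one summary data.frame
#'
#' One row per clone x endpoint x term with the conventional summary
#' columns: F, numerator and denominator df, P, and a significance flag at
#' the Dunn-Sidak adjusted level.
#'
#' @param x a [fit_lifetable()] result.
#' @param row.names,optional,... ignored (data.frame method signature).
#' @return data.frame.
#' @export
as.data.frame.lifetable_fit <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  rows <- list()
  for (cl in names(x$anovas)) {
    for (ep in names(x$anovas[[cl]])) {
      a <- x$anovas[[cl]][[ep]]
      rows[[length(rows) + 1L]] <- data.frame(
        clone = cl, endpoint = ep, source = a$term[1:3],
        F = a$F[1:3], df1 = a$df[1:3], df2 = a$df[4], P = a$P[1:3],
        significant = a$significant[1:3], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
summary.lifetable_fit <- function(object, ...) {
  out <- list(table = as.data.frame(object), alpha = object$alpha,
              cells = object$endpoints$cells,
              excluded = sum(object$endpoints$individuals$excluded),
              missing_pseudovalues = sum(is.na(object$pseudovalues$pseudo_value)),
              design = object$design)
  class(out) <- "summary.lifetable_fit"
  out
}

#' @export
print.summary.lifetable_fit <- function(x, ...) {
  cat("Life-history factorial analysis summary\n")
  cat("  adjusted alpha: ", format(round(x$alpha, 4)), "\n", sep = "")
  cat("  individuals excluded from reproductive output: ", x$excluded,
      "\n", sep = "")
  cat("  missing jackknife pseudo-values: ", x$missing_pseudovalues, "\n\n",
      sep = "")
  tab <- x$table
  tab$F <- signif(tab$F, 3)
  tab$P <- signif(tab$P, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
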