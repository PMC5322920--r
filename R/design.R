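#' Describe a factorial host x toxicant x parasite design
#'
#' A design is the full crossing of host clones, toxicant concentrations,
#' parasite treatment levels and replicate vessels, observed daily for a
#' fixed number of days (21 by default, the standard chronic-test duration).
#'
#' The parasite challenge schedule is part of the design, not of individual
#' records: `challenge_days` maps every parasite level to the experiment days
#' on which hosts of that level are inoculated (an empty vector marks an
#' unchallenged level, e.g. the "no-parasite" control).
#'
#' @param clones character vector of clone labels (no duplicates).
#' @param concentrations strictly increasing numeric vector of nominal
#'   toxicant concentrations, ug/L.
#' @param parasite_levels character vector of parasite treatment labels.
#' @param replicates positive integer: vessels per design cell.
#' @param contaminant name of the toxicant the concentrations refer to.
#' @param challenge_days named list mapping each parasite level to an integer
#'   vector of inoculation days within `[1, duration_days]`. Defaults to
#'   day 5 for every level whose label is not recognisably an unchallenged
#'   control ("no-parasite", "control", "none").
#' @param duration_days positive integer, length of the assay in days.
#' @return An object of class `design_spec`.
#' @examples
#' d <- design_spec(c("12", "47"), c(0, 154, 192, 240),
#'                  c("no-parasite", "parasite"), 20,
#'                  contaminant = "tebuconazole")
#' nrow(expand_design(d))  # 320
#' @export
design_spec <- function(clones, concentrations, parasite_levels, replicates,
                        contaminant = "toxicant", challenge_days = NULL,
                        duration_days = 21L) {
  clones <- as.character(clones)
  parasite_levels <- as.character(parasite_levels)
  if (length(clones) == 0L || length(concentrations) == 0L ||
      length(parasite_levels) == 0L)
    stop("design error: every factor needs at least one level", call. = FALSE)
  if (anyDuplicated(clones))
    stop("design error: duplicate clone labels", call. = FALSE)
  if (anyDuplicated(parasite_levels))
    stop("design error: duplicate parasite level labels", call. = FALSE)
  if (any(concentrations < 0) || is.unsorted(concentrations, strictly = TRUE))
    stop("design error: concentrations must be non-negative and strictly increasing",
         call. = FALSE)
  replicates <- as.integer(replicates)
  if (length(replicates) != 1L || is.na(replicates) || replicates < 1L)
    stop("design error: replicates must be a positive integer", call. = FALSE)
  duration_days <- as.integer(duration_days)
  if (length(duration_days) != 1L || is.na(duration_days) || duration_days < 1L)
    stop("design error: duration_days must be a positive integer", call. = FALSE)
  if (is.null(challenge_days)) {
    unchallenged <- c("no-parasite", "control", "none")
    challenge_days <- lapply(parasite_levels, function(lv)
      if (tolower(lv) %in% unchallenged) integer(0) else 5L)
    names(challenge_days) <- parasite_levels
  }
  if (!setequal(names(challenge_days), parasite_levels))
    stop("design error: challenge_days must be named by the parasite levels",
         call. = FALSE)
  challenge_days <- lapply(challenge_days[parasite_levels], as.integer)
  bad <- vapply(challenge_days, function(d)
    any(is.na(d) | d < 1L | d > duration_days), logical(1))
  if (any(bad))
    stop("design error: challenge days outside [1, duration_days] for level(s) ",
         paste(names(challenge_days)[bad], collapse = ", "), call. = FALSE)
  structure(
    list(clones = clones,
         concentrations = as.numeric(concentrations),
         parasite_levels = parasite_levels,
         replicates = replicates,
         contaminant = as.character(contaminant)[1],
         challenge_days = challenge_days,
         duration_days = duration_days),
    class = "design_spec")
}

#' Expand a design into its experimental units
#'
#' Returns the full cross-product of clone x concentration x parasite level
#' x replicate in deterministic lexicographic order (clone slowest,
#' replicate fastest), one row per experimental unit.
#'
#' @param design a [design_spec()].
#' @return data.frame with columns `clone`, `concentration`,
#'   `parasite_level`, `replicate`.
#' @export
expand_design <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  nc <- length(design$clones); nk <- length(design$concentrations)
  np <- length(design$parasite_levels); nr <- design$replicates
  n <- nc * nk * np * nr
  data.frame(
    clone = rep(design$clones, each = nk * np * nr),
    concentration = rep(rep(design$concentrations, each = np * nr), times = nc),
    parasite_level = rep(rep(design$parasite_levels, each = nr), times = nc * nk),
    replicate = rep(seq_len(nr), times = n / nr),
    stringsAsFactors = FALSE)
}

#' @export
print.design_spec <- function(x, ...) {
  n <- length(x$clones) * length(x$concentrations) *
    length(x$parasite_levels) * x$replicates
  cat("Factorial life-history design (", x$duration_days, " days)\n", sep = "")
  cat("  contaminant:    ", x$contaminant, "\n", sep = "")
  cat("  clones:         ", paste(x$clones, collapse = ", "), "\n", sep = "")
  cat("  concentrations: ", paste(format(x$concentrations), collapse = ", "),
      " ug/L\n", sep = "")
  cat("  parasite levels:", paste(x$parasite_levels, collapse = ", "), "\n")
  cat("  replicates:     ", x$replicates, " -> ", n, " experimental units\n",
      sep = "")
  invisible(x)
}

#' Is a parasite level a challenged treatment?
#' @param design a [design_spec()].
#' @param level a parasite level label.
#' @return logical.
#' @export
is_challenged <- function(design, level) {
  stopifnot(inherits(design, "design_spec"))
  if (!level %in% design$parasite_levels)
    stop("unknown parasite level: ", level, call. = FALSE)
  length(design$challenge_days[[level]]) > 0L
}
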