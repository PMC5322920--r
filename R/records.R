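#' One individual's full daily trajectory
#'
#' Constructs a validated record of one test organism: when it died (or the
#' censoring sentinel `duration + 1` if it was still alive at test end), how
#' many living offspring it released on each day, and its infection status at
#' inspection (hosts are inspected at time of death or at test end; `NA`
#' marks an unchallenged individual whose status carries no information).
#'
#' @param clone clone label.
#' @param concentration toxicant concentration, ug/L.
#' @param parasite_level parasite treatment label.
#' @param replicate positive integer replicate index.
#' @param death_day integer day of death in `[1, duration]`, or
#'   `duration + 1` for an individual censored alive at test end.
#' @param offspring integer vector of length `duration`; `offspring[d]` is
#'   the number of living offspring released on day `d`. Offspring may occur
#'   up to and including the death day, never after.
#' @param infected `TRUE`/`FALSE` for challenged individuals, `NA` otherwise.
#' @param challenge_days integer vector of inoculation days (empty if
#'   unchallenged).
#' @param duration assay length in days.
#' @return An object of class `individual_record`.
#' @export
individual_record <- function(clone, concentration, parasite_level, replicate,
                              death_day, offspring, infected = NA,
                              challenge_days = integer(0), duration = 21L) {
  duration <- as.integer(duration)
  death_day <- as.integer(death_day)
  replicate <- as.integer(replicate)
  offspring <- as.integer(offspring)
  challenge_days <- as.integer(challenge_days)
  if (length(offspring) != duration || any(is.na(offspring)) || any(offspring < 0))
    stop("offspring must be ", duration,
         " non-negative daily counts", call. = FALSE)
  if (is.na(death_day) || death_day < 1L || death_day > duration + 1L)
    stop("death_day must lie in [1, duration] or be the censoring sentinel ",
         duration + 1L, call. = FALSE)
  if (death_day <= duration && death_day < duration &&
      any(offspring[seq.int(death_day + 1L, duration)] > 0L))
    stop("offspring recorded after death (death_day = ", death_day, ")",
         call. = FALSE)
  if (any(challenge_days < 1L | challenge_days > duration))
    stop("challenge days must lie in [1, duration]", call. = FALSE)
  infected <- as.logical(infected)[1]
  if (isTRUE(infected) && length(challenge_days) == 0L)
    stop("infected may be TRUE only for a challenged treatment", call. = FALSE)
  structure(
    list(clone = as.character(clone),
         concentration = as.numeric(concentration),
         parasite_level = as.character(parasite_level),
         replicate = replicate,
         death_day = death_day,
         offspring = offspring,
         infected = infected,
         challenge_days = challenge_days,
         duration = duration),
    class = "individual_record")
}

#' Is the individual censored (alive at test end)?
#' @param record an [individual_record()].
#' @return logical.
#' @export
is_censored <- function(record) {
  record$death_day > record$duration
}

unit_key <- function(clone, concentration, parasite_level, replicate) {
  # as.character is element-wise, so scalar and vectorised calls agree
  paste(clone, as.character(concentration), parasite_level, replicate,
        sep = "|")
}

record_key <- function(r) {
  unit_key(r$clone, r$concentration, r$parasite_level, r$replicate)
}

#' Assemble validated records into an experiment table
#'
#' Checks that the records cover every experimental unit of the design
#' exactly once and agree with the design's factor levels, duration and
#' challenge schedule.
#'
#' @param design a [design_spec()].
#' @param records list of [individual_record()] objects.
#' @return An object of class `experiment_table` with elements `design`,
#'   `records` (in design expansion order) and `units` (the expansion
#'   data.frame).
#' @export
experiment_table <- function(design, records) {
  stopifnot(inherits(design, "design_spec"))
  if (!all(vapply(records, inherits, logical(1), "individual_record")))
    stop("records must be individual_record objects", call. = FALSE)
  units <- expand_design(design)
  want <- unit_key(units$clone, units$concentration, units$parasite_level,
                   units$replicate)
  have <- vapply(records, record_key, character(1))
  dup <- have[duplicated(have)]
  if (length(dup))
    stop("duplicate experimental unit(s): ", paste(unique(dup), collapse = "; "),
         call. = FALSE)
  missing <- setdiff(want, have)
  if (length(missing))
    stop("missing experimental unit(s): ",
         paste(utils::head(missing, 5L), collapse = "; "),
         if (length(missing) > 5L) " ..." else "", call. = FALSE)
  extra <- setdiff(have, want)
  if (length(extra))
    stop("record(s) outside the design: ", paste(utils::head(extra, 5L),
         collapse = "; "), call. = FALSE)
  for (r in records) {
    if (r$duration != design$duration_days)
      stop("unit ", record_key(r), ": duration mismatch with design",
           call. = FALSE)
    cd <- design$challenge_days[[r$parasite_level]]
    if (isTRUE(r$infected) && length(cd) == 0L)
      stop("unit ", record_key(r),
           ": infected in an unchallenged treatment", call. = FALSE)
  }
  structure(list(design = design, records = records[match(want, have)],
                 units = units),
            class = "experiment_table")
}

#' @export
print.experiment_table <- function(x, ...) {
  cat("Experiment table: ", length(x$records), " individuals\n", sep = "")
  print(x$design)
  ncens <- sum(vapply(x$records, is_censored, logical(1)))
  cat("  censored alive at day ", x$design$duration_days, ": ", ncens, "\n",
      sep = "")
  invisible(x)
}

#' Subset the records of one treatment cell
#'
#' @param table an [experiment_table()].
#' @param clone,concentration,parasite_level cell coordinates; any may be
#'   `NULL` to keep all levels of that factor.
#' @return list of [individual_record()]s.
#' @export
cell_records <- function(table, clone = NULL, concentration = NULL,
                         parasite_level = NULL) {
  stopifnot(inherits(table, "experiment_table"))
  keep <- rep(TRUE, length(table$records))
  u <- table$units
  if (!is.null(clone)) keep <- keep & u$clone == clone
  if (!is.null(concentration)) keep <- keep & u$concentration == concentration
  if (!is.null(parasite_level)) keep <- keep & u$parasite_level == parasite_level
  table$records[keep]
}
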