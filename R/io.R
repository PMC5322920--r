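#' Write an experiment table as tidy daily CSV
#'
#' One row per individual per day with columns `clone, contaminant,
#' concentration_ugL, parasite_level, replicate, day, alive, offspring,
#' infected`. Days with no brood are written with an explicit zero, never
#' omitted. `alive` is 1 on days the individual survived through (days
#' strictly before its death day); a censored individual is alive on every
#' day. `infected` is 0/1 repeated on every row of the individual, `NA` for
#' unchallenged individuals. Optional `header_comments` are written as
#' leading `#` lines (used by the simulator to echo its configuration).
#'
#' @param table an [experiment_table()].
#' @param path output file path.
#' @param header_comments optional character vector of provenance lines.
#' @return `path`, invisibly.
#' @export
write_records <- function(table, path, header_comments = NULL) {
  stopifnot(inherits(table, "experiment_table"))
  dur <- table$design$duration_days
  rows <- lapply(table$records, function(r) {
    day <- seq_len(dur)
    data.frame(clone = r$clone,
               contaminant = table$design$contaminant,
               concentration_ugL = r$concentration,
               parasite_level = r$parasite_level,
               replicate = r$replicate,
               day = day,
               alive = as.integer(day < r$death_day),
               offspring = r$offspring,
               infected = as.integer(r$infected),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header_comments))
    writeLines(paste0("# ", header_comments), con)
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

csv_columns <- c("clone", "contaminant", "concentration_ugL", "parasite_level",
                 "replicate", "day", "alive", "offspring", "infected")

#' Read and validate a tidy daily record CSV
#'
#' Reads the dialect written by [write_records()], validates it against the
#' design (every unit present exactly once with a complete day sequence, no
#' resurrection, no offspring after death, infection status constant per
#' individual and only in challenged treatments) and returns a validated
#' [experiment_table()]. Leading `#` comment lines are skipped; unknown
#' columns are ignored with a warning. Validation errors name the offending
#' experimental unit.
#'
#' @param path CSV file path.
#' @param design the [design_spec()] the file is expected to realise.
#' @return An [experiment_table()].
#' @export
read_records <- function(path, design) {
  stopifnot(inherits(design, "design_spec"))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(csv_columns, names(df))
  if (length(missing_cols))
    stop("malformed record file: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), csv_columns)
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
    df <- df[csv_columns]
  }
  bad_cont <- unique(df$contaminant[df$contaminant != design$contaminant])
  if (length(bad_cont))
    stop("contaminant mismatch: file has ", paste(bad_cont, collapse = ", "),
         ", design expects ", design$contaminant, call. = FALSE)
  dur <- design$duration_days
  df$clone <- as.character(df$clone)
  df$parasite_level <- as.character(df$parasite_level)
  key <- unit_key(df$clone, df$concentration_ugL, df$parasite_level,
                  df$replicate)
  records <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    g <- df[idx, ]
    k <- key[idx[1]]
    g <- g[order(g$day), ]
    if (any(is.na(g$day)) || !identical(as.integer(g$day), seq_len(dur)))
      stop("unit ", k, ": day column must be exactly 1..", dur,
           " with no gaps or duplicates", call. = FALSE)
    if (any(is.na(g$alive)) || any(!g$alive %in% c(0L, 1L)))
      stop("unit ", k, ": alive must be 0/1", call. = FALSE)
    if (any(diff(g$alive) > 0L))
      stop("unit ", k, ": alive may not increase over time", call. = FALSE)
    if (any(is.na(g$offspring)) || any(g$offspring < 0))
      stop("unit ", k, ": offspring must be non-negative counts", call. = FALSE)
    death_day <- if (all(g$alive == 1L)) dur + 1L else which(g$alive == 0L)[1]
    late <- g$day[g$offspring > 0 & g$day > death_day]
    if (length(late))
      stop("unit ", k, ": offspring recorded on day ", late[1],
           " after death on day ", death_day, call. = FALSE)
    infected <- unique(g$infected)
    if (length(infected) != 1L)
      stop("unit ", k, ": infection status must be constant per individual",
           call. = FALSE)
    infected <- if (is.na(infected)) NA else as.logical(infected)
    lv <- g$parasite_level[1]
    if (!lv %in% design$parasite_levels)
      stop("unit ", k, ": unknown parasite level ", lv, call. = FALSE)
    individual_record(
      clone = g$clone[1], concentration = g$concentration_ugL[1],
      parasite_level = lv, replicate = g$replicate[1],
      death_day = death_day, offspring = g$offspring,
      infected = infected,
      challenge_days = design$challenge_days[[lv]], duration = dur)
  })
  experiment_table(design, unname(records))
}

#' Write an endpoint table to CSV files
#'
#' Emits the per-individual endpoints and the per-cell proportion summary as
#' two CSV files (`<stem>_individuals.csv`, `<stem>_cells.csv`).
#'
#' @param endpoints an [endpoint_table()].
#' @param stem file path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_endpoints <- function(endpoints, stem) {
  stopifnot(inherits(endpoints, "endpoint_table"))
  p1 <- paste0(stem, "_individuals.csv")
  p2 <- paste0(stem, "_cells.csv")
  utils::write.csv(endpoints$individuals, p1, row.names = FALSE)
  utils::write.csv(endpoints$cells, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' Write an ANOVA summary to CSV
#'
#' Columns mirror the conventional factorial summary table: endpoint, source,
#' F, df1, df2, P and a significance flag at the Dunn-Sidak adjusted level.
#'
#' @param fit a [fit_lifetable()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_anova <- function(fit, path) {
  stopifnot(inherits(fit, "lifetable_fit"))
  utils::write.csv(as.data.frame(fit), path, row.names = FALSE)
  invisible(path)
}
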