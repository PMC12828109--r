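## Delimited-text input of patient tables and report output for a
## monitoring run.

#' Read a patient table from delimited text
#'
#' Expects a header with columns `patient_id`, `entry_day`, `duration_days`,
#' `event` (0/1 or true/false); comma- or tab-separated (detected from the
#' header line).  Rows failing validation are reported together with their
#' line numbers.  Duplicate entry days are accepted: they are split by the
#' monitor's tie-breaking jitter, with a warning listing the duplicates.
#'
#' @param path Path to the file.
#' @param tie_seed Seed for the tie-breaking jitter.
#' @return A data frame with columns `patient_id`, `entry_day`,
#'   `duration_days`, `event` (logical), sorted by entry day.
#' @export
read_patient_table <- function(path, tie_seed = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("patient_id", "entry_day", "duration_days", "event")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop(sprintf("missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)

  entry <- suppressWarnings(as.numeric(tab$entry_day))
  dur <- suppressWarnings(as.numeric(tab$duration_days))
  ev_raw <- tolower(trimws(as.character(tab$event)))
  ev <- ifelse(ev_raw %in% c("1", "true", "t", "yes"), TRUE,
               ifelse(ev_raw %in% c("0", "false", "f", "no"), FALSE, NA))

  # +1 for the header line
  bad <- character()
  flag <- function(cond, what) {
    rows <- which(cond)
    if (length(rows))
      bad <<- c(bad, sprintf("line %d: %s", rows + 1L, what))
  }
  flag(is.na(entry), "entry_day is not numeric")
  flag(!is.na(entry) & entry < 0, "entry_day is negative")
  flag(is.na(dur), "duration_days is not numeric")
  flag(!is.na(dur) & dur <= 0, "duration_days must be > 0")
  flag(is.na(ev), "event is not interpretable as a 0/1 flag")
  if (length(bad))
    stop(paste(c("invalid patient table:", bad), collapse = "\n  "),
         call. = FALSE)

  if (anyDuplicated(entry)) {
    dups <- unique(entry[duplicated(entry)])
    warning(sprintf(
      "tied entry days (%s) split by jitter < 1e-6 days",
      paste(utils::head(dups, 5L), collapse = ", ")), call. = FALSE)
    entry <- .break_entry_ties(entry, tie_seed)
  }
  out <- data.frame(patient_id = tab$patient_id, entry_day = entry,
                    duration_days = dur, event = ev)
  out[order(out$entry_day), , drop = FALSE]
}

#' Write the trajectory table and decision report of a monitoring run
#'
#' Writes `<stem>_trajectory.tsv` (columns `calendar_day`, `n`, `K`, `Ttot`,
#' `Lambda`) and `<stem>_decision.json` (decision, stopping day, patients and
#' events at stopping, thresholds).  Optionally renders the monitoring chart
#' to `<stem>_chart.png`.
#'
#' @param trajectory A `serm_trajectory` from [run_monitor()] (run with
#'   `keep_path = TRUE`).
#' @param stem Output path stem (directories must exist).
#' @param chart If `TRUE`, also write the chart image.
#' @param force Overwrite existing files; default `FALSE`.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(trajectory, stem, chart = FALSE, force = FALSE) {
  stopifnot(inherits(trajectory, "serm_trajectory"))
  if (is.null(trajectory$path) || nrow(trajectory$path) == 0L)
    stop("trajectory has no evaluations to report", call. = FALSE)
  paths <- c(trajectory = paste0(stem, "_trajectory.tsv"),
             decision = paste0(stem, "_decision.json"))
  if (chart) paths <- c(paths, chart = paste0(stem, "_chart.png"))
  if (!force) {
    clash <- paths[file.exists(paths)]
    if (length(clash))
      stop(sprintf("output exists (use force = TRUE): %s",
                   paste(clash, collapse = ", ")), call. = FALSE)
  }
  tab <- trajectory$path
  # full double precision so that a re-read reproduces the statistic
  tab$Ttot <- format(tab$Ttot, digits = 17, trim = TRUE, scientific = FALSE)
  tab$Lambda <- format(tab$Lambda, digits = 17, trim = TRUE,
                       scientific = FALSE)
  utils::write.table(tab, paths[["trajectory"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(
    decision = trajectory$decision,
    stopping_day = trajectory$stopping_day,
    n_at_stop = trajectory$n_at_stop,
    events_at_stop = trajectory$events_at_stop,
    boundaries = list(a = trajectory$boundaries$a, b = trajectory$boundaries$b,
                      gamma0 = trajectory$boundaries$gamma0,
                      gamma1 = trajectory$boundaries$gamma1,
                      alpha = trajectory$boundaries$alpha,
                      beta = trajectory$boundaries$beta),
    interpretation = switch(
      trajectory$decision,
      accept_H0_lower = paste(
        "Lower threshold crossed: the pooled event rate is consistent with",
        "the planned rate; the study is on track for its planned number of",
        "primary events."),
      accept_H1_upper = paste(
        "Upper threshold crossed: the study may not accumulate a sufficient",
        "number of primary events by the end of follow-up; further",
        "investigation and possibly corrective action are warranted."),
      paste("No threshold crossed by the end of study; monitoring is",
            "inconclusive.")))
  jsonlite::write_json(report, paths[["decision"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (chart) {
    grDevices::png(paths[["chart"]], width = 900, height = 500)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(trajectory, main = "Sequential event-rate monitoring chart")
  }
  invisible(paths)
}
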