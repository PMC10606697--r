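## Config serialization (JSON), event-log (JSONL) and summary (CSV) writers.

cal_to_list <- function(cal) {
  if (identical(cal$routine_rate_spec, "custom"))
    stop("a custom routine-rate function cannot be serialized; ",
         "use a constant rate or the default")
  list(
    service = lapply(cal$service, function(d)
      list(family = d$family, mean = d$mean, cv = d$cv)),
    health = unclass(cal$health),
    probabilities = list(
      p_surgery_red = cal$p_surgery_red,
      p_surgery_yellow = cal$p_surgery_yellow,
      p_ct_red = cal$p_ct_red, p_xray_red = cal$p_xray_red,
      p_ct_yellow = cal$p_ct_yellow, p_xray_yellow = cal$p_xray_yellow,
      p_ct_downgrade_eligible = cal$p_ct_downgrade_eligible),
    staffing = cal$staffing,
    routine_rate = cal$routine_rate_spec,
    green_per_nurse = cal$green_per_nurse,
    green_per_rotation_physician = cal$green_per_rotation_physician)
}

cal_from_list <- function(x) {
  calibration(
    service = lapply(x$service, function(d)
      service_dist(d$family, d$mean, d$cv)),
    health = do.call(health_dynamics, x$health),
    p_surgery_red = x$probabilities$p_surgery_red,
    p_surgery_yellow = x$probabilities$p_surgery_yellow,
    p_ct_red = x$probabilities$p_ct_red,
    p_xray_red = x$probabilities$p_xray_red,
    p_ct_yellow = x$probabilities$p_ct_yellow,
    p_xray_yellow = x$probabilities$p_xray_yellow,
    p_ct_downgrade_eligible = x$probabilities$p_ct_downgrade_eligible,
    staffing = lapply(x$staffing, function(groups)
      lapply(groups, function(g) staff_group(unlist(g$cats), g$n))),
    routine_rate_per_min = if (identical(x$routine_rate, "default"))
      default_routine_rate else as.numeric(x$routine_rate),
    green_per_nurse = x$green_per_nurse,
    green_per_rotation_physician = x$green_per_rotation_physician)
}

#' Write and read scenario configurations as JSON
#'
#' The JSON schema holds the label, the seven staff counts, the casualty
#' load, the resource counts, the full calibration (service distributions,
#' health dynamics, probabilities, staffing matrices, routine-load rate),
#' the master seed and the replication count. All times are minutes;
#' time-of-day is minutes since midnight. `read_config(write_config(x))`
#' reproduces an equal configuration.
#'
#' @param config An [scenario_config()].
#' @param path File path.
#' @return `read_config` returns an `mci_scenario`; `write_config` its path,
#'   invisibly.
#' @export
write_config <- function(config, path) {
  x <- list(label = config$label,
            staff = as.list(unclass(config$staff)),
            load = unclass(config$load),
            resources = unclass(config$resources),
            calibration = cal_to_list(config$calibration),
            seed = config$seed, replications = config$replications)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  for (nm in c("label", "staff", "load", "resources", "calibration"))
    if (is.null(x[[nm]])) stop("config is missing required field: ", nm)
  res <- x$resources
  res$dining_hall_capacity <-
    if (is.null(res$dining_hall_capacity)) Inf
    else as.numeric(res$dining_hall_capacity)   # "Inf" round-trips as a string
  scenario_config(
    label = x$label,
    staff = do.call(staff_vector, as.list(x$staff)),
    load = do.call(patient_load, as.list(x$load)),
    resources = do.call(resource_set, as.list(res)),
    calibration = cal_from_list(x$calibration),
    seed = x$seed %||% 1L,
    replications = x$replications %||% 100L)
}

#' Write a replication's event log as JSONL
#'
#' One JSON object per line with fields time, patient, event (one of arrive,
#' queue, seize, release, retriage, death, exit) and detail (station or
#' category).
#'
#' @param replication An `mci_replication` run with `log_events = TRUE`.
#' @param path File path.
#' @export
write_event_log <- function(replication, path) {
  ev <- replication$events
  if (is.null(ev)) stop("replication was run without log_events = TRUE")
  lines <- vapply(seq_len(nrow(ev)), function(i)
    as.character(jsonlite::toJSON(as.list(ev[i, ]), auto_unbox = TRUE,
                                  digits = NA)), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write scenario summaries as CSV
#'
#' One row per metric with the six summary statistics (mean, sd, median,
#' min, max, range) and the applicable benchmark, mirroring the layout of
#' the published waiting-time tables.
#'
#' @param sim An `mci_simulation` (or `mci_sweep` data frame, written as-is).
#' @param path File path.
#' @export
write_summary_csv <- function(sim, path) {
  if (inherits(sim, "mci_sweep")) {
    utils::write.csv(as.data.frame(sim), path, row.names = FALSE)
    return(invisible(path))
  }
  s <- sim$summary
  bm <- sim$benchmarks
  lim <- c(red_critical_wait = bm$red_surgery_limit,
           yellow_critical_wait = bm$yellow_surgery_limit,
           red_total_system_time = bm$red_total_system_limit)
  out <- data.frame(metric = rownames(s), as.data.frame(s),
                    benchmark = unname(lim[rownames(s)]),
                    row.names = NULL)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
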