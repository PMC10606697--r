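#' Staff categories modeled by the simulator
#'
#' The seven on-shift staff categories of the trauma pathway, in canonical
#' order: medical specialists, medical assistants, rotation physicians,
#' general nurses, surgical assistants, surgical nurses, radiology assistants.
#'
#' @return Character vector of the seven category names.
#' @export
staff_categories <- function() {
  c("medical_specialists", "medical_assistants", "rotation_physicians",
    "general_nurses", "surgical_assistants", "surgical_nurses",
    "radiology_assistants")
}

#' Construct an on-shift staff vector
#'
#' @param medical_specialists,medical_assistants,rotation_physicians,general_nurses,surgical_assistants,surgical_nurses,radiology_assistants
#'   Non-negative integer headcounts on shift.
#' @return Named integer vector of class `mci_staff` with the seven
#'   categories in canonical order.
#' @examples
#' staff_vector(17, 5, 3, 20, 1, 4, 2)  # the disaster-plan night shift
#' @export
staff_vector <- function(medical_specialists, medical_assistants,
                         rotation_physicians, general_nurses,
                         surgical_assistants, surgical_nurses,
                         radiology_assistants) {
  x <- c(medical_specialists, medical_assistants, rotation_physicians,
         general_nurses, surgical_assistants, surgical_nurses,
         radiology_assistants)
  if (length(x) != 7L || anyNA(x)) stop("staff vector needs 7 non-missing counts")
  if (any(x < 0) || any(x != round(x))) stop("staff counts must be non-negative integers")
  x <- as.integer(round(x))
  names(x) <- staff_categories()
  class(x) <- "mci_staff"
  x
}

#' @export
print.mci_staff <- function(x, ...) {
  cat("Staff on shift (total ", sum(x), "):\n", sep = "")
  print(unclass(x))
  invisible(x)
}

as_staff <- function(x) {
  if (inherits(x, "mci_staff")) return(x)
  do.call(staff_vector, as.list(as.numeric(x)))
}

#' Construct a patient load
#'
#' The casualty load of one incident: counts per initial triage category and
#' the time span over which they arrive.
#'
#' @param n_red,n_yellow,n_green Non-negative integer numbers of severely
#'   (red), moderately (yellow) and slightly (green) injured patients.
#' @param arrival_window_min Positive expected arrival span in minutes;
#'   inter-arrival times within each category are exponential with mean
#'   `arrival_window_min / n`.
#' @param incident_time_of_day Incident time in minutes since midnight
#'   (default 1320 = 10 p.m.).
#' @return A list of class `mci_load`.
#' @export
patient_load <- function(n_red, n_yellow, n_green,
                         arrival_window_min = 90,
                         incident_time_of_day = 1320) {
  n <- c(n_red, n_yellow, n_green)
  if (anyNA(n) || any(n < 0) || any(n != round(n)))
    stop("patient counts must be non-negative integers")
  if (!is.finite(arrival_window_min) || arrival_window_min <= 0)
    stop("arrival_window_min must be positive")
  structure(list(n_red = as.integer(n_red), n_yellow = as.integer(n_yellow),
                 n_green = as.integer(n_green),
                 arrival_window_min = as.numeric(arrival_window_min),
                 incident_time_of_day = as.numeric(incident_time_of_day)),
            class = "mci_load")
}

#' @export
print.mci_load <- function(x, ...) {
  cat(sprintf("Casualty load: %d red / %d yellow / %d green over %g min (incident at %02d:%02d)\n",
              x$n_red, x$n_yellow, x$n_green, x$arrival_window_min,
              x$incident_time_of_day %/% 60, round(x$incident_time_of_day %% 60)))
  invisible(x)
}

#' Scale a patient load by a common factor
#'
#' Multiplies each category count by `factor` and rounds half-up, leaving the
#' arrival window unchanged. Explicit per-category overrides take precedence,
#' which allows reproducing published sweep rows whose rounding differs.
#'
#' @param load An [patient_load()] object.
#' @param factor Positive scaling factor.
#' @param n_red,n_yellow,n_green Optional integer overrides applied after
#'   scaling.
#' @return A new `mci_load`.
#' @examples
#' scale_load(patient_load(5, 20, 50), 0.4)  # 2 / 8 / 20
#' @export
scale_load <- function(load, factor, n_red = NULL, n_yellow = NULL, n_green = NULL) {
  stopifnot(inherits(load, "mci_load"))
  if (!is.finite(factor) || factor <= 0) stop("factor must be positive")
  half_up <- function(x) floor(x + 0.5)
  patient_load(
    n_red    = if (is.null(n_red))    half_up(load$n_red * factor)    else n_red,
    n_yellow = if (is.null(n_yellow)) half_up(load$n_yellow * factor) else n_yellow,
    n_green  = if (is.null(n_green))  half_up(load$n_green * factor)  else n_green,
    arrival_window_min = load$arrival_window_min,
    incident_time_of_day = load$incident_time_of_day
  )
}

#' Construct the hospital resource set
#'
#' Rooms and machines of the trauma pathway. The defaults mirror an acute
#' specialty hospital: two trauma operating rooms, four usable central
#' operating rooms, one certified plus one improvised resuscitation bay, one
#' CT machine, two X-ray rooms, and four treatment slots for moderately
#' injured patients (acute outpatient department plus cast room). The dining
#' hall gathering slightly injured patients is unbounded.
#'
#' @param n_trauma_or,n_central_or_usable,n_resus_bays,n_ct,n_xray,n_yellow_treatment_slots
#'   Non-negative integer counts.
#' @param dining_hall_capacity Capacity sentinel; `Inf` means unbounded.
#' @return A list of class `mci_resources`.
#' @export
resource_set <- function(n_trauma_or = 2, n_central_or_usable = 4,
                         n_resus_bays = 2, n_ct = 1, n_xray = 2,
                         n_yellow_treatment_slots = 4,
                         dining_hall_capacity = Inf) {
  cnt <- c(n_trauma_or, n_central_or_usable, n_resus_bays, n_ct, n_xray,
           n_yellow_treatment_slots)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("resource counts must be non-negative integers")
  structure(list(n_trauma_or = as.integer(n_trauma_or),
                 n_central_or_usable = as.integer(n_central_or_usable),
                 n_resus_bays = as.integer(n_resus_bays),
                 n_ct = as.integer(n_ct), n_xray = as.integer(n_xray),
                 n_yellow_treatment_slots = as.integer(n_yellow_treatment_slots),
                 dining_hall_capacity = dining_hall_capacity),
            class = "mci_resources")
}

#' Waiting-time benchmarks
#'
#' Medical waiting-time limits used as compliance benchmarks: arrival-to-surgery
#' for severely injured patients (120 min, bleeding-death window), for
#' moderately injured patients (720 min, time-critical fracture care), and the
#' mean total-system-time constraint for severely injured patients used in
#' staff-mix optimization (200 min).
#'
#' @param red_surgery_limit,yellow_surgery_limit,red_total_system_limit
#'   Positive limits in minutes.
#' @return A list of class `mci_benchmarks`.
#' @export
benchmarks <- function(red_surgery_limit = 120, yellow_surgery_limit = 720,
                       red_total_system_limit = 200) {
  if (any(c(red_surgery_limit, yellow_surgery_limit, red_total_system_limit) <= 0))
    stop("benchmarks must be positive")
  if (red_surgery_limit >= yellow_surgery_limit)
    stop("red limit must be below yellow limit")
  structure(list(red_surgery_limit = red_surgery_limit,
                 yellow_surgery_limit = yellow_surgery_limit,
                 red_total_system_limit = red_total_system_limit),
            class = "mci_benchmarks")
}

#' Assemble a scenario configuration
#'
#' Bundles everything that defines one policy scenario: label, staff on shift,
#' casualty load, rooms/machines, service-time and health-dynamics
#' calibration, master seed and replication policy.
#'
#' @param label Scenario label.
#' @param staff An [staff_vector()].
#' @param load An [patient_load()].
#' @param resources An [resource_set()].
#' @param calibration An [calibration()] object (defaults to the shipped one).
#' @param seed Master seed; fixes the layout of every random substream.
#' @param replications Default replication count for fixed-replication runs.
#' @return A list of class `mci_scenario`.
#' @export
scenario_config <- function(label, staff, load, resources = resource_set(),
                            calibration = default_calibration(),
                            seed = 1L, replications = 100L) {
  sc <- structure(list(label = as.character(label), staff = as_staff(staff),
                       load = load, resources = resources,
                       calibration = calibration,
                       seed = as.integer(seed),
                       replications = as.integer(replications)),
                  class = "mci_scenario")
  v <- validate_config(sc)
  if (length(v)) stop("invalid scenario: ", paste(v, collapse = "; "))
  sc
}

#' @export
print.mci_scenario <- function(x, ...) {
  cat("MCI scenario:", x$label, "\n")
  print(x$load)
  print(x$staff)
  cat(sprintf("Rooms: %d trauma OR + %d central OR, %d resus bays, %d CT, %d X-ray, %d yellow slots\n",
              x$resources$n_trauma_or, x$resources$n_central_or_usable,
              x$resources$n_resus_bays, x$resources$n_ct, x$resources$n_xray,
              x$resources$n_yellow_treatment_slots))
  invisible(x)
}

#' Validate a scenario configuration
#'
#' Checks every type invariant and the structural feasibility of the staffing
#' (each task of the calibration's staffing matrices must be satisfiable by
#' the configured staff for the patient categories actually present).
#'
#' @param config An `mci_scenario` (or an untrusted list with the same shape).
#' @return Character vector of violations; empty when the scenario is valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(...) v <<- c(v, sprintf(...))
  st <- config$staff; ld <- config$load; rs <- config$resources
  for (nm in staff_categories())
    if (is.null(st[[nm]]) || is.na(st[[nm]]) || st[[nm]] < 0)
      say("staff category %s must be a non-negative count", nm)
  for (nm in c("n_red", "n_yellow", "n_green"))
    if (is.null(ld[[nm]]) || is.na(ld[[nm]]) || ld[[nm]] < 0)
      say("patient count %s must be non-negative", nm)
  if (is.null(ld$arrival_window_min) || !is.finite(ld$arrival_window_min) ||
      ld$arrival_window_min <= 0)
    say("arrival_window_min must be positive")
  for (nm in c("n_trauma_or", "n_central_or_usable", "n_resus_bays", "n_ct",
               "n_xray", "n_yellow_treatment_slots"))
    if (is.null(rs[[nm]]) || is.na(rs[[nm]]) || rs[[nm]] < 0)
      say("resource %s must be non-negative", nm)
  if (!is.null(ld$n_red) && !is.null(rs$n_resus_bays) &&
      isTRUE(ld$n_red > 0) && isTRUE(rs$n_resus_bays < 1))
    say("n_resus_bays must be >= 1 when severely injured patients arrive")
  cal <- config$calibration
  if (!is.null(cal)) {
    v <- c(v, validate_calibration(cal))
    # structural staffing feasibility for the categories present
    if (length(v) == 0) {
      need <- list()
      if (isTRUE(ld$n_red > 0))
        need <- c(need, cal$staffing[c("triage", "red_stabilization",
                                       "imaging", "red_surgery")])
      if (isTRUE(ld$n_yellow > 0))
        need <- c(need, cal$staffing[c("triage", "yellow_exam", "imaging",
                                       "yellow_surgery")])
      if (isTRUE(ld$n_green > 0))
        need <- c(need, cal$staffing["triage"])
      for (task in names(need)) {
        for (grp in need[[task]]) {
          have <- sum(unlist(st[grp$cats]))
          if (have < grp$n)
            say("task %s needs %d of {%s} but only %d configured",
                task, grp$n, paste(grp$cats, collapse = "|"), have)
        }
      }
    }
  }
  unique(v)
}

#' Canonical baseline scenario of the hospital disaster plan
#'
#' Scenario #1: the current disaster plan of the modeled acute specialty
#' hospital — 5 severely, 20 moderately and 50 slightly injured patients
#' arriving over 90 minutes at 10 p.m., handled by the night shift of
#' 17 medical specialists, 5 medical assistants, 3 rotation physicians,
#' 20 general nurses, 1 surgical assistant, 4 surgical nurses and
#' 2 radiology assistants.
#'
#' @param seed Master seed.
#' @param replications Default replication count.
#' @return An `mci_scenario`.
#' @export
make_disaster_plan_baseline <- function(seed = 1L, replications = 100L) {
  scenario_config(
    label = "disaster-plan baseline",
    staff = staff_vector(17, 5, 3, 20, 1, 4, 2),
    load = patient_load(5, 20, 50, arrival_window_min = 90,
                        incident_time_of_day = 1320),
    seed = seed, replications = replications
  )
}

#' Baseline scenario of the staff-mix optimization study
#'
#' Scenario #2 of the optimization study: the same casualty load as the
#' disaster-plan baseline with the staff mix (11, 5, 6, 23, 2, 5, 2).
#'
#' @inheritParams make_disaster_plan_baseline
#' @return An `mci_scenario`.
#' @export
make_optimization_baseline <- function(seed = 1L, replications = 100L) {
  scenario_config(
    label = "optimization baseline",
    staff = staff_vector(11, 5, 6, 23, 2, 5, 2),
    load = patient_load(5, 20, 50, arrival_window_min = 90,
                        incident_time_of_day = 1320),
    seed = seed, replications = replications
  )
}

#' Staff-mix factor grid of the optimization study
#'
#' Three ordered levels per staff category, from the minimum shift (8, 3, 4,
#' 15, 1, 4, 1) to the maximum shift (12, 7, 8, 25, 3, 8, 3); the full
#' cartesian product enumerates 3^7 = 2187 staffing scenarios.
#'
#' @return Named list of ordered integer level vectors (a factor grid).
#' @export
staff_grid_levels <- function() {
  list(medical_specialists = c(8L, 10L, 12L),
       medical_assistants  = c(3L, 5L, 7L),
       rotation_physicians = c(4L, 6L, 8L),
       general_nurses      = c(15L, 20L, 25L),
       surgical_assistants = c(1L, 2L, 3L),
       surgical_nurses     = c(4L, 6L, 8L),
       radiology_assistants = c(1L, 2L, 3L))
}

#' Published casualty-load sweep rows
#'
#' The load-sensitivity rows as printed in the study design this simulator
#' reproduces: scenarios scaling the baseline (5, 20, 50) from -60% to +40%.
#' The +40% row is shipped verbatim as (7, 29, 72) — it is not a uniform
#' rounding of the baseline — via per-category overrides.
#'
#' @param base Baseline [patient_load()].
#' @return Named list of `mci_load` objects in increasing severity order.
#' @export
table_load_sweep <- function(base = patient_load(5, 20, 50)) {
  list("-60%" = scale_load(base, 0.4),
       "-40%" = scale_load(base, 0.6),
       "-20%" = scale_load(base, 0.8),
       "baseline" = scale_load(base, 1.0),
       "+20%" = scale_load(base, 1.2),
       "+40%" = scale_load(base, 1.4, n_red = 7, n_yellow = 29, n_green = 72))
}
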