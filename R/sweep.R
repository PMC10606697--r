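## Sensitivity sweeps and full-factorial enumeration with common random
## numbers, plus the trend-line fits of the one-way analyses.

#' Full-factorial staff grid
#'
#' Cartesian product of per-category level lists in a documented order: the
#' first category varies slowest and the last fastest, so scenario #1 takes
#' every category's first (minimum) level and the last scenario every
#' category's last (maximum) level. Indices are 1-based and stable.
#'
#' @param levels Named list of ordered level vectors (default:
#'   [staff_grid_levels()], the 3^7 = 2187-scenario staff grid).
#' @return Data frame with one row per scenario, a `scenario` index column
#'   and one column per category.
#' @export
factorial_grid <- function(levels = staff_grid_levels()) {
  if (!length(levels) || any(!vapply(levels, length, 1L)))
    stop("every category needs at least one level")
  # expand.grid varies the FIRST factor fastest; feed reversed names
  g <- expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE)
  g <- g[, rev(seq_along(levels)), drop = FALSE]
  data.frame(scenario = seq_len(nrow(g)), g, row.names = NULL)
}

#' Map a grid row index to its level combination and back
#'
#' Mixed-radix bijection between the 1-based scenario index and the level
#' choices (1-based level index per category, first category slowest-varying).
#'
#' @param index Scenario index.
#' @param levels Named list of ordered level vectors.
#' @return `grid_point()`: integer vector of level positions;
#'   `grid_index()`: the scenario index of a position vector.
#' @export
grid_point <- function(index, levels = staff_grid_levels()) {
  k <- vapply(levels, length, 1L)
  if (index < 1 || index > prod(k)) stop("index out of range")
  pos <- integer(length(k))
  rem <- index - 1L
  for (j in rev(seq_along(k))) {
    pos[j] <- rem %% k[j] + 1L
    rem <- rem %/% k[j]
  }
  names(pos) <- names(levels)
  pos
}

#' @rdname grid_point
#' @param pos Integer vector of level positions (1-based, one per category).
#' @export
grid_index <- function(pos, levels = staff_grid_levels()) {
  k <- vapply(levels, length, 1L)
  if (any(pos < 1 | pos > k)) stop("position out of range")
  idx <- 0L
  for (j in seq_along(k)) idx <- idx * k[j] + (pos[j] - 1L)
  unname(idx + 1L)
}

# apply a named axis value to a scenario (parameter paths understood by sweeps)
apply_axis <- function(scenario, path, value) {
  sc <- scenario
  if (path %in% staff_categories()) {
    st <- unclass(sc$staff); st[path] <- value
    sc$staff <- do.call(staff_vector, as.list(st))
  } else if (path == "arrival_window_min") {
    sc$load$arrival_window_min <- value
  } else if (path == "load_factor") {
    sc$load <- scale_load(sc$load, value)
  } else if (path == "load") {
    stopifnot(inherits(value, "mci_load"))
    sc$load <- value
  } else if (path %in% c("n_red", "n_yellow", "n_green")) {
    sc$load[[path]] <- as.integer(value)
  } else if (path %in% c("n_trauma_or", "n_central_or_usable", "n_resus_bays",
                         "n_ct", "n_xray", "n_yellow_treatment_slots")) {
    sc$resources[[path]] <- as.integer(value)
  } else stop("unknown axis parameter: ", path)
  sc$label <- paste0(scenario$label, " [", path, "=",
                     if (inherits(value, "mci_load"))
                       paste(value$n_red, value$n_yellow, value$n_green,
                             sep = "/")
                     else value, "]")
  sc
}

#' One-way sensitivity sweep
#'
#' Evaluates a base scenario along one ordered axis of parameter values.
#' With common random numbers (the default) every scenario is run with the
#' same replication seeds, so metric differences along the axis reflect the
#' policy change rather than sampling noise.
#'
#' @param base Base [scenario_config()].
#' @param axis Name of the swept parameter: a staff category,
#'   `"arrival_window_min"`, `"load_factor"`, `"load"` (values are
#'   `mci_load` objects), a patient count, or a resource count.
#' @param values Ordered vector (or list, for `"load"`) of axis values.
#' @param replications Replications per scenario.
#' @param seed Base seed; shared across scenarios when `crn = TRUE`.
#' @param crn Couple scenarios by common random numbers.
#' @param bm An [benchmarks()] object.
#' @return Data frame of class `mci_sweep`: one row per scenario x metric
#'   with the six summary statistics.
#' @export
run_sweep <- function(base, axis, values, replications = base$replications,
                      seed = base$seed, crn = TRUE, bm = benchmarks()) {
  rows <- list()
  for (v in seq_along(values)) {
    val <- if (is.list(values) && !inherits(values, "mci_load"))
      values[[v]] else values[v]
    sc <- apply_axis(base, axis, val)
    sc_seed <- if (crn) seed else seed + (v - 1L) * (replications + 1L)
    sim <- run_scenario(sc, replications = replications, seed = sc_seed,
                        bm = bm)
    s <- sim$summary
    for (m in rownames(s)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = v, axis = axis,
        value = if (inherits(val, "mci_load"))
          paste(val$n_red, val$n_yellow, val$n_green, sep = "/")
        else as.character(val),
        metric = m, mean = s[m, "mean"], sd = s[m, "sd"],
        median = s[m, "median"], min = s[m, "min"], max = s[m, "max"],
        range = s[m, "range"], replications = replications,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("mci_sweep", "data.frame")
  out
}

#' Ordinary least-squares trend line
#'
#' Fits the one-way trend reported alongside the sensitivity analyses, e.g.
#' the marginal increase in waiting time per additional severely injured
#' patient.
#'
#' @param xs,ys Numeric vectors (at least two distinct x values).
#' @return List with `slope`, `intercept` and `r_squared`.
#' @export
fit_trend <- function(xs, ys) {
  if (length(unique(xs)) < 2) stop("need at least two distinct x values")
  fit <- stats::lm(ys ~ xs)
  co <- stats::coef(fit)
  r2 <- withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })$r.squared
  list(slope = unname(co[2]), intercept = unname(co[1]), r_squared = r2)
}
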