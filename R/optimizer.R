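## Constrained simulation-optimization over the integer staff lattice:
## minimize total headcount subject to the mean red total-system-time
## constraint, with an exhaustive-enumeration oracle.

# default DES evaluator: mean red total system time with a t-based CI
des_evaluator <- function(scenario, replications, seed, bm = benchmarks()) {
  force(scenario); force(replications); force(seed); force(bm)
  function(staff, reps = replications) {
    sc <- scenario
    st <- unclass(sc$staff)
    if (is.null(names(staff))) st[] <- staff
    else st[names(staff)] <- staff  # points may cover a subset of categories
    sc$staff <- as_staff(st)
    sim <- run_scenario(sc, replications = reps, seed = seed, bm = bm)
    v <- sim$metrics$red_total_system_time
    v <- v[!is.na(v)]
    m <- mean(v)
    hw <- if (length(v) > 1)
      stats::qt(0.975, length(v) - 1) * stats::sd(v) / sqrt(length(v)) else Inf
    list(estimate = m, halfwidth = hw, replications = length(v))
  }
}

#' Evaluate one staff point of a scenario
#'
#' Mean red total system time of the scenario run with the given staff
#' vector, with a t-based 95% confidence interval. Scenarios evaluated with
#' the same `seed` share random substreams (common random numbers).
#'
#' @param staff A staff vector (or 7 counts).
#' @param scenario Base [scenario_config()]; its staff is replaced.
#' @param replications Fixed replication count.
#' @param seed Base seed.
#' @return List with `estimate`, `halfwidth`, `replications`.
#' @export
evaluate_point <- function(staff, scenario, replications = 50, seed = scenario$seed) {
  des_evaluator(scenario, replications, seed)(staff)
}

#' Enumerate and rank a staff search space
#'
#' Evaluates every lattice point and ranks the feasible ones (estimate below
#' the constraint limit) by total headcount, breaking ties by the smaller
#' estimate. Deterministic given the seed.
#'
#' @param space Named list of ordered level vectors (a factor grid).
#' @param scenario Base scenario.
#' @param replications Replications per point.
#' @param seed Base seed (shared: common random numbers across points).
#' @param limit Constraint on mean red total system time (minutes).
#' @param evaluate Optional custom evaluator `function(staff, reps)`
#'   returning `list(estimate, halfwidth)`; defaults to the simulator.
#' @return Data frame of class `mci_ranking`, ordered with feasible points
#'   first (by headcount then estimate), with one row per lattice point.
#' @export
enumerate_rank <- function(space, scenario, replications = 20,
                           seed = scenario$seed, limit = 200,
                           evaluate = NULL) {
  grid <- factorial_grid(space)
  if (!nrow(grid)) stop("empty search space")
  if (is.null(evaluate))
    evaluate <- des_evaluator(scenario, replications, seed)
  staff_cols <- setdiff(names(grid), "scenario")
  est <- hw <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    ev <- evaluate(unlist(grid[r, staff_cols]), replications)
    est[r] <- ev$estimate; hw[r] <- ev$halfwidth %||% 0
  }
  out <- data.frame(grid, headcount = rowSums(grid[, staff_cols]),
                    estimate = est, halfwidth = hw,
                    feasible = est < limit, row.names = NULL)
  ord <- order(!out$feasible, out$headcount, out$estimate)
  out <- out[ord, ]
  class(out) <- c("mci_ranking", "data.frame")
  out
}

# lattice point <-> key for the tabu memory
point_key <- function(pos) paste(pos, collapse = ",")

#' Constrained staff-mix simulation-optimization
#'
#' Population-based search over the integer staff lattice: scatter-search
#' style recombination of elite points with rounding to the nearest
#' admissible level, one-coordinate mutations, a tabu memory of visited
#' points, and a systematic diversification scan of unvisited points when
#' recombination stalls. A candidate replaces the incumbent only if it is
#' feasible with lower headcount, or equal headcount and an estimate whose
#' confidence interval lies below the incumbent's (noise-aware acceptance);
#' incumbent candidates are confirmed at a larger replication count.
#' Deterministic given `seed`. If no point satisfies the constraint the
#' least-violating point is returned with `feasible = FALSE`.
#'
#' @param space Named list of ordered level vectors.
#' @param scenario Base scenario (staff replaced per point).
#' @param limit Constraint: mean red total system time below `limit` minutes.
#' @param budget Maximum number of point evaluations.
#' @param seed Seed for both the search and the simulator streams.
#' @param screen_reps,confirm_reps Replications for screening and for
#'   confirming candidate incumbents.
#' @param evaluate Optional custom evaluator `function(staff, reps)`.
#' @return List of class `mci_opt`: `best_staff`, `estimate`, `halfwidth`,
#'   `headcount`, `feasible`, `evaluations`, `trace` (one row per evaluated
#'   point).
#' @export
optimize_staff <- function(space, scenario, limit = 200, budget = 100,
                           seed = scenario$seed, screen_reps = 10,
                           confirm_reps = 30, evaluate = NULL) {
  k <- vapply(space, length, 1L)
  npoints <- prod(k)
  if (budget < 1) stop("budget must allow at least one evaluation")
  if (is.null(evaluate))
    evaluate <- des_evaluator(scenario, confirm_reps, seed)
  rng <- new_stream(seed)
  tabu <- new.env(parent = emptyenv())
  trace <- list()
  evals <- 0L

  eval_pos <- function(pos, reps) {
    staff <- mapply(function(lv, p) lv[p], space, pos)
    ev <- evaluate(staff, reps)
    evals <<- evals + 1L
    assign(point_key(pos), TRUE, tabu)
    rec <- list(pos = pos, staff = staff, headcount = sum(staff),
                estimate = ev$estimate, halfwidth = ev$halfwidth %||% 0,
                replications = reps)
    trace[[length(trace) + 1L]] <<- rec
    rec
  }
  visited <- function(pos) exists(point_key(pos), tabu)

  # objective ordering: feasibility, then headcount, then estimate
  better <- function(a, b) {
    fa <- a$estimate < limit; fb <- b$estimate < limit
    if (fa != fb) return(fa)
    if (fa) {
      if (a$headcount != b$headcount) return(a$headcount < b$headcount)
      # noise-aware tie-break: CI of a must lie below b's point estimate
      return(a$estimate + a$halfwidth < b$estimate)
    }
    a$estimate < b$estimate                    # least violating
  }

  rand_pos <- function() {
    u <- stream_draw(rng, length(k), stats::runif)
    pmin(k, pmax(1L, ceiling(u * k)))
  }

  # seed population: all-min, all-max, and random points
  pop <- list(rep(1L, length(k)), as.integer(k))
  pop_n <- max(4L, min(10L, npoints))
  attempts <- 0L
  while (length(pop) < pop_n && attempts < 20L * pop_n) {
    cand <- as.integer(rand_pos())
    attempts <- attempts + 1L
    if (!point_key(cand) %in% vapply(pop, point_key, ""))
      pop[[length(pop) + 1L]] <- cand
  }
  pop <- pop[!duplicated(vapply(pop, point_key, ""))]

  incumbent <- NULL
  for (pos in pop) {
    if (evals >= budget) break
    if (visited(pos)) next
    rec <- eval_pos(pos, screen_reps)
    if (is.null(incumbent) || better(rec, incumbent)) incumbent <- rec
  }

  scan_cursor <- 0L
  next_unvisited <- function() {
    while (scan_cursor < npoints) {
      scan_cursor <<- scan_cursor + 1L
      pos <- grid_point(scan_cursor, space)
      if (!visited(pos)) return(pos)
    }
    NULL
  }

  while (evals < budget) {
    elite <- trace[order(vapply(trace, function(r)
      (r$estimate >= limit) * 1e6 + r$headcount + r$estimate / 1e4, 0))]
    elite <- elite[seq_len(min(4L, length(elite)))]
    cand <- NULL
    if (length(elite) >= 2) {
      # recombine two elites, round to the nearest admissible level
      pr <- stream_draw(rng, 2L, function(n) sample.int(length(elite), n))
      w <- stream_draw(rng, 1L, stats::runif)
      mix <- w * elite[[pr[1]]]$pos + (1 - w) * elite[[pr[2]]]$pos
      cand <- as.integer(pmin(k, pmax(1L, round(mix))))
      if (visited(cand)) {
        # mutate one coordinate of the best elite
        j <- stream_draw(rng, 1L, function(n) sample.int(length(k), n))
        dlt <- if (stream_draw(rng, 1L, stats::runif) < 0.5) -1L else 1L
        cand <- elite[[1]]$pos
        cand[j] <- min(k[j], max(1L, cand[j] + dlt))
        cand <- as.integer(cand)
      }
    }
    if (is.null(cand) || visited(cand)) cand <- next_unvisited()
    if (is.null(cand)) break                  # whole lattice visited
    rec <- eval_pos(cand, screen_reps)
    if (better(rec, incumbent)) {
      if (confirm_reps > rec$replications && evals < budget) {
        rec <- eval_pos(rec$pos, confirm_reps)   # confirmation stage
      }
      if (better(rec, incumbent)) incumbent <- rec
    }
  }

  trace_df <- do.call(rbind, lapply(trace, function(r)
    data.frame(t(r$staff), headcount = r$headcount, estimate = r$estimate,
               halfwidth = r$halfwidth, replications = r$replications)))
  structure(list(best_staff = incumbent$staff,
                 estimate = incumbent$estimate,
                 halfwidth = incumbent$halfwidth,
                 headcount = incumbent$headcount,
                 feasible = incumbent$estimate < limit,
                 limit = limit, evaluations = evals, trace = trace_df),
            class = "mci_opt")
}

#' @export
print.mci_opt <- function(x, ...) {
  cat(sprintf("Staff-mix optimization: %s point (headcount %d, estimate %.2f min, limit %g)\n",
              if (x$feasible) "feasible" else "infeasible (least violating)",
              x$headcount, x$estimate, x$limit))
  print(unclass(x$best_staff))
  cat(x$evaluations, "evaluations\n")
  invisible(x)
}
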