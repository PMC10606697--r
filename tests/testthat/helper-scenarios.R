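# shared fixtures, all built in code

# a small, fast scenario for engine tests: 3 red / 6 yellow / 10 green
tiny_scenario <- function(seed = 1L) {
  scenario_config(
    label = "tiny",
    staff = staff_vector(6, 3, 3, 10, 1, 2, 1),
    load = patient_load(3, 6, 10, arrival_window_min = 45),
    seed = seed)
}

# effectively unlimited resources, no deterioration, no routine load:
# every wait must be zero
unconstrained_scenario <- function(seed = 1L, n_red = 3, n_yellow = 4,
                                   n_green = 5) {
  cal <- calibration(
    health = health_dynamics(d_red = 0, d_yellow = 0, d_green = 0),
    routine_rate_per_min = 0)
  scenario_config(
    label = "unconstrained",
    staff = staff_vector(50, 50, 50, 90, 50, 50, 50),
    load = patient_load(n_red, n_yellow, n_green, arrival_window_min = 60),
    resources = resource_set(n_trauma_or = 20, n_central_or_usable = 20,
                             n_resus_bays = 20, n_ct = 20, n_xray = 20,
                             n_yellow_treatment_slots = 20),
    calibration = cal, seed = seed)
}

# deterministic noise-free surrogate objective over a staff lattice:
# a fixed linear surface plus a point-specific deterministic wiggle
surrogate_evaluator <- function(salt = 0) {
  force(salt)
  co <- reference_surface()
  function(staff, reps = 1) {
    w <- co[names(staff)]
    wig <- sum(sin(seq_along(staff) * as.numeric(staff) + salt))
    list(estimate = unname(co[1] + sum(w * as.numeric(staff)) + wig),
         halfwidth = 0, replications = reps)
  }
}

apply_window <- function(sc, w) {
  sc$load$arrival_window_min <- w
  sc
}

# random small search space over a subset of staff categories
random_space <- function(rng_seed, max_levels = 4) {
  set.seed(rng_seed)
  n_cat <- sample(2:3, 1)
  cats <- sample(staff_categories(), n_cat)
  space <- lapply(cats, function(cc)
    sort(sample(1:9, sample(2:max_levels, 1))))
  names(space) <- cats
  space[order(match(names(space), staff_categories()))]
}
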