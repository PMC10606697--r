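## Discrete-event core: arrivals, triage, health dynamics with progressive
## re-triage and death, pathway routing, and priority seizing of staff, rooms
## and machines. One replication is a single event-calendar loop over
## pre-allocated patient vectors; queues are FIFO-within-priority buckets with
## lazy invalidation, and every stochastic purpose draws from its own stream.

# triage category codes used throughout the engine
CAT_RED <- 1L; CAT_YELLOW <- 2L; CAT_GREEN <- 3L; CAT_BLACK <- 4L

cat_names <- function() c("red", "yellow", "green", "black")

# station codes
ST_TRIAGE <- 1L; ST_STAB <- 2L; ST_EXAM <- 3L; ST_CT <- 4L; ST_XRAY <- 5L
ST_SURG <- 6L
station_names <- function()
  c("triage", "stabilization", "exam", "ct", "xray", "surgery")

# room codes
RM_RESUS <- 1L; RM_YSLOT <- 2L; RM_CT <- 3L; RM_XRAY <- 4L
RM_OR_TRAUMA <- 5L; RM_OR_CENTRAL <- 6L
room_names <- function()
  c("resus_bay", "yellow_slot", "ct_machine", "xray_machine",
    "trauma_or", "central_or")

#' Update a patient's health score over an interval
#'
#' While awaiting the first clinical treatment the score falls at the
#' category's deterioration rate; under treatment it rises at the improvement
#' rate. The score is clamped to [0, 99]; a score of 0 means death (triage
#' black, absorbing).
#'
#' @param h Current score in [0, 99].
#' @param dt Elapsed minutes (non-negative).
#' @param category Current triage category, one of `"red"`, `"yellow"`,
#'   `"green"` (or codes 1-3).
#' @param waiting `TRUE` while the patient is untreated and waiting,
#'   `FALSE` under treatment.
#' @param health An [health_dynamics()] object.
#' @return The updated score.
#' @export
update_health <- function(h, dt, category, waiting, health = health_dynamics()) {
  if (any(dt < 0)) stop("dt must be non-negative")
  if (is.character(category))
    category <- match(category, cat_names())
  d <- c(health$d_red, health$d_yellow, health$d_green)[category]
  rate <- ifelse(waiting, -d, health$r)
  pmin(99, pmax(0, h + rate * dt))
}

#' Map a health score to a triage category
#'
#' Progressive patient care: a score of 0 is black (deceased), below
#' `theta_red` red, below `theta_yellow` yellow, otherwise green.
#'
#' @param h Score(s) in [0, 99].
#' @param health An [health_dynamics()] object supplying the thresholds.
#' @return Character vector of categories.
#' @export
retriage <- function(h, health = health_dynamics()) {
  if (any(h < 0 | h > 99)) stop("health score outside [0, 99]")
  out <- ifelse(h <= 0, "black",
         ifelse(h < health$theta_red, "red",
         ifelse(h < health$theta_yellow, "yellow", "green")))
  out
}

#' Dining-hall supervision requirement
#'
#' Staff locked to supervising slightly injured patients gathered in the
#' dining hall, at the plan's ratios of one general nurse per 10 and one
#' rotation physician per 25 patients present.
#'
#' @param n_green_present Number of slightly injured patients in the hall.
#' @param per_nurse,per_rotation_physician Supervision ratios.
#' @return Named integer vector `c(general_nurses=, rotation_physicians=)`.
#' @export
required_green_supervision <- function(n_green_present, per_nurse = 10L,
                                       per_rotation_physician = 25L) {
  if (any(n_green_present < 0)) stop("count must be non-negative")
  c(general_nurses = as.integer(ceiling(n_green_present / per_nurse)),
    rotation_physicians =
      as.integer(ceiling(n_green_present / per_rotation_physician)))
}

#' Generate category arrival times
#'
#' For each category with `n > 0`, inter-arrival times are i.i.d. exponential
#' with mean `arrival_window_min / n`, starting at the incident (time 0);
#' exactly `n` arrivals are emitted per category, so the window is the
#' expected, not a hard, makespan.
#'
#' @param load An [patient_load()].
#' @param streams Stream set from the replication (or `NULL` to draw from the
#'   session RNG).
#' @return Named list of numeric arrival-time vectors `red`, `yellow`, `green`.
#' @export
generate_arrivals <- function(load, streams = NULL) {
  draw1 <- function(n, purpose) {
    if (n == 0) return(numeric(0))
    rate <- n / load$arrival_window_min
    if (is.null(streams)) cumsum(stats::rexp(n, rate))
    else cumsum(stream_draw(streams[[purpose]], n,
                            function(k) stats::rexp(k, rate)))
  }
  list(red = draw1(load$n_red, "arrival_red"),
       yellow = draw1(load$n_yellow, "arrival_yellow"),
       green = draw1(load$n_green, "arrival_green"))
}

#' Next station on a patient's pathway
#'
#' Routing in the trauma pathway: red patients go to resuscitation-bay
#' stabilization, then imaging (if indicated), then surgery (if needed), then
#' transfer out; yellow patients go to a treatment-slot examination instead of
#' stabilization; green patients are gathered in the dining hall until
#' discharge at the horizon.
#'
#' @param category `"red"`, `"yellow"` or `"green"` (current category).
#' @param phase One of `"arrived"`, `"post_triage"`,
#'   `"post_first_treatment"`, `"post_imaging"`, `"post_surgery"`.
#' @param imaging `"none"`, `"xray"` or `"ct"` (still pending).
#' @param needs_surgery Logical.
#' @return Station name, `"dining"`, or `"exit"`.
#' @export
route_next <- function(category, phase, imaging = "none", needs_surgery = FALSE) {
  if (phase == "arrived") return("triage")
  if (phase == "post_triage") {
    return(switch(category, red = "stabilization", yellow = "exam",
                  green = "dining", stop("unroutable category ", category)))
  }
  if (phase == "post_first_treatment") {
    if (imaging != "none") return(imaging)
    if (needs_surgery) return("surgery")
    return("exit")
  }
  if (phase == "post_imaging") {
    if (needs_surgery) return("surgery")
    return("exit")
  }
  if (phase == "post_surgery") return("exit")
  stop("unknown phase ", phase)
}

# convert a staffing matrix (names) to index form once per replication
staffing_to_idx <- function(staffing) {
  cats <- staff_categories()
  lapply(staffing, function(groups)
    lapply(groups, function(g)
      list(cats = match(g$cats, cats), n = g$n)))
}

#' Run one replication of a scenario
#'
#' Executes the full discrete-event simulation of one mass-casualty scenario:
#' exponential arrivals per triage category, triage, health-score dynamics
#' with exact threshold-crossing re-triage and death, pathway routing,
#' non-preemptive priority seizing (red > yellow > green, FIFO within a
#' category, all resources of a task seized and released together), the CT
#' downgrade rule, dining-hall supervision locks, and the routine
#' operating-room background load. Deterministic given `(scenario, seed)`.
#'
#' @param scenario An [scenario_config()].
#' @param seed Replication seed (defaults to the scenario's master seed).
#' @param log_events Keep a full event log (`data.frame`) in the result.
#' @param max_events Wall guard: an event count beyond this signals a
#'   modeling bug (non-termination) and aborts with an error.
#' @return A list of class `mci_replication` with elements `patients`
#'   (per-patient record data frame), `deaths`, `end_time`, `utilization`,
#'   `staff_workload`, `seed` and optionally `events`.
#' @export
run_replication <- function(scenario, seed = scenario$seed, log_events = FALSE,
                            max_events = NULL) {
  cal <- scenario$calibration
  hd <- cal$health
  res <- scenario$resources
  ld <- scenario$load
  streams <- make_streams(seed, 1L)

  n_cat <- c(ld$n_red, ld$n_yellow, ld$n_green)
  N <- sum(n_cat)
  if (is.null(max_events)) max_events <- 10000L + 400L * N

  ## --- patient state ------------------------------------------------------
  p_arr <- numeric(N); p_cat0 <- integer(N); p_cat <- integer(N)
  p_h <- numeric(N); p_ht <- numeric(N)
  p_need_surg <- logical(N); p_img <- integer(N)  # 0 none, 1 xray, 2 ct
  p_ct_elig <- logical(N)
  p_first <- logical(N)     # first clinical treatment started
  p_qstation <- integer(N); p_qtime <- numeric(N)
  p_hev <- integer(N)       # pending health-cross calendar slot (0 none)
  p_curev <- integer(N)     # current in-service end-event slot (0 none)
  t_tri_s <- rep(NA_real_, N); t_tri_e <- rep(NA_real_, N)
  t_ft_s <- rep(NA_real_, N); t_ft_e <- rep(NA_real_, N)
  t_img_s <- rep(NA_real_, N); t_img_e <- rep(NA_real_, N)
  t_surg_s <- rep(NA_real_, N); t_surg_e <- rep(NA_real_, N)
  t_exit <- rep(NA_real_, N); t_death <- rep(NA_real_, N)

  arr <- generate_arrivals(ld, streams)
  idx_red <- seq_len(n_cat[1])
  idx_yel <- n_cat[1] + seq_len(n_cat[2])
  idx_grn <- n_cat[1] + n_cat[2] + seq_len(n_cat[3])
  p_cat0[idx_red] <- CAT_RED; p_cat0[idx_yel] <- CAT_YELLOW
  p_cat0[idx_grn] <- CAT_GREEN
  p_cat <- p_cat0
  p_arr[idx_red] <- arr$red; p_arr[idx_yel] <- arr$yellow
  p_arr[idx_grn] <- arr$green
  h0 <- c(hd$h0_red, hd$h0_yellow, hd$h0_green)
  p_h <- h0[p_cat0]
  drate <- c(hd$d_red, hd$d_yellow, hd$d_green, 0)

  # pathway flags, drawn reds first then yellows (fixed order for CRN)
  u_surg <- stream_draw(streams$bern_surgery, n_cat[1] + n_cat[2], stats::runif)
  p_need_surg[idx_red] <- u_surg[seq_len(n_cat[1])] < cal$p_surgery_red
  p_need_surg[idx_yel] <- u_surg[n_cat[1] + seq_len(n_cat[2])] < cal$p_surgery_yellow
  u_img <- stream_draw(streams$bern_imaging, n_cat[1] + n_cat[2], stats::runif)
  img_of <- function(u, p_ct, p_xr) ifelse(u < p_ct, 2L, ifelse(u < p_ct + p_xr, 1L, 0L))
  p_img[idx_red] <- img_of(u_img[seq_len(n_cat[1])], cal$p_ct_red, cal$p_xray_red)
  p_img[idx_yel] <- img_of(u_img[n_cat[1] + seq_len(n_cat[2])],
                           cal$p_ct_yellow, cal$p_xray_yellow)
  u_elig <- stream_draw(streams$bern_ct_eligible, n_cat[1] + n_cat[2], stats::runif)
  p_ct_elig[c(idx_red, idx_yel)] <- u_elig < cal$p_ct_downgrade_eligible

  ## --- resources ----------------------------------------------------------
  sa <- as.integer(unclass(scenario$staff))        # available staff by category
  staff_cap <- sa
  room_avail <- c(res$n_resus_bays, res$n_yellow_treatment_slots, res$n_ct,
                  res$n_xray, res$n_trauma_or, res$n_central_or_usable)
  room_cap <- room_avail
  GN <- 4L; RP <- 3L                               # category indices
  hall <- 0L
  lock_held <- c(0L, 0L); lock_last_t <- 0
  staff_busy <- numeric(7); room_busy <- numeric(6)

  staffing <- staffing_to_idx(cal$staffing)
  triage_reserve <- integer(7)
  for (g in staffing$triage)
    triage_reserve[g$cats[1]] <- triage_reserve[g$cats[1]] + g$n
  st_staffing <- function(station, cat) {
    switch(station,
           staffing$triage, staffing$red_stabilization, staffing$yellow_exam,
           staffing$imaging, staffing$imaging,
           if (cat == CAT_RED) staffing$red_surgery else staffing$yellow_surgery)
  }
  fam_names <- c("triage", "red_stabilization", "yellow_exam", "ct", "xray",
                 "red_surgery", "yellow_surgery", "transfer_out", "routine_case")
  fam_stream <- c("svc_triage", "svc_red_stabilization", "svc_yellow_exam",
                  "svc_ct", "svc_xray", "svc_red_surgery", "svc_yellow_surgery",
                  "svc_transfer_out", "svc_routine_case")
  fam_buf <- vector("list", 9); fam_pos <- integer(9)
  next_dur <- function(fam) {
    pos <- fam_pos[fam] + 1L
    buf <- fam_buf[[fam]]
    if (is.null(buf) || pos > length(buf)) {
      buf <- draw_service(cal$service[[fam_names[fam]]], 128L,
                          streams[[fam_stream[fam]]])
      fam_buf[[fam]] <<- buf
      pos <- 1L
    }
    fam_pos[fam] <<- pos
    buf[pos]
  }
  st_family <- function(station, cat) {
    switch(station, 1L, 2L, 3L, 4L, 5L,
           if (cat == CAT_RED) 6L else 7L)
  }
  st_room <- c(0L, RM_RESUS, RM_YSLOT, RM_CT, RM_XRAY, 0L)  # SURG special

  ## --- queues: 6 stations x 3 category buckets ----------------------------
  qv <- vector("list", 18); qn <- integer(18); qh <- integer(18)
  for (k in 1:18) qv[[k]] <- integer(16)
  enqueue <- function(station, i, t) {
    c0 <- p_cat[i]
    k <- (station - 1L) * 3L + c0
    n1 <- qn[k] + 1L
    if (n1 > length(qv[[k]])) qv[[k]] <<- c(qv[[k]], integer(length(qv[[k]])))
    qv[[k]][n1] <<- i
    qn[k] <<- n1
    p_qstation[i] <<- station
    p_qtime[i] <<- t
    log_ev(t, i, "queue", station_names()[station])
  }
  peek <- function(station) {
    for (c0 in 1:3) {
      k <- (station - 1L) * 3L + c0
      h <- qh[k]
      while (h < qn[k]) {
        i <- qv[[k]][h + 1L]
        if (p_qstation[i] == station && p_cat[i] == c0) {
          if (h != qh[k]) qh[k] <<- h
          return(i)
        }
        h <- h + 1L
      }
      qh[k] <<- h
    }
    0L
  }
  pop <- function(i) {                 # i must be the current peek result
    k <- (p_qstation[i] - 1L) * 3L + p_cat[i]
    qh[k] <<- qh[k] + 1L
    p_qstation[i] <<- 0L
  }

  ## --- event calendar -----------------------------------------------------
  EV_ARRIVAL <- 1L; EV_END <- 2L; EV_HEALTH <- 3L
  EV_ROUTINE_ARR <- 4L; EV_ROUTINE_END <- 5L
  cal_cap <- 256L
  cal_time <- rep(Inf, cal_cap); cal_type <- integer(cal_cap)
  cal_id <- integer(cal_cap); cal_aux <- vector("list", cal_cap)
  cal_n <- 0L; freelist <- integer(0)
  sched <- function(time, type, id = 0L, aux = NULL) {
    if (length(freelist)) {
      s <- freelist[length(freelist)]
      freelist <<- freelist[-length(freelist)]
    } else {
      s <- cal_n + 1L
      if (s > cal_cap) {
        cal_time <<- c(cal_time, rep(Inf, cal_cap))
        cal_type <<- c(cal_type, integer(cal_cap))
        cal_id <<- c(cal_id, integer(cal_cap))
        cal_aux <<- c(cal_aux, vector("list", cal_cap))
        cal_cap <<- 2L * cal_cap
      }
      cal_n <<- s
    }
    cal_time[s] <<- time; cal_type[s] <<- type; cal_id[s] <<- id
    cal_aux[s] <<- list(aux)
    s
  }
  cancel <- function(s) {
    cal_time[s] <<- Inf
    cal_aux[s] <<- list(NULL)
    freelist <<- c(freelist, s)
  }

  ## --- event log ----------------------------------------------------------
  if (log_events) {
    lg_t <- numeric(1024); lg_p <- integer(1024); lg_e <- character(1024)
    lg_d <- character(1024); lg_n <- 0L
  }
  log_ev <- function(t, i, ev, detail = "") {
    if (!log_events) return(invisible())
    n1 <- lg_n + 1L
    if (n1 > length(lg_t)) {
      m <- length(lg_t)
      lg_t <<- c(lg_t, numeric(m)); lg_p <<- c(lg_p, integer(m))
      lg_e <<- c(lg_e, character(m)); lg_d <<- c(lg_d, character(m))
    }
    lg_t[n1] <<- t; lg_p[n1] <<- i; lg_e[n1] <<- ev; lg_d[n1] <<- detail
    lg_n <<- n1
  }

  ## --- health dynamics ----------------------------------------------------
  # schedule the next downward boundary crossing for an untreated patient
  sched_health <- function(i, now) {
    d <- drate[p_cat[i]]
    if (d <= 0 || p_first[i]) return(invisible())
    h <- p_h[i]
    b <- if (h > hd$theta_yellow) hd$theta_yellow
         else if (h > hd$theta_red) hd$theta_red else 0
    p_hev[i] <<- sched(now + (h - b) / d, EV_HEALTH, i, aux = b)
  }
  cancel_health <- function(i) {
    if (p_hev[i] > 0L) { cancel(p_hev[i]); p_hev[i] <<- 0L }
  }
  # bring an untreated patient's score up to date at time t
  sync_health <- function(i, t) {
    d <- drate[p_cat[i]]
    if (d > 0 && !p_first[i]) p_h[i] <<- max(0, p_h[i] - d * (t - p_ht[i]))
    p_ht[i] <<- t
  }

  # a patient is resolved once they exit, die, or settle in the dining hall;
  # a hall patient re-triaged back into the clinical pathway is unresolved again
  p_resolved <- logical(N)
  unresolved <- N
  resolve <- function(i) {
    if (!p_resolved[i]) { p_resolved[i] <<- TRUE; unresolved <<- unresolved - 1L }
  }
  unresolve <- function(i) {
    if (p_resolved[i]) { p_resolved[i] <<- FALSE; unresolved <<- unresolved + 1L }
  }
  deaths <- 0L
  routine_pending <- 0L
  routine_ongoing_end <- numeric(0)

  update_lock_busy <- function(t) {
    staff_busy[GN] <<- staff_busy[GN] + lock_held[1] * (t - lock_last_t)
    staff_busy[RP] <<- staff_busy[RP] + lock_held[2] * (t - lock_last_t)
    lock_last_t <<- t
  }
  top_up_locks <- function(t) {
    # supervision never strips the triage crew: at least the staffing of one
    # triage slot stays lockable-free, so casualties can always be triaged
    need <- pmin(c(ceiling(hall / cal$green_per_nurse),
                   ceiling(hall / cal$green_per_rotation_physician)),
                 pmax(0L, c(staff_cap[GN] - triage_reserve[GN],
                            staff_cap[RP] - triage_reserve[RP])))
    if (need[1] == lock_held[1] && need[2] == lock_held[2]) return(invisible())
    update_lock_busy(t)
    for (j in 1:2) {
      cat_j <- if (j == 1) GN else RP
      if (need[j] < lock_held[j]) {            # release surplus supervisors
        sa[cat_j] <<- sa[cat_j] + (lock_held[j] - need[j])
        lock_held[j] <<- need[j]
      } else if (need[j] > lock_held[j]) {
        take <- min(sa[cat_j], need[j] - lock_held[j])
        sa[cat_j] <<- sa[cat_j] - take
        lock_held[j] <<- lock_held[j] + take
      }
    }
  }

  # greedy multiset seize check; returns 7-vector of counts or NULL
  staff_take <- function(groups) {
    take <- integer(7)
    for (g in groups) {
      rem <- g$n
      for (cc in g$cats) {
        av <- sa[cc] - take[cc]
        if (av > 0L) {
          u <- min(av, rem); take[cc] <- take[cc] + u; rem <- rem - u
          if (rem == 0L) break
        }
      }
      if (rem > 0L) return(NULL)
    }
    take
  }

  start_task <- function(i, station, t) {
    cat_i <- p_cat[i]
    groups <- st_staffing(station, cat_i)
    take <- staff_take(groups)
    if (is.null(take)) return(FALSE)
    room <- st_room[station]
    if (station == ST_SURG)
      room <- if (room_avail[RM_OR_TRAUMA] > 0L) RM_OR_TRAUMA
              else if (room_avail[RM_OR_CENTRAL] > 0L) RM_OR_CENTRAL else 0L
    if (station == ST_SURG && room == 0L) return(FALSE)
    if (room > 0L && room_avail[room] <= 0L) return(FALSE)
    # grant
    pop(i)
    sa <<- sa - take
    if (room > 0L) room_avail[room] <<- room_avail[room] - 1L
    fam <- st_family(station, cat_i)
    dur <- next_dur(fam)
    staff_busy <<- staff_busy + take * dur
    if (room > 0L) room_busy[room] <<- room_busy[room] + dur
    # timestamps and first-treatment bookkeeping
    if (station == ST_TRIAGE) {
      t_tri_s[i] <<- t
    } else if (station == ST_STAB || station == ST_EXAM) {
      sync_health(i, t)
      cancel_health(i)
      p_first[i] <<- TRUE
      t_ft_s[i] <<- t
    } else if (station == ST_CT || station == ST_XRAY) {
      t_img_s[i] <<- t
    } else if (station == ST_SURG) {
      t_surg_s[i] <<- t
    }
    p_curev[i] <<- sched(t + dur, EV_END, i,
                         aux = list(station = station, take = take, room = room))
    log_ev(t, i, "seize", station_names()[station])
    TRUE
  }

  start_routine <- function(t) {
    while (routine_pending > 0L && room_avail[RM_OR_CENTRAL] > 0L) {
      routine_pending <<- routine_pending - 1L
      room_avail[RM_OR_CENTRAL] <<- room_avail[RM_OR_CENTRAL] - 1L
      dur <- next_dur(9L)
      room_busy[RM_OR_CENTRAL] <<- room_busy[RM_OR_CENTRAL] + dur
      routine_ongoing_end <<- c(routine_ongoing_end, t + dur)
      sched(t + dur, EV_ROUTINE_END)
      log_ev(t, 0L, "seize", "central_or routine")
    }
  }

  dispatch <- function(t) {
    top_up_locks(t)
    for (station in c(ST_STAB, ST_SURG, ST_CT, ST_XRAY, ST_EXAM, ST_TRIAGE)) {
      repeat {
        i <- peek(station)
        if (i == 0L) break
        if (!start_task(i, station, t)) break   # head-of-line blocking
      }
    }
    start_routine(t)
  }

  enter_dining <- function(i, t) {
    hall <<- hall + 1L
    resolve(i)
    log_ev(t, i, "queue", "dining")
  }

  # route a patient after a completed stage
  route_after <- function(i, phase, t) {
    cat_i <- p_cat[i]
    img <- c("none", "xray", "ct")[p_img[i] + 1L]
    nxt <- route_next(cat_names()[cat_i], phase, img, p_need_surg[i])
    if (nxt == "dining") { enter_dining(i, t); return(invisible()) }
    if (nxt == "exit") {
      fam <- 8L
      dur <- next_dur(fam)
      p_curev[i] <<- sched(t + dur, EV_END, i,
                           aux = list(station = 0L, take = NULL, room = 0L))
      return(invisible())
    }
    station <- match(nxt, station_names())
    if (station == ST_CT && p_img[i] == 2L && p_ct_elig[i] &&
        room_avail[RM_CT] == 0L) {
      station <- ST_XRAY                      # downgrade CT -> X-ray
      p_img[i] <<- 1L
      log_ev(t, i, "retriage", "ct_downgraded_to_xray")
    }
    enqueue(station, i, t)
  }

  finish_patient <- function(i, t) {
    t_exit[i] <<- t
    resolve(i)
    log_ev(t, i, "exit", "")
  }

  handle_end <- function(i, t, aux) {
    p_curev[i] <<- 0L
    station <- aux$station
    if (!is.null(aux$take)) sa <<- sa + aux$take
    if (aux$room > 0L) room_avail[aux$room] <<- room_avail[aux$room] + 1L
    if (station > 0L) log_ev(t, i, "release", station_names()[station])
    if (p_cat[i] == CAT_BLACK) return(invisible())  # died mid-service (triage)
    if (station == 0L) {                            # transfer-out finished
      finish_patient(i, t)
    } else if (station == ST_TRIAGE) {
      t_tri_e[i] <<- t
      route_after(i, "post_triage", t)
    } else if (station == ST_STAB || station == ST_EXAM) {
      t_ft_e[i] <<- t
      p_h[i] <<- min(99, p_h[i] + hd$r * (t - t_ft_s[i])); p_ht[i] <<- t
      route_after(i, "post_first_treatment", t)
    } else if (station == ST_CT || station == ST_XRAY) {
      t_img_e[i] <<- t
      p_img[i] <<- 0L
      p_h[i] <<- min(99, p_h[i] + hd$r * (t - t_img_s[i])); p_ht[i] <<- t
      route_after(i, "post_imaging", t)
    } else if (station == ST_SURG) {
      t_surg_e[i] <<- t
      p_h[i] <<- min(99, p_h[i] + hd$r * (t - t_surg_s[i])); p_ht[i] <<- t
      route_after(i, "post_surgery", t)
    }
  }

  kill_patient <- function(i, t) {
    p_h[i] <<- 0; p_ht[i] <<- t
    was_green_in_hall <- p_cat[i] == CAT_GREEN && p_qstation[i] == 0L &&
      !is.na(t_tri_e[i]) && is.na(t_exit[i])
    p_cat[i] <<- CAT_BLACK
    p_qstation[i] <<- 0L
    t_death[i] <<- t
    deaths <<- deaths + 1L
    if (p_curev[i] > 0L) {      # dies during triage: release held resources
      s <- p_curev[i]
      aux <- cal_aux[[s]]
      end_t <- cal_time[s]
      cancel(s); p_curev[i] <<- 0L
      if (!is.null(aux$take)) {
        sa <<- sa + aux$take
        # the seize charged the full drawn duration up front; refund the rest
        staff_busy <<- staff_busy - aux$take * (end_t - t)
      }
      if (aux$room > 0L) {
        room_avail[aux$room] <<- room_avail[aux$room] + 1L
        room_busy[aux$room] <<- room_busy[aux$room] - (end_t - t)
      }
    }
    if (was_green_in_hall) hall <<- hall - 1L
    resolve(i)
    log_ev(t, i, "death", "")
  }

  handle_health <- function(i, t, boundary) {
    p_hev[i] <<- 0L
    if (p_cat[i] == CAT_BLACK || p_first[i]) return(invisible())
    p_h[i] <<- boundary; p_ht[i] <<- t
    if (boundary <= 0) {
      kill_patient(i, t)
      return(invisible())
    }
    new_cat <- if (boundary <= hd$theta_red) CAT_RED else CAT_YELLOW
    old_cat <- p_cat[i]
    if (new_cat != old_cat) {
      in_hall <- old_cat == CAT_GREEN && p_qstation[i] == 0L &&
        !is.na(t_tri_e[i]) && is.na(t_exit[i])
      station <- p_qstation[i]
      p_cat[i] <<- new_cat
      log_ev(t, i, "retriage", cat_names()[new_cat])
      if (in_hall) {
        hall <<- hall - 1L
        unresolve(i)
        enqueue(ST_EXAM, i, t)                 # leaves the hall for treatment
      } else if (station == ST_EXAM && new_cat == CAT_RED) {
        p_qstation[i] <<- 0L                   # re-queued on the red pathway
        enqueue(ST_STAB, i, t)
      } else if (station > 0L) {
        p_qstation[i] <<- 0L                   # same station, new priority
        enqueue(station, i, t)
      }
      # else: in triage service; routing after triage uses the new category
    }
    sched_health(i, t)
  }

  ## --- routine background load -------------------------------------------
  routine_max_rate <- max(cal$routine_rate_per_min(0:1439))
  tod0 <- ld$incident_time_of_day
  next_routine_candidate <- function(from) {
    t <- from
    repeat {
      draws <- stream_draw(streams$routine_arrivals, 2L,
                           function(k) stats::runif(k))
      t <- t - log(draws[1]) / routine_max_rate
      if (draws[2] < cal$routine_rate_per_min((tod0 + t) %% 1440) /
            routine_max_rate) return(t)
    }
  }
  if (routine_max_rate > 0) {
    t <- -720
    repeat {                                 # warm-up so cases can straddle t=0
      t <- next_routine_candidate(t)
      if (t >= 0) break
      dur <- next_dur(9L)
      if (t + dur > 0 && room_avail[RM_OR_CENTRAL] > 0L) {
        room_avail[RM_OR_CENTRAL] <- room_avail[RM_OR_CENTRAL] - 1L
        room_busy[RM_OR_CENTRAL] <- room_busy[RM_OR_CENTRAL] + (t + dur)
        routine_ongoing_end <- c(routine_ongoing_end, t + dur)
        sched(t + dur, EV_ROUTINE_END)
      }
    }
    sched(t, EV_ROUTINE_ARR)
  }

  ## --- seed the calendar with first arrivals ------------------------------
  arr_next <- c(1L, 1L, 1L)      # next arrival index per category
  arr_base <- c(0L, n_cat[1], n_cat[1] + n_cat[2])
  for (c0 in 1:3) if (n_cat[c0] > 0)
    sched(p_arr[arr_base[c0] + 1L], EV_ARRIVAL, c0)

  ## --- main loop ----------------------------------------------------------
  n_events <- 0L
  now <- 0
  while (unresolved > 0L) {
    if (cal_n == 0L) break
    s <- which.min(cal_time[seq_len(cal_n)])
    t <- cal_time[s]
    if (!is.finite(t)) break                     # nothing left to do
    type <- cal_type[s]; id <- cal_id[s]; aux <- cal_aux[[s]]
    cancel(s)
    now <- t
    n_events <- n_events + 1L
    if (n_events > max_events)
      stop("event cap exceeded: the scenario does not terminate ",
           "(structurally starved task or zero-rate resource)")
    if (type == EV_ARRIVAL) {
      c0 <- id
      i <- arr_base[c0] + arr_next[c0]
      arr_next[c0] <- arr_next[c0] + 1L
      if (arr_next[c0] <= n_cat[c0])
        sched(p_arr[arr_base[c0] + arr_next[c0]], EV_ARRIVAL, c0)
      p_ht[i] <- t
      log_ev(t, i, "arrive", cat_names()[c0])
      enqueue(ST_TRIAGE, i, t)
      sched_health(i, t)
    } else if (type == EV_END) {
      handle_end(id, t, aux)
    } else if (type == EV_HEALTH) {
      handle_health(id, t, aux)
    } else if (type == EV_ROUTINE_ARR) {
      routine_pending <- routine_pending + 1L
      sched(next_routine_candidate(t), EV_ROUTINE_ARR)
    } else if (type == EV_ROUTINE_END) {
      room_avail[RM_OR_CENTRAL] <- room_avail[RM_OR_CENTRAL] + 1L
      log_ev(t, 0L, "release", "central_or routine")
    }
    dispatch(now)
  }
  end_time <- now
  update_lock_busy(end_time)

  # greens (and any still-gathered patients) are discharged at the horizon
  still_in <- is.na(t_exit) & p_cat != CAT_BLACK
  t_exit[still_in] <- end_time

  # correct room-busy overshoot of routine cases running past the horizon
  over <- routine_ongoing_end[routine_ongoing_end > end_time]
  if (length(over))
    room_busy[RM_OR_CENTRAL] <- room_busy[RM_OR_CENTRAL] - sum(over - end_time)

  span <- max(end_time, 1e-12)
  util <- ifelse(room_cap > 0, pmin(1, room_busy / (room_cap * span)), NA_real_)
  names(util) <- room_names()
  wl <- ifelse(staff_cap > 0, pmin(1, staff_busy / (staff_cap * span)), NA_real_)
  names(wl) <- staff_categories()

  patients <- data.frame(
    id = seq_len(N), arrival = p_arr,
    initial_category = cat_names()[p_cat0],
    final_category = cat_names()[p_cat],
    health = p_h, needs_surgery = p_need_surg,
    deceased = p_cat == CAT_BLACK,
    triage_start = t_tri_s, triage_end = t_tri_e,
    first_treatment_start = t_ft_s, first_treatment_end = t_ft_e,
    imaging_start = t_img_s, imaging_end = t_img_e,
    surgery_start = t_surg_s, surgery_end = t_surg_e,
    exit_time = t_exit, death_time = t_death,
    stringsAsFactors = FALSE)

  out <- list(patients = patients, deaths = deaths, end_time = end_time,
              utilization = util, staff_workload = wl, seed = seed,
              n_events = n_events)
  if (log_events) {
    keep <- seq_len(lg_n)
    out$events <- data.frame(time = lg_t[keep], patient = lg_p[keep],
                             event = lg_e[keep], detail = lg_d[keep],
                             stringsAsFactors = FALSE)
  }
  class(out) <- "mci_replication"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mci_replication <- function(x, ...) {
  cat(sprintf("MCI replication: %d patients, %d deaths, horizon %.1f min, %d events\n",
              nrow(x$patients), x$deaths, x$end_time, x$n_events))
  invisible(x)
}
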