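#' @title Per-purpose random-number streams
#' @description
#' Each stochastic purpose of a replication (arrivals per triage category,
#' each service-time family, each Bernoulli decision, the routine workload)
#' draws from its own stream derived deterministically from the replication
#' seed. Streams advance independently, so two scenarios evaluated with the
#' same seeds consume identical substreams for their common purposes — the
#' common-random-numbers coupling used throughout the sweep and optimization
#' drivers.
#' @name streams
NULL

# canonical purpose order; the offset of a purpose is its position here
stream_purposes <- function() {
  c("arrival_red", "arrival_yellow", "arrival_green",
    "svc_triage", "svc_red_stabilization", "svc_yellow_exam", "svc_xray",
    "svc_ct", "svc_red_surgery", "svc_yellow_surgery", "svc_transfer_out",
    "svc_routine_case",
    "bern_surgery", "bern_imaging", "bern_ct_eligible",
    "routine_arrivals")
}

# a stream is an environment holding a saved .Random.seed state
new_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  e$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  e
}

# draw via `fun(n)` under the stream's state, then save the advanced state
stream_draw <- function(stream, n, fun) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", stream$state, globalenv())
  out <- fun(n)
  stream$state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  out
}

# derive the full stream set for one replication
make_streams <- function(master_seed, replication = 1L) {
  purposes <- stream_purposes()
  # independent 32-bit purpose seeds from a seed-derivation generator
  base <- new_stream((as.numeric(master_seed) * 747796405 +
                        as.numeric(replication) * 2891336453) %% 2147483629 + 1)
  seeds <- stream_draw(base, length(purposes),
                       function(k) sample.int(2147483646L, k, replace = TRUE))
  streams <- lapply(seeds, new_stream)
  names(streams) <- purposes
  streams
}
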