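#' Synchronization state of the computation/playback protocol
#'
#' The protocol keeps two clocks: \code{t_computed}, the leading edge of the
#' cached solution, and \code{t_visualization}, the playback position. The
#' backend computes the next block of length \code{dt} only while
#' \code{t_computed - t_visualization <= t_buffer}, so the buffer never
#' grows beyond \code{t_buffer + dt} and the backend stays responsive to
#' live interaction; between failed polls it waits a refractory period
#' \code{tau} of wall-clock time. Playback advances at \code{rate_normal}
#' simulated seconds per wall second (default 100 ms/s), dropping to
#' \code{rate_transition} (40 ms/s) while a stimulus transition or ablation
#' is in flight so the induced dynamics stay observable.
#'
#' @param t_computed,t_visualization initial clocks, s.
#' @param t_buffer allowed lead of computation over playback, s.
#' @param dt block (data stack) length, s.
#' @param tau refractory period between polls, wall-clock s.
#' @param rate_normal,rate_transition playback rates, simulated s per wall s.
#' @return object of class \code{"sync_state"}.
#' @export
sync_state <- function(t_computed = 0, t_visualization = 0,
                       t_buffer = 0.100, dt = 0.050, tau = 0.050,
                       rate_normal = 0.100, rate_transition = 0.040) {
  stopifnot(t_buffer > 0, dt > 0, tau > 0,
            t_visualization <= t_computed + 1e-12)
  structure(list(t_computed = t_computed,
                 t_visualization = t_visualization,
                 t_buffer = t_buffer, dt = dt, tau = tau,
                 rate_normal = rate_normal,
                 rate_transition = rate_transition),
            class = "sync_state")
}

#' Should the backend compute the next block?
#'
#' TRUE iff \code{t_computed - t_visualization <= t_buffer}.
#'
#' @param s a \code{\link{sync_state}}.
#' @return logical.
#' @export
should_compute <- function(s) {
  s$t_computed - s$t_visualization <= s$t_buffer + 1e-12
}

#' Run a buffered interactive session
#'
#' Drives the full computation/playback cycle in simulated (wall-clock-free)
#' time: poll the buffer condition, integrate the next block when it holds,
#' advance the playback clock at the configured rate otherwise, and repeat
#' until the playback reaches \code{duration}. Interaction enters through
#' \code{callback(t_block_start, view)}, invoked before each block is
#' computed; it may return a list of commands (each a list with
#' \code{type = "stimulus"} plus \code{neuron}, \code{amplitude_nA}, or
#' \code{type = "ablate"}/\code{"reinsert"} plus \code{neurons}) which are
#' applied exactly as a pre-declared event schedule would be. The protocol
#' buffers but never alters the dynamics: with the same event log the block
#' sequence is identical to \code{\link{integrate_session}}.
#'
#' In \code{headless} mode playback consumes each block instantly
#' (\code{t_visualization} tracks \code{t_computed}); otherwise the loop
#' models a consumer in discrete wall ticks of \code{tau}, with an optional
#' simulated computation cost per block, counting a stutter whenever
#' playback wants to advance but finds an empty buffer
#' (\code{t_visualization = t_computed}).
#'
#' @inheritParams integrate_session
#' @param sync a \code{\link{sync_state}} (its \code{dt} should equal
#'   \code{cfg$block_dt}).
#' @param callback optional interaction callback, see above.
#' @param headless TRUE for instant playback (protocol-transparency mode).
#' @param compute_time simulated wall seconds the backend needs per block
#'   (only used when \code{headless = FALSE}).
#' @return a \code{"session_timeline"} whose \code{sync}, \code{stutters}
#'   and \code{desync} fields record the protocol trace; the buffer bound
#'   \code{t_computed - t_visualization <= t_buffer + dt} is asserted at
#'   every iteration.
#' @export
run_session <- function(duration, c, p, sched, cfg,
                        sync = sync_state(dt = cfg$block_dt),
                        callback = NULL, state = NULL,
                        headless = TRUE, compute_time = 0) {
  stopifnot(duration > 0)
  if (is.null(state)) state <- init_state(p$n, cfg$seed)
  eng <- .new_engine(c, p, sched, cfg, state)
  sync$t_computed <- state$t
  sync$t_visualization <- state$t
  t_end <- state$t + duration
  eps <- 1e-9

  stutters <- 0L
  desync <- numeric()
  remaining_compute <- NA_real_  # NA: no block in progress

  compute_next <- function() {
    # nominal block-start time, snapped to the block grid so that events a
    # callback adds here coincide exactly with a pre-declared schedule
    t0 <- .quantize_up(eng$state$t, eng$t0, eng$cfg$block_dt)
    if (!is.null(callback)) {
      cmds <- callback(t0, list(t_computed = sync$t_computed,
                                t_visualization = sync$t_visualization,
                                sched = eng$sched,
                                active = eng$conn$active))
      for (cmd in cmds) {
        if (cmd$type == "stimulus") {
          .engine_add_stimulus(eng, cmd$neuron, cmd$amplitude_nA, t0)
        } else {
          .engine_add_structural(eng, cmd$type, cmd$neurons, t0)
        }
      }
    }
    .engine_step(eng)
  }

  if (headless) {
    while (sync$t_computed < t_end - eps) {
      if (should_compute(sync)) {
        compute_next()
        sync$t_computed <- sync$t_computed + sync$dt
      }
      sync$t_visualization <- sync$t_computed
      lead <- sync$t_computed - sync$t_visualization
      stopifnot(lead <= sync$t_buffer + sync$dt + eps)
      desync <- c(desync, lead)
    }
  } else {
    while (sync$t_visualization < t_end - eps) {
      # one wall tick of tau: playback advances, then the backend works
      rate <- if (transition_in_flight(eng$sched, sync$t_visualization) ||
                  length(eng$structural)) {
        sync$rate_transition
      } else {
        sync$rate_normal
      }
      target <- sync$t_visualization + rate * sync$tau
      new_vis <- min(target, sync$t_computed, t_end)
      if (new_vis < target - eps && sync$t_computed < t_end - eps &&
          abs(new_vis - sync$t_computed) < eps) {
        stutters <- stutters + 1L  # buffer empty: playback pauses
      }
      sync$t_visualization <- new_vis

      if (!is.na(remaining_compute)) {
        remaining_compute <- remaining_compute - sync$tau
        if (remaining_compute <= eps) {
          sync$t_computed <- sync$t_computed + sync$dt
          remaining_compute <- NA_real_
        }
      } else if (should_compute(sync) && sync$t_computed < t_end - eps) {
        compute_next()
        if (compute_time <= 0) {
          sync$t_computed <- sync$t_computed + sync$dt
        } else {
          remaining_compute <- compute_time
        }
      }
      lead <- sync$t_computed - sync$t_visualization
      stopifnot(lead >= -eps, lead <= sync$t_buffer + sync$dt + eps)
      desync <- c(desync, lead)
    }
  }
  .engine_timeline(eng, sync = sync, stutters = stutters, desync = desync)
}

#' Seek to a time point in a computed timeline
#'
#' Implements the review-system time bar: returns the cached sample at the
#' output-grid point nearest \code{t} (ties resolve to the earlier sample).
#' Resuming playback from a seek continues from cached data; nothing is
#' recomputed.
#'
#' @param tl a session timeline.
#' @param t requested time, s; must lie within the computed range.
#' @return list with \code{state} (a \code{\link{network_state}} at the
#'   snapped time), \code{index} into the sample grid, and \code{time}.
#' @export
seek <- function(tl, t) {
  sm <- timeline_samples(tl)
  if (t < sm$times[1] - 1e-9 || t > sm$times[length(sm$times)] + 1e-9) {
    stop("seek time outside computed range")
  }
  # nearest grid index, half-way points resolving to the earlier sample
  dt <- tl$cfg$output_dt
  i <- 1L + floor((t - sm$times[1]) / dt + 0.5 - 1e-9)
  i <- max(1L, min(length(sm$times), i))
  list(state = network_state(sm$times[i], sm$V[i, ], sm$s[i, ]),
       index = i, time = sm$times[i])
}

#' Playback lag metric
#'
#' Scalar figure of merit for a protocol configuration: the product of the
#' aggregated desynchronization (computed-minus-visualized time; mean or
#' max over a session, caller's choice) and the stutter count (playback
#' steps that found an empty buffer). Lower is better; a session with no
#' stutters scores 0.
#'
#' @param desync aggregated desynchronization, s.
#' @param stutters stutter count.
#' @return \code{desync * stutters}.
#' @export
lag_metric <- function(desync, stutters) {
  stopifnot(desync >= 0, stutters >= 0)
  desync * stutters
}
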