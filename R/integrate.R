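#' Network state
#'
#' The instantaneous state of the dynome: per-neuron membrane voltage
#' \code{V} (mV) and synaptic activity \code{s} (dimensionless, in [0, 1]),
#' at time \code{t}. For N neurons the ODE system has 2N dimensions.
#'
#' @param t time, s.
#' @param V N-vector of voltages, mV.
#' @param s N-vector of synaptic activities.
#' @return object of class \code{"network_state"}.
#' @export
network_state <- function(t, V, s) {
  stopifnot(length(V) == length(s))
  structure(list(t = t, V = as.numeric(V), s = as.numeric(s)),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network_state> t=%.3f s  n=%d  V in [%.3f, %.3f] mV\n",
              x$t, length(x$V), min(x$V), max(x$V)))
  invisible(x)
}

#' Solver configuration
#'
#' Tolerances and grids for the adaptive integrator: relative tolerance
#' 1e-9, absolute tolerance 1e-10, minimum step 1e-9 s (the step size itself
#' is chosen adaptively), uniform output sampling every 10 ms, and solution
#' blocks of 50 ms (the data-stack length of the playback protocol). The
#' output grid must divide the block length evenly.
#'
#' @param rtol,atol relative/absolute integration tolerances.
#' @param min_step minimum internal step, s.
#' @param output_dt uniform sampling interval, s.
#' @param block_dt block (data stack) length, s.
#' @param seed integer seed for the initial-condition draw.
#' @return object of class \code{"solver_config"}.
#' @export
solver_config <- function(rtol = 1e-9, atol = 1e-10, min_step = 1e-9,
                          output_dt = 0.010, block_dt = 0.050, seed = 1L) {
  stopifnot(rtol > 0, atol > 0, min_step > 0, output_dt > 0, block_dt > 0)
  k <- block_dt / output_dt
  if (abs(k - round(k)) > 1e-9) {
    stop("output_dt must divide block_dt evenly")
  }
  structure(list(rtol = rtol, atol = atol, min_step = min_step,
                 output_dt = output_dt, block_dt = block_dt,
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Draw the standard initial condition
#'
#' Voltages and synaptic activities are initialized with i.i.d. draws from
#' Normal(0, 0.94) scaled by 1e-4 (a 2N-sized draw, V first), i.e. the
#' network starts within a fraction of a microvolt of 0. The s components
#' are clamped into [0, 1] to satisfy the activity invariant; at the 1e-4
#' scale this changes nothing at reported precision. Deterministic given
#' \code{seed}; the caller's RNG state is left untouched.
#'
#' @param n neuron count.
#' @param seed integer seed.
#' @return a \code{\link{network_state}} at t = 0.
#' @export
init_state <- function(n, seed = 1L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  x <- stats::rnorm(2L * n, mean = 0, sd = 0.94) * 1e-4
  network_state(0, x[seq_len(n)], pmin(pmax(x[n + seq_len(n)], 0), 1))
}

#' Integrate one solution block
#'
#' Advances the dynome over \code{[state$t, state$t + block_dt]} with an
#' adaptive stiff-capable solver (\code{deSolve::ode}, lsoda), honouring
#' the configured tolerances and minimum step, and samples the dense
#' solution on the uniform \code{output_dt} grid. Stimulus amplitudes are
#' evaluated continuously at the solver's internal times through the
#' schedule's tanh transitions, so no discontinuity handling is needed
#' inside a block; structural (ablation) events are applied between blocks.
#' The result is reproducible bit-identically for identical inputs.
#'
#' @param state a \code{\link{network_state}} at the block start.
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{model_params}}.
#' @param sched a \code{\link{stimulus_schedule}}.
#' @param cfg a \code{\link{solver_config}}.
#' @param vth threshold potentials used inside the activation sigmoid;
#'   computed from the schedule at block start when NULL.
#' @param block_dt override of the block length (defaults to
#'   \code{cfg$block_dt}; must be a multiple of \code{cfg$output_dt}).
#' @return object of class \code{"solution_block"}: \code{t_start},
#'   \code{t_end}, \code{times}, \code{V} and \code{s} sample matrices
#'   (rows = times), and \code{end_state}.
#' @export
integrate_block <- function(state, c, p, sched, cfg, vth = NULL,
                            block_dt = cfg$block_dt) {
  n <- p$n
  stopifnot(length(state$V) == n)
  if (!all(is.finite(state$V)) || !all(is.finite(state$s))) {
    stop("non-finite state at block start t=", state$t)
  }
  if (is.null(vth)) {
    vth <- compute_vth(c, p, evaluate_stimulus(sched, state$t))
  }
  m <- .norm_model(c, p)
  nsteps <- round(block_dt / cfg$output_dt)
  times <- state$t + cfg$output_dt * (0:nsteps)

  func <- function(t, y, parms) {
    d <- .rhs_core(y[seq_len(n)], y[n + seq_len(n)], m,
                   evaluate_stimulus(sched, t), vth)
    list(c(d$dV, d$ds))
  }
  out <- deSolve::ode(y = c(state$V, state$s), times = times, func = func,
                      parms = NULL, method = "lsoda",
                      rtol = cfg$rtol, atol = cfg$atol, hmin = cfg$min_step,
                      tcrit = times[length(times)])
  if (!all(is.finite(out))) {
    bad <- which(rowSums(!is.finite(out)) > 0)[1]
    stop("non-finite solution encountered near t=", times[bad])
  }
  V <- unname(out[, 1 + seq_len(n), drop = FALSE])
  s <- unname(out[, 1 + n + seq_len(n), drop = FALSE])
  structure(list(
    t_start = state$t, t_end = times[length(times)], times = times,
    V = V, s = s,
    end_state = network_state(times[length(times)],
                              V[nrow(V), ], s[nrow(s), ])
  ), class = "solution_block")
}

#' Apply a structural event (ablation or reinsertion)
#'
#' Structural changes are instantaneous edits of the connectivity matrices,
#' followed by recalculation of the structure-dependent quantities — here
#' the threshold potentials. The state vector is untouched: an ablated
#' neuron's voltage keeps evolving under leak (and any stimulus), since its
#' couplings are zero.
#'
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{model_params}}.
#' @param event list with \code{type} (\code{"ablate"} or
#'   \code{"reinsert"}) and \code{neurons} (names or indices).
#' @param I_ext current external input (arb) used in the threshold solve.
#' @return list with the edited \code{connectome} and recomputed \code{vth}.
#' @export
apply_structural_event <- function(c, p, event, I_ext = 0) {
  c <- switch(event$type,
              ablate = ablate(c, event$neurons),
              reinsert = reinsert(c, event$neurons),
              stop("unknown structural event type: ", event$type))
  list(connectome = c, vth = compute_vth(c, p, I_ext))
}

# ---- shared session engine -------------------------------------------------
#
# Both the offline integrator and the buffered playback session step the
# simulation through this engine, so the playback protocol cannot alter the
# computed dynamics: for the same event log the block sequence is identical
# by construction. Structural events are quantized to the next block
# boundary; stimulus changes keep their exact switch time (they are
# continuous in t). Threshold potentials are recomputed at every structural
# event and at the first block boundary after each stimulus transition
# completes (t_switch + 2 * t_offset).

.quantize_up <- function(t, t0, dt) {
  t0 + ceiling((t - t0) / dt - 1e-9) * dt
}

.new_engine <- function(c, p, sched, cfg, state) {
  eng <- new.env(parent = emptyenv())
  eng$conn <- c
  eng$params <- p
  eng$sched <- sched
  eng$cfg <- cfg
  eng$state <- state
  eng$t0 <- state$t
  eng$blocks <- list()
  eng$event_log <- list()
  eng$structural <- list()
  eng$vth_times <- numeric()
  eng$vth <- compute_vth(c, p, evaluate_stimulus(sched, state$t))
  eng
}

.engine_add_stimulus <- function(eng, neuron, amplitude_nA, t) {
  eng$sched <- set_stimulus(eng$sched, neuron, amplitude_nA, t_now = t)
  eng$event_log[[length(eng$event_log) + 1L]] <-
    list(t = t, type = "stimulus", neuron = neuron,
         amplitude_nA = amplitude_nA)
  if (t <= 0) {
    eng$vth <- compute_vth(eng$conn, eng$params,
                           evaluate_stimulus(eng$sched, eng$t0))
  } else {
    ev <- eng$sched$events[[length(eng$sched$events)]]
    done <- t + 2 * ev$t_offset
    eng$vth_times <- c(eng$vth_times,
                       .quantize_up(done, eng$t0, eng$cfg$block_dt))
  }
  invisible(eng)
}

.engine_add_structural <- function(eng, type, neurons, t) {
  tb <- .quantize_up(t, eng$t0, eng$cfg$block_dt)
  eng$structural[[length(eng$structural) + 1L]] <-
    list(t = tb, type = type, neurons = neurons)
  eng$event_log[[length(eng$event_log) + 1L]] <-
    list(t = t, type = type, neurons = neurons, t_applied = tb)
  invisible(eng)
}

.engine_step <- function(eng) {
  tb <- eng$state$t
  eps <- 1e-9
  recompute <- FALSE
  if (length(eng$structural)) {
    due <- vapply(eng$structural, function(e) e$t <= tb + eps, logical(1))
    for (e in eng$structural[due]) {
      eng$conn <- switch(e$type,
                         ablate = ablate(eng$conn, e$neurons),
                         reinsert = reinsert(eng$conn, e$neurons))
      recompute <- TRUE
    }
    eng$structural <- eng$structural[!due]
  }
  if (any(eng$vth_times <= tb + eps)) {
    recompute <- TRUE
    eng$vth_times <- eng$vth_times[eng$vth_times > tb + eps]
  }
  if (recompute) {
    eng$vth <- compute_vth(eng$conn, eng$params,
                           evaluate_stimulus(eng$sched, tb))
  }
  blk <- integrate_block(eng$state, eng$conn, eng$params, eng$sched,
                         eng$cfg, vth = eng$vth)
  eng$blocks[[length(eng$blocks) + 1L]] <- blk
  eng$state <- blk$end_state
  invisible(eng)
}

.engine_timeline <- function(eng, sync = NULL, stutters = NULL,
                             desync = NULL) {
  structure(list(
    blocks = eng$blocks, event_log = eng$event_log,
    connectome = eng$conn, params = eng$params, sched = eng$sched,
    cfg = eng$cfg, vth = eng$vth,
    sync = sync, stutters = stutters, desync = desync
  ), class = "session_timeline")
}

#' Offline integration of a session
#'
#' Integrates the dynome over \code{[state$t, state$t + duration]} in
#' contiguous blocks, applying a pre-declared event schedule: stimulus
#' changes at their exact times (continuous tanh transitions) and
#' structural events at the next block boundary. This is the reference
#' against which the buffered \code{\link{run_session}} is byte-identical.
#'
#' @inheritParams integrate_block
#' @param duration simulated time to cover, s (a whole number of blocks).
#' @param events list of events, each a list with \code{t} and \code{type}
#'   (\code{"stimulus"} with \code{neuron}, \code{amplitude_nA};
#'   \code{"ablate"}/\code{"reinsert"} with \code{neurons}).
#' @param state starting \code{\link{network_state}}; drawn via
#'   \code{\link{init_state}} with \code{cfg$seed} when NULL.
#' @return a \code{"session_timeline"}: contiguous \code{blocks}, the
#'   \code{event_log}, and the final connectome/schedule/thresholds.
#' @export
integrate_session <- function(duration, c, p, sched, cfg,
                              events = list(), state = NULL) {
  stopifnot(duration > 0)
  if (is.null(state)) state <- init_state(p$n, cfg$seed)
  eng <- .new_engine(c, p, sched, cfg, state)
  if (length(events)) {
    ord <- order(vapply(events, `[[`, numeric(1), "t"))
    for (e in events[ord]) {
      if (e$type == "stimulus") {
        .engine_add_stimulus(eng, e$neuron, e$amplitude_nA, e$t)
      } else {
        .engine_add_structural(eng, e$type, e$neurons, e$t)
      }
    }
  }
  n_blocks <- round(duration / cfg$block_dt)
  for (i in seq_len(n_blocks)) .engine_step(eng)
  .engine_timeline(eng)
}

#' @export
print.session_timeline <- function(x, ...) {
  tspan <- if (length(x$blocks)) {
    c(x$blocks[[1]]$t_start, x$blocks[[length(x$blocks)]]$t_end)
  } else c(NA, NA)
  cat(sprintf("<session_timeline> %d blocks over [%.3f, %.3f] s, %d events\n",
              length(x$blocks), tspan[1], tspan[2], length(x$event_log)))
  if (!is.null(x$stutters)) {
    cat(sprintf("  playback: %d stutters, mean desync %.4f s\n",
                x$stutters, mean(x$desync)))
  }
  invisible(x)
}

#' Assemble the uniform sample grid of a timeline
#'
#' Concatenates the blocks' samples, dropping the duplicated boundary
#' sample between consecutive blocks.
#'
#' @param tl a session timeline.
#' @return list with \code{times}, \code{V} and \code{s} (rows = times).
#' @export
timeline_samples <- function(tl) {
  stopifnot(length(tl$blocks) > 0)
  times <- tl$blocks[[1]]$times
  V <- tl$blocks[[1]]$V
  s <- tl$blocks[[1]]$s
  for (b in tl$blocks[-1]) {
    keep <- -1L  # first row duplicates previous block's last
    times <- c(times, b$times[keep])
    V <- rbind(V, b$V[keep, , drop = FALSE])
    s <- rbind(s, b$s[keep, , drop = FALSE])
  }
  list(times = times, V = V, s = s)
}

#' Export a timeline's sampled dynamics
#'
#' Writes the time-by-2N sample array (voltages then synaptic activities)
#' as npy — the format of the original release's saved dynamics — or as a
#' CSV with named columns, plus the event log as JSON for exact replay.
#'
#' @param tl a session timeline.
#' @param path output directory.
#' @param format \code{"npy"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
save_dynamics <- function(tl, path, format = c("npy", "csv")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sm <- timeline_samples(tl)
  if (format == "npy") {
    write_npy(cbind(sm$V, sm$s), file.path(path, "dynamics.npy"))
    write_npy(sm$times, file.path(path, "times.npy"))
  } else {
    df <- data.frame(time = sm$times, sm$V, sm$s, check.names = FALSE)
    names(df) <- c("time",
                   paste0("V_", tl$connectome$roster$name),
                   paste0("s_", tl$connectome$roster$name))
    utils::write.csv(df, file.path(path, "dynamics.csv"), row.names = FALSE)
  }
  jsonlite::write_json(tl$event_log, file.path(path, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
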