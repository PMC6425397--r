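#' Smooth stimulus transition events
#'
#' When an injected current changes during a simulation, the new amplitude
#' is reached through a smooth blend of two hyperbolic tangents rather than
#' a jump:
#' \deqn{S(t) = S_{old}\,(1 - u) + S_{new}\,u,\quad
#'       u = \tfrac12\left(1 + \tanh\frac{t - (t_{switch} + t_{offset})}{r}\right)}
#' With the defaults \code{t_offset = 0.150} s and \code{r = 0.025} s the
#' blend is centred 150 ms after the switch and is complete (to within
#' \code{tanh(6) ~ 1 - 5e-6}) at \code{t_switch + 2 * t_offset}, i.e. the
#' transitional period is about 300 ms.
#'
#' @param neuron neuron index (1-based).
#' @param S_old,S_new amplitudes before/after, arb units.
#' @param t_switch time the change was requested, s.
#' @param t_offset transition midpoint delay, s.
#' @param r transition width, s.
#' @return object of class \code{"transition_event"}.
#' @export
transition_event <- function(neuron, S_old, S_new, t_switch,
                             t_offset = 0.150, r = 0.025) {
  stopifnot(t_offset > 0, r > 0)
  structure(list(neuron = as.integer(neuron), S_old = S_old, S_new = S_new,
                 t_switch = t_switch, t_offset = t_offset, r = r),
            class = "transition_event")
}

#' Evaluate a transition at time t
#'
#' @param t time, s (vectorized).
#' @param e a \code{\link{transition_event}}.
#' @return amplitude(s) in the units of \code{S_old}/\code{S_new}; monotone
#'   in \code{t} when the two amplitudes differ.
#' @export
transition_value <- function(t, e) {
  u <- 0.5 * (1 + tanh((t - (e$t_switch + e$t_offset)) / e$r))
  e$S_old * (1 - u) + e$S_new * u
}

#' Stimulus schedules
#'
#' A schedule holds a piecewise-constant baseline of injected currents (arb
#' units, one per neuron) plus a time-ordered list of
#' \code{\link{transition_event}}s. At any time \code{t} each neuron's
#' amplitude is governed by its latest event with \code{t_switch <= t}
#' (evaluated through \code{\link{transition_value}}), or by the baseline if
#' no event has fired yet. A new event supersedes an in-flight one by
#' reading its \code{S_old} from the currently evaluated value, so rapid
#' consecutive changes stay continuous.
#'
#' @param n neuron count.
#' @param baseline_nA baseline amplitudes in nA (scalar or N-vector).
#' @return object of class \code{"stimulus_schedule"}.
#' @export
stimulus_schedule <- function(n, baseline_nA = 0) {
  structure(list(n = as.integer(n),
                 baseline = nA_to_arb(rep_len(baseline_nA, n)),
                 events = list()),
            class = "stimulus_schedule")
}

#' Change a neuron's stimulus
#'
#' Before the run starts (\code{t_now <= 0}) the baseline is set directly;
#' during a run a \code{\link{transition_event}} is appended whose
#' \code{S_old} is the schedule's evaluated amplitude at \code{t_now}, so
#' the injected current is continuous through the change.
#'
#' @param sched a \code{\link{stimulus_schedule}}.
#' @param neuron neuron index (1-based) or name resolved beforehand.
#' @param amplitude new amplitude.
#' @param t_now current simulation time, s; \code{<= 0} means "before start".
#' @param units \code{"nA"} (default, the panel unit) or \code{"arb"}.
#' @param t_offset,r transition parameters, s.
#' @return the updated schedule.
#' @export
set_stimulus <- function(sched, neuron, amplitude, t_now = 0,
                         units = c("nA", "arb"),
                         t_offset = 0.150, r = 0.025) {
  units <- match.arg(units)
  neuron <- as.integer(neuron)
  if (neuron < 1L || neuron > sched$n) stop("neuron index out of range")
  amp <- if (units == "nA") nA_to_arb(amplitude) else amplitude
  if (t_now <= 0) {
    sched$baseline[neuron] <- amp
    return(sched)
  }
  s_old <- evaluate_stimulus(sched, t_now)[neuron]
  ev <- transition_event(neuron, s_old, amp, t_now, t_offset, r)
  sched$events[[length(sched$events) + 1L]] <- ev
  ord <- order(vapply(sched$events, `[[`, numeric(1), "t_switch"))
  sched$events <- sched$events[ord]
  sched
}

#' Evaluate the full stimulus vector at time t
#'
#' @param sched a \code{\link{stimulus_schedule}}.
#' @param t time, s.
#' @return N-vector of amplitudes in arb units.
#' @export
evaluate_stimulus <- function(sched, t) {
  amp <- sched$baseline
  for (e in sched$events) {       # time-ordered; later events supersede
    # strictly after the switch: an event contributes nothing before (or
    # at) its own switch time, so declaring it ahead of time is exactly
    # equivalent to adding it live at t_switch
    if (e$t_switch < t) amp[e$neuron] <- transition_value(t, e)
  }
  amp
}

#' Is any stimulus transition still in flight at time t?
#'
#' Used by the playback protocol to slow the visualization rate during
#' transitions. An event counts as in flight from its switch until
#' \code{t_switch + 2 * t_offset}.
#'
#' @inheritParams evaluate_stimulus
#' @return logical.
#' @export
transition_in_flight <- function(sched, t) {
  for (e in sched$events) {
    if (t >= e$t_switch && t <= e$t_switch + 2 * e$t_offset) return(TRUE)
  }
  FALSE
}

#' Presets: named stimulus/ablation configurations
#'
#' A preset captures a panel configuration — stimulus amplitudes in nA per
#' neuron name plus a set of ablated neurons — and round-trips losslessly
#' through JSON.
#'
#' @param name preset name.
#' @param stimuli_nA named list/vector, neuron name -> amplitude in nA.
#' @param ablated character vector of ablated neuron names.
#' @return object of class \code{"preset"}.
#' @export
preset <- function(name, stimuli_nA = list(), ablated = character()) {
  structure(list(name = name,
                 stimuli_nA = as.list(stimuli_nA),
                 ablated = as.character(ablated)),
            class = "preset")
}

#' @param p a \code{\link{preset}}.
#' @param path JSON file path.
#' @rdname preset
#' @export
save_preset <- function(p, path) {
  jsonlite::write_json(
    list(name = p$name, stimuli_nA = p$stimuli_nA,
         ablated = as.list(p$ablated)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param roster optional roster data frame; when given, neuron names in the
#'   preset are validated against it and unknown names raise an error.
#' @rdname preset
#' @export
load_preset <- function(path, roster = NULL) {
  x <- jsonlite::fromJSON(path)
  p <- preset(x$name, x$stimuli_nA, unlist(x$ablated))
  if (!is.null(roster)) {
    nm <- c(names(p$stimuli_nA), p$ablated)
    bad <- setdiff(nm, roster$name)
    if (length(bad)) stop("preset names not in roster: ",
                          paste(bad, collapse = ", "))
  }
  p
}

#' Apply a preset to a connectome and schedule
#'
#' Ablates the preset's neurons and sets its stimuli as the schedule
#' baseline (before the run starts).
#'
#' @param c a \code{\link{connectome}}.
#' @param p a \code{\link{preset}}.
#' @param sched optional existing schedule (defaults to an all-zero one).
#' @return list with elements \code{connectome} and \code{schedule}.
#' @export
apply_preset <- function(c, p, sched = stimulus_schedule(c$n)) {
  if (length(p$ablated)) c <- ablate(c, p$ablated)
  for (nm in names(p$stimuli_nA)) {
    idx <- resolve_neurons(c, nm)
    sched <- set_stimulus(sched, idx, p$stimuli_nA[[nm]], t_now = 0)
  }
  list(connectome = c, schedule = sched)
}
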