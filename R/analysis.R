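#' Estimate the oscillation period of a sampled trace
#'
#' Spectrally guided autocorrelation estimator. The fundamental is first
#' localized in the periodogram (taking a subharmonic instead when a lower
#' frequency bin carries a substantial share of the peak power, so
#' harmonic-rich waveforms do not report a fraction of their cycle). The
#' trace must be aperiodicity-gated: the raw autocorrelation near the
#' candidate lag has to reach \code{min_corr}, otherwise \code{NA} is
#' returned (noise that happens to have a spectral maximum somewhere is
#' rejected here). The trace is then low-pass filtered just above the
#' fundamental to strip faster ripples and most of the noise, and the
#' period is read off as the autocorrelation peak of the filtered signal
#' near the candidate lag, refined by parabolic interpolation. Returns
#' \code{NA} for constant or aperiodic traces.
#'
#' @param x numeric trace, uniformly sampled; should span at least ~4
#'   cycles of any oscillation to be resolved.
#' @param dt sampling interval, s.
#' @param min_corr minimum raw autocorrelation near the candidate period
#'   for the trace to count as periodic.
#' @return period in seconds, or \code{NA_real_}.
#' @export
estimate_period <- function(x, dt, min_corr = 0.2) {
  n <- length(x)
  if (n < 8L) stop("trace too short for period estimation")
  if (stats::sd(x) == 0) return(NA_real_)
  x <- x - mean(x)

  # fundamental from the periodogram; bin k means k - 1 cycles per window
  pw <- Mod(stats::fft(x))^2
  k_lo <- 4L                       # at least 3 full cycles in the window
  k_hi <- floor(n / 2)
  if (k_hi <= k_lo) stop("trace too short for period estimation")
  kp <- k_lo - 1L + which.max(pw[k_lo:k_hi])
  for (d in c(3L, 2L)) {           # prefer the lowest plausible subharmonic
    ks <- round((kp - 1L) / d) + 1L
    cand <- max(k_lo, ks - 1L):(ks + 1L)
    if (ks >= k_lo && max(pw[cand]) >= 0.2 * pw[kp]) {
      kp <- cand[which.max(pw[cand])]
      break
    }
  }
  L0 <- n / (kp - 1L)              # candidate period in samples

  lag_max <- min(n - 2L, ceiling(1.5 * L0))
  win <- max(2L, floor(0.5 * L0)):lag_max
  a_raw <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                                 demean = FALSE)$acf)
  if (max(a_raw[1L + win]) < min_corr) return(NA_real_)

  # low-pass just above the fundamental, then locate the ACF peak
  keep <- floor(1.5 * (kp - 1L)) + 1L
  fx <- stats::fft(x)
  kill <- (keep + 1L):(n - keep + 1L)
  fx[kill[kill >= 1L & kill <= n]] <- 0
  xf <- Re(stats::fft(fx, inverse = TRUE)) / n
  a <- as.numeric(stats::acf(xf, lag.max = lag_max, plot = FALSE,
                             demean = FALSE)$acf)
  sel <- win[which.max(a[1L + win])]
  if (sel <= 1L || sel >= lag_max) return(NA_real_)
  y1 <- a[sel]; y2 <- a[sel + 1L]; y3 <- a[sel + 2L]
  denom <- y1 - 2 * y2 + y3
  delta <- if (abs(denom) > .Machine$double.eps) {
    0.5 * (y1 - y3) / denom
  } else 0
  (sel + delta) * dt
}

#' Phase difference between two periodic traces
#'
#' Finds the shift (within half a period either way) that maximizes the
#' correlation between the traces and converts it to radians in
#' \code{(-pi, pi]}. Positive phase means \code{b} lags \code{a}. Identical
#' traces give 0; a trace against its negation gives pi.
#'
#' @param a,b numeric traces, same sampling.
#' @param period shared oscillation period, s.
#' @param dt sampling interval, s.
#' @return phase in radians.
#' @export
phase_difference <- function(a, b, period, dt) {
  if (is.na(period) || period <= 0) stop("phase requires a periodic input")
  n <- length(a)
  stopifnot(length(b) == n)
  L <- round(period / dt)
  half <- floor(L / 2)
  lags <- -half:half
  r <- vapply(lags, function(l) {
    if (l >= 0) {
      ia <- 1:(n - l); ib <- (1 + l):n
    } else {
      ia <- (1 - l):n; ib <- 1:(n + l)
    }
    suppressWarnings(stats::cor(a[ia], b[ib]))
  }, numeric(1))
  r[is.na(r)] <- -Inf
  shift <- lags[which.max(r)]
  phi <- 2 * pi * shift / L
  if (phi <= -pi) phi <- phi + 2 * pi
  if (phi > pi) phi <- phi - 2 * pi
  phi
}

#' Responsive neurons and active fraction
#'
#' A neuron is responsive when its maximum absolute threshold-relative
#' voltage excursion over the analysis window reaches \code{threshold_mV}.
#' The active fraction is the number of responsive neurons over the number
#' of non-ablated neurons. The cut-off is a reporting choice (default 5 mV);
#' responsive sets should be read qualitatively.
#'
#' @param V time-by-N voltage sample matrix, mV.
#' @param vth per-neuron thresholds, mV.
#' @param active logical mask of non-ablated neurons.
#' @param names neuron names.
#' @param threshold_mV responsiveness cut-off, mV (> 0).
#' @return list with \code{responsive} (character vector),
#'   \code{amplitude} (named per-neuron max excursions) and
#'   \code{active_fraction}.
#' @export
responsive_neurons <- function(V, vth, active, names,
                               threshold_mV = 5) {
  stopifnot(threshold_mV > 0)
  amp <- apply(abs(sweep(V, 2, vth)), 2, max)
  names(amp) <- names
  resp <- active & amp >= threshold_mV
  list(responsive = names[resp],
       amplitude = amp,
       active_fraction = if (sum(active)) sum(resp) / sum(active) else 0)
}

#' Scenario specification
#'
#' A named stimulation/ablation experiment: stimulus amplitudes in nA per
#' neuron name, a set of ablated neurons, the simulated duration, and a
#' settle time discarded before analysis so transients do not contaminate
#' period estimates.
#'
#' @param name scenario label.
#' @param stimuli_nA named list, neuron name -> amplitude in nA.
#' @param ablated character vector of neuron names to ablate.
#' @param duration simulated time, s.
#' @param settle_time discarded initial transient, s
#'   (\code{< duration}).
#' @param seed seed for the initial-condition draw.
#' @return object of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(name, stimuli_nA = list(), ablated = character(),
                          duration = 30, settle_time = 10, seed = 42L) {
  stopifnot(duration > settle_time, settle_time >= 0)
  structure(list(name = name, stimuli_nA = as.list(stimuli_nA),
                 ablated = as.character(ablated),
                 duration = duration, settle_time = settle_time,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Expand a neuron class name to its roster members
#'
#' Stimulation protocols address cell classes ("PLM", "AVB", "IL2"); each
#' class expands to all roster names sharing the prefix (e.g. PLML/PLMR),
#' every member receiving the stated amplitude. Names already present in
#' the roster pass through unchanged.
#'
#' @param roster_names character vector of roster names.
#' @param class class or neuron name.
#' @return character vector of matching roster names.
#' @export
expand_neuron_class <- function(roster_names, class) {
  if (class %in% roster_names) return(class)
  hits <- roster_names[startsWith(roster_names, class)]
  if (!length(hits)) stop("no neurons match class: ", class)
  hits
}

#' Run a stimulation/ablation scenario
#'
#' Applies the scenario's ablations, sets its stimuli as the baseline
#' (class names are expanded to all members), integrates for the full
#' duration from the standard initial condition, discards the settle
#' window, and characterizes the remaining dynamics: per-neuron oscillation
#' periods, phases relative to a reference neuron (the most responsive
#' one), the responsive set with its active fraction, and a circuit-level
#' consensus period (median over responsive motor neurons when any, else
#' over all responsive neurons). Deterministic given the spec's seed.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{model_params}} (defaults from the connectome).
#' @param cfg a \code{\link{solver_config}}.
#' @param threshold_mV responsiveness cut-off, mV.
#' @return object of class \code{"scenario_result"} with fields
#'   \code{times}, \code{V} (post-settle traces), \code{periods},
#'   \code{phases}, \code{responsive}, \code{active_fraction},
#'   \code{consensus_period}, \code{reference}, \code{vth},
#'   \code{timeline}.
#' @export
run_scenario <- function(spec, c, p = model_params(c),
                         cfg = solver_config(seed = spec$seed),
                         threshold_mV = 5) {
  if (length(spec$ablated)) {
    abl <- unlist(lapply(spec$ablated,
                         function(x) expand_neuron_class(c$roster$name, x)))
    c <- ablate(c, abl)
  }
  sched <- stimulus_schedule(c$n)
  for (nm in names(spec$stimuli_nA)) {
    for (member in expand_neuron_class(c$roster$name, nm)) {
      sched <- set_stimulus(sched, resolve_neurons(c, member),
                            spec$stimuli_nA[[nm]], t_now = 0)
    }
  }
  cfg$seed <- spec$seed
  tl <- integrate_session(spec$duration, c, p, sched, cfg)
  sm <- timeline_samples(tl)
  keep <- sm$times >= spec$settle_time - 1e-9
  times <- sm$times[keep]
  V <- sm$V[keep, , drop = FALSE]
  dt <- cfg$output_dt

  resp <- responsive_neurons(V, tl$vth, c$active, c$roster$name,
                             threshold_mV)
  periods <- rep(NA_real_, c$n)
  names(periods) <- c$roster$name
  for (i in which(c$roster$name %in% resp$responsive)) {
    periods[i] <- estimate_period(V[, i], dt)
  }
  motor_resp <- resp$responsive[
    resp$responsive %in% c$roster$name[c$roster$group == "motor"]]
  consensus <- if (length(motor_resp)) {
    stats::median(periods[motor_resp], na.rm = TRUE)
  } else if (length(resp$responsive)) {
    stats::median(periods[resp$responsive], na.rm = TRUE)
  } else {
    NA_real_
  }

  reference <- if (length(resp$responsive)) {
    resp$responsive[which.max(resp$amplitude[resp$responsive])]
  } else {
    NA_character_
  }
  phases <- rep(NA_real_, c$n)
  names(phases) <- c$roster$name
  if (!is.na(reference) && !is.na(consensus)) {
    ref_trace <- V[, match(reference, c$roster$name)]
    for (nm in resp$responsive) {
      i <- match(nm, c$roster$name)
      if (!is.na(periods[i])) {
        phases[i] <- phase_difference(ref_trace, V[, i], consensus, dt)
      }
    }
  }

  structure(list(
    name = spec$name, times = times, V = V, vth = tl$vth,
    periods = periods, phases = phases,
    responsive = resp$responsive, amplitude = resp$amplitude,
    active_fraction = resp$active_fraction,
    consensus_period = consensus, reference = reference,
    timeline = tl
  ), class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result> '%s': %d responsive (%.1f%% of active)\n",
              x$name, length(x$responsive), 100 * x$active_fraction))
  if (!is.na(x$consensus_period)) {
    cat(sprintf("  consensus period %.2f s (reference neuron %s)\n",
                x$consensus_period, x$reference))
  } else {
    cat("  no consensus oscillation detected\n")
  }
  invisible(x)
}

#' Robustness scan over model perturbations
#'
#' Repeats a scenario with every nonzero connection (gap entries mirrored
#' to keep the layer symmetric) and each neuron's membrane parameters
#' (\code{C}, \code{Gc}) multiplied by independent Uniform(1-p, 1+p)
#' factors, recording whether the oscillation persists and its consensus
#' period. Draws are reproducible given \code{seed}; \code{perturbation = 0}
#' reproduces the baseline in every draw.
#'
#' @inheritParams run_scenario
#' @param perturbation relative perturbation half-width, in (0, 1) (0
#'   allowed for the degenerate no-op scan).
#' @param n_draws number of perturbed replicates.
#' @param seed seed for the perturbation factors.
#' @return data frame with columns \code{draw}, \code{period},
#'   \code{oscillating}, \code{n_responsive}.
#' @export
robustness_scan <- function(spec, c, p = model_params(c),
                            cfg = solver_config(seed = spec$seed),
                            perturbation = 0.20, n_draws = 10, seed = 1L) {
  stopifnot(perturbation >= 0, perturbation < 1)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  res <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    cp <- c
    up <- upper.tri(cp$gap) & cp$reference_gap > 0
    f <- stats::runif(sum(up), 1 - perturbation, 1 + perturbation)
    cp$gap[up] <- cp$reference_gap[up] * f
    cp$gap[lower.tri(cp$gap)] <- t(cp$gap)[lower.tri(cp$gap)]
    nz <- cp$reference_syn > 0
    cp$syn[nz] <- cp$reference_syn[nz] *
      stats::runif(sum(nz), 1 - perturbation, 1 + perturbation)
    cp$reference_gap <- cp$gap
    cp$reference_syn <- cp$syn
    pp <- p
    pp$C <- p$C * stats::runif(p$n, 1 - perturbation, 1 + perturbation)
    pp$Gc <- p$Gc * stats::runif(p$n, 1 - perturbation, 1 + perturbation)
    r <- run_scenario(spec, cp, pp, cfg)
    res[[d]] <- data.frame(draw = d,
                           period = r$consensus_period,
                           oscillating = !is.na(r$consensus_period),
                           n_responsive = length(r$responsive))
  }
  do.call(rbind, res)
}
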