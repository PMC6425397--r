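#' Visualization mapping configuration
#'
#' Controls how dynamics map to node attributes. The saturating radius map
#' uses maximum radius \code{R_max = 15} display units; the slope factor
#' \code{rho} (mV^2) sets the half-saturation activity and defaults to 225,
#' i.e. half radius at 15 mV of activity — a display choice, exposed here
#' because it is tunable. \code{activity_reference} selects the voltage fed
#' into the map: \code{"threshold_relative"} (default, \code{V - V_th}; at
#' rest near threshold all radii vanish and the sign channel alternates
#' during oscillations) or \code{"absolute"} (raw \code{V}).
#'
#' @param R_max maximum node radius, display units.
#' @param rho slope factor, mV^2.
#' @param activity_reference \code{"threshold_relative"} or
#'   \code{"absolute"}.
#' @return object of class \code{"viz_config"}.
#' @export
viz_config <- function(R_max = 15, rho = 225,
                       activity_reference = c("threshold_relative",
                                              "absolute")) {
  stopifnot(R_max > 0, rho > 0)
  structure(list(R_max = R_max, rho = rho,
                 activity_reference = match.arg(activity_reference)),
            class = "viz_config")
}

#' Map activity voltage to a signed node radius
#'
#' \deqn{|R| = R_{max} \frac{V^2}{\rho + V^2}, \qquad sign(R) = sign(V)}
#' Bounded (\eqn{|R| < R_{max}}), odd in V, strictly monotone in |V|.
#'
#' @param V activity voltage, mV (vectorized).
#' @param cfg a \code{\link{viz_config}}.
#' @return signed radii.
#' @export
node_radius <- function(V, cfg = viz_config()) {
  sign(V) * cfg$R_max * V^2 / (cfg$rho + V^2)
}

#' Per-neuron visual frame for a network state
#'
#' Pure function of (state, thresholds, config): computes each neuron's
#' activity (threshold-relative by default), its signed radius and sign,
#' and flags ablated neurons (rendered grayed-out regardless of voltage).
#'
#' @param state a \code{\link{network_state}}.
#' @param vth per-neuron threshold potentials, mV.
#' @param c a \code{\link{connectome}} (roster names and active mask).
#' @param cfg a \code{\link{viz_config}}.
#' @return data frame with columns \code{name}, \code{radius}, \code{sign},
#'   \code{ablated}.
#' @export
viz_frame <- function(state, vth, c, cfg = viz_config()) {
  act <- if (cfg$activity_reference == "threshold_relative") {
    state$V - vth
  } else {
    state$V
  }
  r <- node_radius(act, cfg)
  data.frame(name = c$roster$name, radius = abs(r), sign = sign(r),
             ablated = !c$active)
}

#' Export the static layout description of a connectome
#'
#' Emits the graph quantities a force-directed renderer needs: nodes with
#' their group colour class and a radius scaled by in/out synaptic degree
#' (hub neurons larger), and one edge record per connected pair and layer —
#' synaptic edges with width \code{max(n(A->B), n(B->A))}, gap edges with
#' their junction count. Layout coordinates are left to the renderer.
#'
#' @param c a \code{\link{connectome}}.
#' @param cfg a \code{\link{viz_config}}.
#' @param path optional file; when given the description is written as JSON.
#' @param r_min minimum node radius, display units.
#' @return list with \code{nodes} and \code{edges} data frames (invisibly
#'   when \code{path} is given).
#' @export
layout_export <- function(c, cfg = viz_config(), path = NULL, r_min = 1) {
  deg <- vapply(seq_len(c$n), function(i) synaptic_degree(c, i), numeric(1))
  scale <- if (max(deg) > 0) deg / max(deg) else deg
  nodes <- data.frame(
    name = c$roster$name,
    group = c$roster$group,
    degree = deg,
    radius = r_min + (cfg$R_max - r_min) * scale
  )
  syn_cnt <- c$syn / c$g
  gap_cnt <- c$gap / c$g
  pairs <- which(upper.tri(syn_cnt), arr.ind = TRUE)
  w_syn <- pmax(syn_cnt[pairs], t(syn_cnt)[pairs])
  w_gap <- gap_cnt[pairs]
  nm <- c$roster$name
  edges <- rbind(
    data.frame(from = nm[pairs[, 1]], to = nm[pairs[, 2]],
               layer = "syn", width = w_syn)[w_syn > 0, ],
    data.frame(from = nm[pairs[, 1]], to = nm[pairs[, 2]],
               layer = "gap", width = w_gap)[w_gap > 0, ]
  )
  rownames(edges) <- NULL
  out <- list(nodes = nodes, edges = edges)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA)
    return(invisible(out))
  }
  out
}

#' Stream of visual frames for a timeline
#'
#' Converts sampled dynamics into a list of per-time frames (the JSON frame
#' stream a renderer would consume).
#'
#' @param tl a session timeline.
#' @param cfg a \code{\link{viz_config}}.
#' @param every keep every k-th sample (thinning).
#' @return list of lists with \code{t} and \code{nodes}.
#' @export
frame_stream <- function(tl, cfg = viz_config(), every = 1L) {
  sm <- timeline_samples(tl)
  idx <- seq(1L, length(sm$times), by = every)
  lapply(idx, function(i) {
    st <- network_state(sm$times[i], sm$V[i, ], sm$s[i, ])
    list(t = sm$times[i],
         nodes = viz_frame(st, tl$vth, tl$connectome, cfg))
  })
}
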