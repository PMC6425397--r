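#' Built-in stimulation scenarios
#'
#' The canonical C. elegans stimulation protocols, as scenario specs whose
#' class names expand against the loaded roster:
#' \describe{
#'   \item{forward}{posterior touch response: PLM mechanoreceptors at
#'     1.4 nA and AVB command interneurons at 2.3 nA, driving the forward
#'     locomotion circuit (VB/DB with out-of-phase VD/DD, period ~2 s).}
#'   \item{backward}{anterior touch response: ALM at 5.8 nA, AVA at
#'     2.0 nA, AVD and AVE at 1.0 nA, driving the backward circuit
#'     (VA/DA, VD/DD, AS; period ~3.5 s).}
#'   \item{nictation}{IL2 sensory neurons stimulated jointly; head motor
#'     neurons (RMG/RMH/RME/SMD) respond with a ~5.7 s period. The IL2
#'     amplitude is not fixed by the protocol descriptions; 2.0 nA is this
#'     package's default and can be overridden.}
#'   \item{forward_avb_ablated, forward_ava_ablated}{the forward protocol
#'     with the AVB (resp. AVA) interneuron pair ablated.}
#' }
#'
#' @param name scenario name.
#' @param duration,settle_time,seed passed to \code{\link{scenario_spec}}.
#' @param il2_nA amplitude for the nictation scenario, nA.
#' @return a \code{\link{scenario_spec}}.
#' @export
builtin_scenario <- function(name = c("forward", "backward", "nictation",
                                      "forward_avb_ablated",
                                      "forward_ava_ablated"),
                             duration = 30, settle_time = 10, seed = 42L,
                             il2_nA = 2.0) {
  name <- match.arg(name)
  forward_stim <- list(PLM = 1.4, AVB = 2.3)
  spec <- switch(name,
    forward = list(stim = forward_stim, abl = character()),
    backward = list(stim = list(ALM = 5.8, AVA = 2.0, AVD = 1.0, AVE = 1.0),
                    abl = character()),
    nictation = list(stim = list(IL2 = il2_nA), abl = character()),
    forward_avb_ablated = list(stim = forward_stim, abl = "AVB"),
    forward_ava_ablated = list(stim = forward_stim, abl = "AVA")
  )
  scenario_spec(name, spec$stim, spec$abl,
                duration = duration, settle_time = settle_time, seed = seed)
}

#' Built-in presets
#'
#' Panel presets for the built-in scenarios with class names expanded
#' against a roster (so they can be saved/loaded as preset JSON).
#'
#' @param name scenario name, see \code{\link{builtin_scenario}}.
#' @param roster_names roster names to expand classes against.
#' @param ... passed to \code{\link{builtin_scenario}}.
#' @return a \code{\link{preset}}.
#' @export
builtin_preset <- function(name, roster_names, ...) {
  spec <- builtin_scenario(name, ...)
  stim <- list()
  for (cls in names(spec$stimuli_nA)) {
    for (member in expand_neuron_class(roster_names, cls)) {
      stim[[member]] <- spec$stimuli_nA[[cls]]
    }
  }
  abl <- unlist(lapply(spec$ablated,
                       function(x) expand_neuron_class(roster_names, x)))
  preset(name, stim, if (is.null(abl)) character() else abl)
}
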