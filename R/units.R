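#' Unit conversions for injected current
#'
#' The model equations are integrated in a normalized unit system in which
#' both sides of the voltage equation are divided by a reference conductance
#' of 100 pS (one gap/synaptic junction). Conductances then become
#' dimensionless junction counts, voltages stay in mV, time in seconds, and
#' the natural unit of injected current ("arb") equals 0.1 pA, so that
#' 1000 arb = 0.1 nA and 1 nA = 10,000 arb. All user-facing stimulus
#' interfaces take nano-amperes; these helpers convert.
#'
#' @param x numeric vector of current amplitudes.
#' @return numeric vector in the target unit.
#' @examples
#' nA_to_arb(0.1)  # 1000
#' arb_to_nA(1000) # 0.1
#' @export
nA_to_arb <- function(x) x * 1e4

#' @rdname nA_to_arb
#' @export
arb_to_nA <- function(x) x / 1e4

# reference conductance (pS) used to normalize the voltage equation
.G_REF_PS <- 100
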