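#' Synthetic connectome specification
#'
#' Parameters for random connectome generation: network size, independent
#' Bernoulli densities for the gap (symmetric) and synaptic (directed)
#' layers, integer junction multiplicities drawn uniformly from
#' \code{1..max_multiplicity}, an i.i.d. inhibitory (GABAergic) fraction,
#' and group proportions for the sensory/inter/motor labels. No attempt is
#' made to mimic the real connectome's degree distribution or community
#' structure; these networks exercise the machinery, not the biology.
#'
#' @param n neuron count (>= 1).
#' @param gap_density,syn_density connection probabilities in [0, 1].
#' @param inhibitory_fraction probability a neuron is inhibitory.
#' @param max_multiplicity maximum junction count per connection.
#' @param group_proportions named numeric vector over sensory/inter/motor.
#' @param seed integer seed.
#' @return object of class \code{"synth_spec"}.
#' @export
synth_spec <- function(n, gap_density = 0.1, syn_density = 0.15,
                       inhibitory_fraction = 0.3, max_multiplicity = 5,
                       group_proportions = c(sensory = 0.3, inter = 0.3,
                                             motor = 0.4),
                       seed = 1L) {
  stopifnot(n >= 1, gap_density >= 0, gap_density <= 1,
            syn_density >= 0, syn_density <= 1,
            inhibitory_fraction >= 0, inhibitory_fraction <= 1,
            max_multiplicity >= 1)
  structure(list(n = as.integer(n), gap_density = gap_density,
                 syn_density = syn_density,
                 inhibitory_fraction = inhibitory_fraction,
                 max_multiplicity = as.integer(max_multiplicity),
                 group_proportions = group_proportions,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a random connectome
#'
#' Draws a connectome with the structure of the real data: non-negative
#' integer junction-count matrices scaled by the per-junction conductance
#' (100 pS), a symmetric gap layer with zero diagonal, a directed synaptic
#' layer, and signed (excitatory/inhibitory) synapse classes from the
#' roster. Deterministic given the spec's seed; the caller's RNG state is
#' left untouched.
#'
#' @param spec a \code{\link{synth_spec}}.
#' @return a \code{\link{connectome}}.
#' @export
random_connectome <- function(spec) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  n <- spec$n
  gap <- matrix(0, n, n)
  if (n > 1) {
    up <- upper.tri(gap)
    m <- sum(up)
    counts <- stats::rbinom(m, 1, spec$gap_density) *
      sample.int(spec$max_multiplicity, m, replace = TRUE)
    gap[up] <- counts
    gap <- gap + t(gap)
  }
  syn <- matrix(0, n, n)
  off <- row(syn) != col(syn)
  m <- sum(off)
  syn[off] <- stats::rbinom(m, 1, spec$syn_density) *
    sample.int(spec$max_multiplicity, m, replace = TRUE)
  roster <- data.frame(
    name = sprintf("N%03d", seq_len(n)),
    group = sample(names(spec$group_proportions), n, replace = TRUE,
                   prob = spec$group_proportions),
    inhibitory = stats::runif(n) < spec$inhibitory_fraction
  )
  connectome(gap, syn, roster, input = "counts")
}

#' Analytically tractable micro-fixtures
#'
#' Hand-built networks whose threshold potentials and dynamics have closed
#' forms (or, for the oscillator, a frozen reference period), used
#' throughout the test suite:
#' \describe{
#'   \item{single}{one isolated neuron. Threshold equals the leak
#'     potential (-35 mV); with 1 arb of input it shifts by
#'     \code{I/Gc = 10 mV} to -25 mV; the membrane time constant is
#'     \code{C/Gc = 0.15 s}.}
#'   \item{gap_pair}{two neurons joined by one gap junction (100 pS).
#'     Under input (1, 0) arb the thresholds are -625/21 and -635/21 mV
#'     (~-29.7619 / -30.2381): the pair mean shifts by \code{I/(2 Gc)} =
#'     5 mV and splits by \code{I/(Gc + 2 g)}.}
#'   \item{syn_pair}{an excitatory synapse (100 pS, reversal 0 mV) from
#'     neuron 2 onto neuron 1. Postsynaptic threshold
#'     \code{Gc Ecell/(Gc + s_eq Gs)} = -385/21 mV (~-18.333);
#'     presynaptic stays at -35 mV.}
#'   \item{inhib_pair}{same wiring but GABAergic (reversal -48 mV):
#'     postsynaptic threshold -865/21 mV (~-41.190), the
#'     conductance-weighted average of leak and inhibitory reversal,
#'     strictly between -48 and -35 mV.}
#'   \item{ring_oscillator}{three inhibitory neurons in a directed ring
#'     (1 -> 2 -> 3 -> 1, 20 junctions per synapse) under constant drive
#'     of 0.02 nA each: the frustrated loop oscillates; the expected
#'     period is the frozen value measured from the reference trajectory
#'     (seeded run documented in the package sources).}
#' }
#'
#' @param name fixture name.
#' @return list with the \code{connectome}, default \code{params}, the
#'   external input (\code{I_ext_arb} / \code{stimuli_nA}) and an
#'   \code{expected} list of derived quantities.
#' @export
fixture <- function(name = c("single", "gap_pair", "syn_pair",
                             "inhib_pair", "ring_oscillator")) {
  name <- match.arg(name)
  out <- switch(name,
    single = {
      c1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1),
                       data.frame(name = "SOLO", group = "inter",
                                  inhibitory = FALSE))
      list(connectome = c1, I_ext_arb = 0,
           expected = list(vth = -35, vth_1arb = -25, tau = 0.15))
    },
    gap_pair = {
      gap <- matrix(c(0, 1, 1, 0), 2, 2)
      c1 <- connectome(gap, matrix(0, 2, 2),
                       data.frame(name = c("GA", "GB"),
                                  group = "inter", inhibitory = FALSE))
      list(connectome = c1, I_ext_arb = c(1, 0),
           expected = list(vth = c(-625 / 21, -635 / 21)))
    },
    syn_pair = {
      syn <- matrix(0, 2, 2)
      syn[1, 2] <- 1  # TO neuron 1 FROM neuron 2
      c1 <- connectome(matrix(0, 2, 2), syn,
                       data.frame(name = c("POST", "PRE"),
                                  group = "inter", inhibitory = FALSE))
      list(connectome = c1, I_ext_arb = c(0, 0),
           expected = list(vth = c(-385 / 21, -35)))
    },
    inhib_pair = {
      syn <- matrix(0, 2, 2)
      syn[1, 2] <- 1
      c1 <- connectome(matrix(0, 2, 2), syn,
                       data.frame(name = c("POST", "PRE"),
                                  group = "inter",
                                  inhibitory = c(FALSE, TRUE)))
      list(connectome = c1, I_ext_arb = c(0, 0),
           expected = list(vth = c(-865 / 21, -35),
                           vth_bounds = c(-48, -35)))
    },
    ring_oscillator = {
      syn <- matrix(0, 3, 3)
      syn[2, 1] <- 20  # 1 inhibits 2
      syn[3, 2] <- 20  # 2 inhibits 3
      syn[1, 3] <- 20  # 3 inhibits 1
      c1 <- connectome(matrix(0, 3, 3), syn,
                       data.frame(name = c("R1", "R2", "R3"),
                                  group = "motor", inhibitory = TRUE))
      # reference period: 20 s run, 5 s settle, default solver tolerances,
      # initial-condition seeds 1/7/42 all give 0.962-0.965 s
      list(connectome = c1,
           stimuli_nA = 0.02, I_ext_arb = rep(nA_to_arb(0.02), 3),
           expected = list(period = 0.963, period_rel_tol = 0.02))
    }
  )
  out$params <- model_params(out$connectome)
  out
}
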