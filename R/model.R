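#' Biophysical model parameters
#'
#' Single-compartment graded-potential membrane model parameters. Defaults
#' are the standard literature values for C. elegans: membrane capacitance
#' C = 1.5 pF, membrane (leak) conductance Gc = 10 pS, leak potential
#' E_cell = -35 mV, per-junction conductance g = 100 pS, synaptic rise and
#' decay rates a_r = 1/1.5 and a_d = 5/1.5 per second, and sigmoid width
#' beta = 0.125 per mV. Synaptic reversal potentials E_j come from the
#' roster: 0 mV for excitatory, -48 mV for inhibitory (GABAergic) neurons.
#'
#' \code{C} and \code{Gc} may be per-neuron vectors (recycled from scalars),
#' which is what the robustness scan perturbs.
#'
#' @param c optional \code{\link{connectome}} supplying \code{n} and the
#'   reversal potentials.
#' @param n neuron count (required when \code{c} is NULL).
#' @param C membrane capacitance, pF.
#' @param Gc membrane conductance, pS.
#' @param Ecell leak potential, mV.
#' @param g per-junction conductance, pS (the normalization conductance).
#' @param a_r,a_d synaptic activity rise/decay rates, 1/s.
#' @param beta sigmoid width, 1/mV.
#' @param Ej optional explicit N-vector of reversal potentials, mV.
#' @return object of class \code{"model_params"}.
#' @export
model_params <- function(c = NULL, n = if (!is.null(c)) c$n else NULL,
                         C = 1.5, Gc = 10, Ecell = -35, g = 100,
                         a_r = 1 / 1.5, a_d = 5 / 1.5, beta = 0.125,
                         Ej = NULL) {
  if (is.null(n)) stop("supply a connectome or a neuron count n")
  if (is.null(Ej)) {
    Ej <- if (!is.null(c)) c$roster$reversal_potential else rep(0, n)
  }
  stopifnot(all(C > 0), all(Gc > 0), g > 0, a_r > 0, a_d > 0, beta > 0,
            length(Ej) == n)
  structure(list(
    n = n,
    C = rep_len(C, n), Gc = rep_len(Gc, n),
    Ecell = Ecell, g = g, a_r = a_r, a_d = a_d, beta = beta,
    Ej = Ej
  ), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "<model_params> n=%d  C=%.3g pF  Gc=%.3g pS  Ecell=%g mV  g=%g pS\n",
    x$n, x$C[1], x$Gc[1], x$Ecell, x$g))
  cat(sprintf("  a_r=%.4g /s  a_d=%.4g /s  beta=%g /mV  inhibitory Ej: %d\n",
              x$a_r, x$a_d, x$beta, sum(x$Ej < 0)))
  invisible(x)
}

#' Synaptic activation sigmoid
#'
#' \code{1 / (1 + exp(-beta * (V - vth)))}, evaluated with the
#' exp-of-negative-absolute-value formulation so large arguments of either
#' sign cannot overflow.
#'
#' @param V membrane voltage, mV (vectorized).
#' @param beta sigmoid width, 1/mV.
#' @param vth threshold potential, mV (vectorized).
#' @return values in (0, 1).
#' @export
sigmoid_phi <- function(V, beta, vth) {
  x <- beta * (V - vth)
  e <- exp(-abs(x))
  ifelse(x >= 0, 1 / (1 + e), e / (1 + e))
}

#' Equilibrium synaptic activity
#'
#' Setting \code{ds/dt = 0} with the activation sigmoid at its midpoint
#' (1/2) gives \code{s_eq = a_r / (a_r + 2 a_d)}; with the default rates
#' this is 1/11.
#'
#' @param a_r,a_d rise/decay rates, 1/s.
#' @return scalar equilibrium activity.
#' @export
s_equilibrium <- function(a_r, a_d) a_r / (a_r + 2 * a_d)

# Normalized (dimensionless-conductance) coefficients: everything divided by
# the reference conductance g. Gc -> Gc/g, C -> C/g (seconds), matrices ->
# junction counts, currents in arb (1 arb = 0.1 pA at g = 100 pS).
.norm_model <- function(c, p) {
  list(
    n = p$n,
    Cn = p$C / p$g,              # pF/pS = seconds; 1.5/100 = 0.015 s
    Gcn = p$Gc / p$g,
    Gg = c$gap / p$g,
    Gs = c$syn / p$g,
    Ecell = p$Ecell, Ej = p$Ej,
    a_r = p$a_r, a_d = p$a_d, beta = p$beta
  )
}

#' Right-hand side of the dynome equations
#'
#' Evaluates the coupled membrane/synapse derivatives
#' \deqn{C dV_i/dt = -G_c (V_i - E_{cell}) - \sum_j G^g_{ij}(V_i - V_j)
#'       - \sum_j G^s_{ij} s_j (V_i - E_j) + I^{ext}_i}
#' \deqn{ds_i/dt = a_r \Phi(V_i)(1 - s_i) - a_d s_i}
#' where the gap sum runs over the symmetric electrical couplings, the
#' synaptic current uses presynaptic activity \eqn{s_j} with the presynaptic
#' reversal potential \eqn{E_j}, and \eqn{\Phi} is
#' \code{\link{sigmoid_phi}} centred at the per-neuron threshold
#' \code{vth}. Ablated neurons have zero rows/columns, so their couplings
#' vanish automatically and they relax under leak (plus any stimulus).
#'
#' @param state a \code{\link{network_state}}.
#' @param c a \code{\link{connectome}}.
#' @param p \code{\link{model_params}}.
#' @param I_ext external input, arb units, length-N vector (or scalar).
#' @param vth per-neuron threshold potentials, mV (see
#'   \code{\link{compute_vth}}).
#' @return list with elements \code{dV} (mV/s) and \code{ds} (1/s).
#' @export
dynome_rhs <- function(state, c, p, I_ext = 0, vth = rep(0, p$n)) {
  if (!all(is.finite(state$V)) || !all(is.finite(state$s))) {
    stop("non-finite state values")
  }
  m <- .norm_model(c, p)
  d <- .rhs_core(state$V, state$s, m, rep_len(I_ext, m$n), vth)
  list(dV = d$dV, ds = d$ds)
}

.rhs_core <- function(V, s, m, I_ext, vth) {
  i_gap <- V * rowSums(m$Gg) - drop(m$Gg %*% V)
  i_syn <- V * drop(m$Gs %*% s) - drop(m$Gs %*% (s * m$Ej))
  dV <- (-m$Gcn * (V - m$Ecell) - i_gap - i_syn + I_ext) / m$Cn
  phi <- sigmoid_phi(V, m$beta, vth)
  ds <- m$a_r * phi * (1 - s) - m$a_d * s
  list(dV = unname(dV), ds = unname(ds))
}

#' Threshold potentials: the network's linear fixed point
#'
#' Solves the linear system obtained by imposing \code{dV/dt = 0} with
#' synaptic activity frozen at its equilibrium \code{s_eq} (activation at
#' the sigmoid midpoint): \code{A x = b} with
#' \code{A = M1 + M2 + M3}, \code{b = -b1 - b3 - I_ext}, where
#' \code{M1 = diag(-Gc)}, \code{M3 = diag(-s_eq * rowSums(Gs))},
#' \code{b1 = Gc * Ecell} and \code{b3 = Gs \%*\% (s_eq * Ej)}.
#'
#' For the gap term, the default \code{mode = "laplacian"} uses the full
#' weighted gap Laplacian (diagonal \code{rowSums(Gg)} minus the
#' off-diagonal couplings), which is the literal zero-derivative condition
#' of the membrane equation. \code{mode = "diagonal"} keeps only the
#' diagonal \code{-rowSums(Gg)} term; it coincides with the Laplacian mode
#' when all gap neighbours sit at 0 mV but yields implausible thresholds for
#' strongly gap-coupled neurons, and is provided for comparison only.
#'
#' The returned solution satisfies
#' \code{max|Ax - b| <= 1e-10 * max|b|} (checked; the system is
#' diagonally dominant and nonsingular for \code{Gc > 0}).
#'
#' @inheritParams dynome_rhs
#' @param mode gap-term treatment, \code{"laplacian"} (default) or
#'   \code{"diagonal"}.
#' @return N-vector of threshold potentials, mV.
#' @export
compute_vth <- function(c, p, I_ext = 0, mode = c("laplacian", "diagonal")) {
  mode <- match.arg(mode)
  m <- .norm_model(c, p)
  I_ext <- rep_len(I_ext, m$n)
  if (anyNA(I_ext) || anyNA(m$Gg) || anyNA(m$Gs)) stop("NaN in inputs")
  s_eq <- s_equilibrium(p$a_r, p$a_d)

  A <- diag(-m$Gcn - rowSums(m$Gg) - s_eq * rowSums(m$Gs), m$n)
  if (mode == "laplacian") A <- A + m$Gg
  b <- -(m$Gcn * m$Ecell) - drop(m$Gs %*% (s_eq * m$Ej)) - I_ext

  x <- solve(A, b)
  res <- max(abs(A %*% x - b))
  if (res > 1e-10 * max(abs(b), 1)) {
    stop(sprintf("threshold system residual too large: %g", res))
  }
  unname(x)
}
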