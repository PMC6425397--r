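#' Construct a connectome
#'
#' A connectome bundles the static wiring of the network: a symmetric
#' gap-junction (electrical) conductivity matrix, a directed chemical-synapse
#' conductivity matrix, and a neuron roster. Matrices are stored in pS;
#' integer junction-count inputs are scaled by the per-junction conductance
#' \code{g} (default 100 pS). The synaptic matrix is oriented so that
#' \code{syn[i, j]} is the maximal total conductivity of synapses TO neuron
#' \code{i} FROM neuron \code{j}; sources using the opposite convention can
#' be read with \code{transpose_syn = TRUE}.
#'
#' Pristine copies of both matrices are kept so that \code{\link{reinsert}}
#' after \code{\link{ablate}} is exact.
#'
#' @param gap N x N symmetric non-negative matrix, zero diagonal.
#' @param syn N x N non-negative matrix, zero diagonal; \code{[i, j]} = TO i
#'   FROM j.
#' @param roster data frame with columns \code{name} (unique labels),
#'   \code{group} (\code{"sensory"}, \code{"inter"} or \code{"motor"}) and
#'   \code{inhibitory} (logical; TRUE for GABAergic). A reversal-potential
#'   column is derived: 0 mV for excitatory, -48 mV for inhibitory neurons.
#' @param input \code{"counts"} if the matrices hold integer junction counts
#'   (scaled by \code{g}), \code{"conductance"} if already in pS.
#' @param g per-junction conductance in pS used to scale counts.
#' @param transpose_syn set TRUE when \code{syn[i, j]} in the source means
#'   FROM i TO j.
#' @param tol tolerance for the gap-layer symmetry check.
#' @return an object of class \code{"connectome"}: a list with elements
#'   \code{n}, \code{roster}, \code{gap}, \code{syn}, \code{active},
#'   \code{reference_gap}, \code{reference_syn}, \code{g}.
#' @export
connectome <- function(gap, syn, roster, input = c("counts", "conductance"),
                       g = 100, transpose_syn = FALSE, tol = 1e-8) {
  input <- match.arg(input)
  gap <- as.matrix(gap)
  syn <- as.matrix(syn)
  if (transpose_syn) syn <- t(syn)
  n <- nrow(gap)
  if (ncol(gap) != n || nrow(syn) != n || ncol(syn) != n) {
    stop("gap and syn must be square matrices of equal size")
  }
  roster <- validate_roster(roster, n)
  if (any(gap < 0) || any(syn < 0)) stop("negative conductivity entries")
  if (max(abs(gap - t(gap))) > tol * max(1, max(abs(gap)))) {
    stop("gap-junction matrix is not symmetric")
  }
  gap <- (gap + t(gap)) / 2
  diag(gap) <- 0
  diag(syn) <- 0
  if (input == "counts") {
    gap <- gap * g
    syn <- syn * g
  }
  dimnames(gap) <- dimnames(syn) <- list(roster$name, roster$name)
  structure(list(
    n = n, roster = roster, gap = gap, syn = syn,
    active = rep(TRUE, n), reference_gap = gap, reference_syn = syn,
    g = g
  ), class = "connectome")
}

validate_roster <- function(roster, n) {
  roster <- as.data.frame(roster)
  if (nrow(roster) != n) stop("roster length does not match matrix size")
  if (is.null(roster$name)) roster$name <- sprintf("N%03d", seq_len(n))
  roster$name <- as.character(roster$name)
  if (anyDuplicated(roster$name)) stop("duplicate neuron names in roster")
  if (is.null(roster$group)) roster$group <- "inter"
  if (!all(roster$group %in% c("sensory", "inter", "motor"))) {
    stop("group must be sensory, inter or motor")
  }
  if (is.null(roster$inhibitory)) roster$inhibitory <- FALSE
  roster$inhibitory <- as.logical(roster$inhibitory)
  roster$reversal_potential <- ifelse(roster$inhibitory, -48, 0)
  rownames(roster) <- NULL
  roster[, c("name", "group", "inhibitory", "reversal_potential")]
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d neurons (%d active)\n", x$n, sum(x$active)))
  cat(sprintf("  gap junctions : %d pairs\n", sum(x$gap[upper.tri(x$gap)] > 0)))
  cat(sprintf("  synapses      : %d directed connections\n", sum(x$syn > 0)))
  cat(sprintf("  inhibitory    : %d neurons\n", sum(x$roster$inhibitory)))
  invisible(x)
}

#' Resolve neuron names or indices against a roster
#'
#' @param c a \code{\link{connectome}}.
#' @param neurons character vector of names or integer indices (1-based).
#' @return integer indices.
#' @export
resolve_neurons <- function(c, neurons) {
  if (is.character(neurons)) {
    idx <- match(neurons, c$roster$name)
    if (anyNA(idx)) {
      stop("unknown neuron name(s): ",
           paste(neurons[is.na(idx)], collapse = ", "))
    }
    idx
  } else {
    idx <- as.integer(neurons)
    if (any(idx < 1L | idx > c$n)) stop("neuron index out of range")
    idx
  }
}

#' In/out synaptic degree of a neuron
#'
#' Number of nonzero incoming plus outgoing synaptic connections; used to
#' scale node radii in the static connectivity view (hub neurons get larger
#' radii).
#'
#' @inheritParams resolve_neurons
#' @param i neuron name or index.
#' @return integer count.
#' @export
synaptic_degree <- function(c, i) {
  i <- resolve_neurons(c, i)
  sum(c$syn[i, ] > 0) + sum(c$syn[, i] > 0)
}

#' Edge width between a pair of neurons
#'
#' The display width of the synaptic edge between neurons A and B is the
#' larger of the two directed synapse counts,
#' \code{max(n_syn(A -> B), n_syn(B -> A))}.
#'
#' @inheritParams resolve_neurons
#' @param a,b neuron names or indices, distinct.
#' @return numeric count (conductivities divided by the per-junction
#'   conductance \code{g}).
#' @export
edge_width <- function(c, a, b) {
  a <- resolve_neurons(c, a)
  b <- resolve_neurons(c, b)
  if (a == b) stop("edge_width requires two distinct neurons")
  max(c$syn[b, a], c$syn[a, b]) / c$g
}

#' Ablate or reinsert neurons
#'
#' Ablation disconnects a neuron from the network: row and column \code{i}
#' of both connectivity matrices are set to zero (in/out, gap and synaptic)
#' and the neuron is marked inactive. Its membrane still integrates as an
#' isolated cell. Reinsertion restores the row and column from the pristine
#' reference copies, so \code{reinsert(ablate(c, s), s)} is an exact
#' identity. Ablating an already-ablated neuron is a no-op.
#'
#' @inheritParams resolve_neurons
#' @param neurons neuron names or indices.
#' @return the modified connectome.
#' @export
ablate <- function(c, neurons) {
  idx <- resolve_neurons(c, neurons)
  c$active[idx] <- FALSE
  c$gap[idx, ] <- 0
  c$gap[, idx] <- 0
  c$syn[idx, ] <- 0
  c$syn[, idx] <- 0
  c
}

#' @rdname ablate
#' @export
reinsert <- function(c, neurons) {
  idx <- resolve_neurons(c, neurons)
  c$active[idx] <- TRUE
  inact <- which(!c$active)
  c$gap <- c$reference_gap
  c$syn <- c$reference_syn
  if (length(inact)) {
    c$gap[inact, ] <- 0
    c$gap[, inact] <- 0
    c$syn[inact, ] <- 0
    c$syn[, inact] <- 0
  }
  c
}

#' Load a connectome bundle from disk
#'
#' A bundle is a directory containing a roster \code{neurons.json}, the two
#' connectivity matrices as either \code{gap.csv}/\code{syn.csv} (dense,
#' header row of neuron names) or \code{Gg.npy}/\code{Gs.npy} (as in the
#' original release of the 279-neuron somatic connectome), and an optional
#' \code{meta.json} declaring units (\code{"counts"} or \code{"conductance"}),
#' the per-junction conductance \code{g_pS} and a \code{transpose_syn} flag
#' for sources whose synaptic matrix is oriented FROM row TO column.
#'
#' @param path bundle directory.
#' @param format \code{"auto"} picks csv if present, else npy.
#' @return a \code{\link{connectome}}.
#' @export
load_connectome <- function(path, format = c("auto", "csv", "npy")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("no such bundle directory: ", path)
  roster_file <- file.path(path, "neurons.json")
  if (!file.exists(roster_file)) stop("bundle is missing neurons.json")
  roster <- jsonlite::fromJSON(roster_file)

  meta <- list(units = "counts", g_pS = 100, transpose_syn = FALSE)
  meta_file <- file.path(path, "meta.json")
  if (file.exists(meta_file)) {
    user <- jsonlite::fromJSON(meta_file)
    meta[names(user)] <- user
  }

  if (format == "auto") {
    format <- if (file.exists(file.path(path, "gap.csv"))) "csv" else "npy"
  }
  if (format == "csv") {
    gap <- as.matrix(utils::read.csv(file.path(path, "gap.csv"),
                                     check.names = FALSE))
    syn <- as.matrix(utils::read.csv(file.path(path, "syn.csv"),
                                     check.names = FALSE))
  } else {
    gap <- read_npy(file.path(path, "Gg.npy"))
    syn <- read_npy(file.path(path, "Gs.npy"))
  }
  connectome(gap, syn, roster,
             input = if (identical(meta$units, "conductance")) "conductance"
                     else "counts",
             g = meta$g_pS, transpose_syn = isTRUE(meta$transpose_syn))
}

#' Write a connectome bundle to disk
#'
#' Inverse of \code{\link{load_connectome}}; writes the pristine reference
#' matrices (in pS, \code{units = "conductance"}) so that a round trip
#' reproduces them: exactly for npy, to printed precision for csv.
#'
#' @param c a \code{\link{connectome}}.
#' @param path target directory (created if needed).
#' @param format \code{"csv"} or \code{"npy"}.
#' @return \code{path}, invisibly.
#' @export
write_connectome <- function(c, path, format = c("csv", "npy")) {
  format <- match.arg(format)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    c$roster[, c("name", "group", "inhibitory")],
    file.path(path, "neurons.json")
  )
  jsonlite::write_json(
    list(units = "conductance", g_pS = c$g, transpose_syn = FALSE),
    file.path(path, "meta.json"), auto_unbox = TRUE
  )
  if (format == "csv") {
    utils::write.csv(as.data.frame(c$reference_gap),
                     file.path(path, "gap.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(c$reference_syn),
                     file.path(path, "syn.csv"), row.names = FALSE)
  } else {
    write_npy(c$reference_gap, file.path(path, "Gg.npy"))
    write_npy(c$reference_syn, file.path(path, "Gs.npy"))
  }
  invisible(path)
}
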