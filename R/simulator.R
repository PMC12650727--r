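# Controlled-variable generator of dynamic-network pairs: two undirected
# weighted networks sharing initial structure and sine-driven evolution,
# with four dials for their differences (phase offset delta_phi, amplitude
# ratio lam, structural perturbation power alpha, strength scale beta) plus
# observation noise.

# Evaluate expr with a locally seeded RNG; the caller's RNG state is
# untouched. seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulation specification for a dynamic-network pair
#'
#' Collects every parameter of the evolving-network model. Edge `i` of
#' network 1 evolves as `F_i(t) = F_i(0) + a_{1i} sin(t + phi_{1i}) + eps`,
#' `t = 0, ..., T-1`; network 2 shares the generative draw but differs
#' through the four controlled variables:
#' \itemize{
#'   \item `delta_phi` in `[0, pi]`: phase offset, `phi_2i = phi_1i +
#'     delta_phi` (evolutionary-trend dissimilarity);
#'   \item `lam` in `(0, 1]`: amplitude ratio `lam = a_{1i}/a_{2i}`, so
#'     `a_{2i} = a_{1i}/lam` (evolving relative amplitude);
#'   \item `alpha >= 0`: power (variance) of zero-mean Gaussian noise added
#'     to network 2's initial structure (structural topological
#'     distribution);
#'   \item `beta > 0`: multiplicative scale of network 2's initial edge
#'     strengths (connectivity strength span).
#' }
#' `noise_power` is the variance of the i.i.d. observation noise `eps`,
#' drawn independently for the two networks; the paper's levels 0.1, 0.01,
#' 0.001 correspond to SNRs of 10, 20, 30 dB for unit signal power.
#'
#' @param n_nodes,n_timepoints Network size; both default to 10.
#' @param delta_phi,lam,alpha,beta,noise_power The controlled variables
#'   (neutral defaults 0, 1, 0, 1, 0: the two networks are then identical).
#' @param init_weight_range Uniform range of initial weights `F(0)`; the
#'   default `[0.5, 1.5]` keeps weights positive with mean squared weight
#'   ~1.08, i.e. edge power near 1 as the SNR calibration assumes.
#' @param amplitude_range Uniform range of the base amplitudes `a_{1i}`;
#'   default `[0.2, 0.5]` so the evolution modulates but does not dominate
#'   the baseline.
#' @param phase_range Uniform range of the base phases `phi_{1i}`; default
#'   `[0, 2 pi)`.
#' @param seed Optional integer seed; under a fixed seed generation is fully
#'   deterministic.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_nodes = 10L, n_timepoints = 10L,
                            delta_phi = 0, lam = 1, alpha = 0, beta = 1,
                            noise_power = 0,
                            init_weight_range = c(0.5, 1.5),
                            amplitude_range = c(0.2, 0.5),
                            phase_range = c(0, 2 * pi),
                            seed = NULL) {
  if (n_nodes < 2L) stop("n_nodes must be at least 2")
  if (n_timepoints < 1L) stop("n_timepoints must be at least 1")
  if (lam <= 0) stop("lam must be positive (lam = 0 leaves the amplitude ",
                     "ratio a_1/a_2 undefined)")
  if (alpha < 0) stop("alpha must be nonnegative")
  if (beta <= 0) stop("beta must be positive")
  if (noise_power < 0) stop("noise_power must be nonnegative")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_timepoints = as.integer(n_timepoints),
                 delta_phi = delta_phi, lam = lam, alpha = alpha, beta = beta,
                 noise_power = noise_power,
                 init_weight_range = init_weight_range,
                 amplitude_range = amplitude_range,
                 phase_range = phase_range,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec> n =", x$n_nodes, " T =", x$n_timepoints,
      "\n  delta_phi =", format(x$delta_phi, digits = 4),
      " lam =", x$lam, " alpha =", x$alpha, " beta =", x$beta,
      " noise_power =", x$noise_power, "\n")
  invisible(x)
}

#' Generate the random initial structure of a simulated network
#'
#' Every off-diagonal edge weight is an independent uniform draw from
#' `spec$init_weight_range`; the matrix is symmetric with zero diagonal.
#' The default range keeps the mean squared edge weight (edge "power")
#' around 1.
#'
#' @param spec A `simulation_spec`.
#' @param seed Optional seed (defaults to `spec$seed`).
#' @return An `n x n` symmetric weight matrix.
#' @export
generate_initial_structure <- function(spec, seed = spec$seed) {
  with_seed(seed, {
    m <- n_edges(spec$n_nodes)
    w <- stats::runif(m, spec$init_weight_range[1L], spec$init_weight_range[2L])
    edges_to_matrix(w, spec$n_nodes)
  })
}

#' Evolve an initial structure into a dynamic network
#'
#' Edge `i` at timepoint `t` (integer `t = 0, ..., T-1`) has weight
#' `F_i(0) + a_i sin(t + phi_i) + eps_{it}` with
#' `eps_{it} ~ N(0, sqrt(noise_power))` i.i.d.
#'
#' @param initial `n x n` symmetric matrix of initial weights `F(0)`.
#' @param amplitudes,phases Numeric vectors of length `m = n(n-1)/2`, in
#'   canonical edge order ([edge_pairs()]).
#' @param n_timepoints Number of timepoints `T`.
#' @param noise_power Variance of the observation noise (0 for none).
#' @return A `dynamic_network`.
#' @export
evolve <- function(initial, amplitudes, phases, n_timepoints,
                   noise_power = 0) {
  if (noise_power < 0) stop("noise_power must be nonnegative")
  n <- nrow(initial)
  m <- n_edges(n)
  if (length(amplitudes) == 1L) amplitudes <- rep(amplitudes, m)
  if (length(phases) == 1L) phases <- rep(phases, m)
  if (length(amplitudes) != m || length(phases) != m)
    stop("amplitudes and phases must have length m = ", m)
  f0 <- upper_vec(initial)
  tgrid <- seq_len(n_timepoints) - 1
  # m x T matrix of edge trajectories
  traj <- f0 + amplitudes * sin(outer(phases, tgrid, "+"))
  if (noise_power > 0)
    traj <- traj + matrix(stats::rnorm(m * n_timepoints,
                                       sd = sqrt(noise_power)), m, n_timepoints)
  w <- array(0, dim = c(n_timepoints, n, n))
  for (t in seq_len(n_timepoints)) w[t, , ] <- edges_to_matrix(traj[, t], n)
  dynamic_network(w)
}

#' Generate a controlled pair of dynamic networks
#'
#' Draws a shared initial structure, base amplitudes and base phases, then
#' builds: network 1 from `(F(0), a_1, phi_1)`; network 2 from the perturbed
#' initial structure `beta * (F(0) + eta)`, `eta ~ N(0, sqrt(alpha))`
#' (symmetric, off-diagonal), amplitudes `a_2 = a_1 / lam` and phases
#' `phi_2 = phi_1 + delta_phi`. Observation noise of power `noise_power` is
#' drawn independently for the two networks. With all variables neutral and
#' no noise the two networks are bit-identical.
#'
#' @param spec A `simulation_spec`.
#' @param seed Optional seed (defaults to `spec$seed`).
#' @return A list of class `network_pair`: `net1`, `net2`, `spec`.
#' @export
make_network_pair <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(seed, {
    n <- spec$n_nodes
    m <- n_edges(n)
    f0 <- stats::runif(m, spec$init_weight_range[1L],
                       spec$init_weight_range[2L])
    a1 <- stats::runif(m, spec$amplitude_range[1L], spec$amplitude_range[2L])
    p1 <- stats::runif(m, spec$phase_range[1L], spec$phase_range[2L])
    eta <- if (spec$alpha > 0) stats::rnorm(m, sd = sqrt(spec$alpha)) else 0
    f0_2 <- spec$beta * (f0 + eta)
    net1 <- evolve(edges_to_matrix(f0, n), a1, p1,
                   spec$n_timepoints, spec$noise_power)
    net2 <- evolve(edges_to_matrix(f0_2, n), a1 / spec$lam,
                   p1 + spec$delta_phi, spec$n_timepoints, spec$noise_power)
    structure(list(net1 = net1, net2 = net2, spec = spec),
              class = "network_pair")
  })
}

#' @export
print.network_pair <- function(x, ...) {
  cat("<network_pair> n =", n_nodes(x$net1), " T =", n_timepoints(x$net1),
      "\n")
  print(x$spec)
  invisible(x)
}

#' Randomly disrupt the timing sequence of a dynamic network
#'
#' A uniformly chosen subset of `floor(gamma * T)` timepoints is randomly
#' permuted among themselves; the remaining timepoints are untouched. The
#' multiset of snapshots is always conserved. `gamma = 0` (or a subset of
#' fewer than 2 timepoints) is the identity; `gamma = 1` applies a uniform
#' random permutation to all slices.
#'
#' @param net A `dynamic_network`.
#' @param gamma Fraction in `[0, 1]` of timepoints to disrupt.
#' @param seed Optional seed.
#' @return A `dynamic_network` with permuted slices (time labels unchanged:
#'   the time axis itself is not relabeled, its content is).
#' @export
shuffle_timepoints <- function(net, gamma, seed = NULL) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  validate_dynamic_network(net)
  with_seed(seed, {
    tt <- n_timepoints(net)
    k <- floor(gamma * tt)
    if (k < 2L) return(net)
    idx <- sort(sample.int(tt, k))
    perm <- sample.int(k)
    w <- net$weights
    w[idx, , ] <- w[idx[perm], , ]
    dynamic_network(w, net$node_labels, net$time_labels)
  })
}
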