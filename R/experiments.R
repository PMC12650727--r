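# The six validation experiments: sweep one controlled variable across
# replicate network pairs, compute DNS/DNES per replicate, and summarize the
# index-vs-variable relation with a Pearson correlation and the residual sum
# of squares of the OLS line.

EXPERIMENT_VARIABLES <- c("delta_phi", "lam", "alpha", "beta", "sigma",
                          "gamma")

# Sweep ranges of the four feature experiments. delta_phi spans in-phase to
# anti-phase; lam is bounded away from 0 (lam = 0 is undefined); alpha spans
# no perturbation up to a perturbation comparable to the initial-weight
# variance; beta spans strong shrinkage up to the neutral value 1.
FEATURE_RANGES <- list(delta_phi = c(0, pi), lam = c(0.05, 1),
                       alpha = c(0, 0.5), beta = c(0.1, 1))

#' Pearson correlation and OLS residual sum of squares
#'
#' Summary statistics of an experiment: the Pearson correlation (with
#' two-sided p-value) between an index and the swept variable, and the
#' residual sum of squares of the ordinary least-squares fit of the index on
#' the variable over all replicates.
#'
#' @param samples A data frame with a `variable` column and index columns.
#' @param index_name Which index column to summarize (e.g. `"dns"`).
#' @return A list with `r`, `p`, `rss`.
#' @export
correlation_and_rss <- function(samples, index_name = "dns") {
  if (!is.data.frame(samples) || is.null(samples$variable))
    stop("`samples` must be a data frame with a `variable` column")
  x <- samples$variable
  y <- samples[[index_name]]
  if (is.null(y)) stop("no column `", index_name, "` in samples")
  if (length(x) < 3L) stop("need at least 3 samples for a correlation")
  if (pop_sd(x) == 0 || pop_sd(y) == 0)
    stop("degenerate fit: ", if (pop_sd(x) == 0) "variable" else index_name,
         " is constant")
  ct <- stats::cor.test(x, y)
  fit <- stats::lm(y ~ x)
  list(r = unname(ct$estimate), p = ct$p.value,
       rss = sum(stats::residuals(fit)^2))
}

new_experiment_result <- function(experiment_id, variable_name, noise_power,
                                  samples, seed) {
  sdns <- correlation_and_rss(samples, "dns")
  sdnes <- correlation_and_rss(samples, "dnes")
  structure(list(experiment_id = experiment_id,
                 variable_name = variable_name,
                 noise_power = noise_power,
                 samples = samples,
                 r_dns = sdns$r, p_dns = sdns$p, rss_dns = sdns$rss,
                 r_dnes = sdnes$r, p_dnes = sdnes$p, rss_dnes = sdnes$rss,
                 seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> Experiment ", x$experiment_id, ": ",
      nrow(x$samples), " replicates sweeping ", x$variable_name,
      " (observation noise power ", format(x$noise_power), ")\n",
      "  DNS : r = ", sprintf("%.4f", x$r_dns),
      ", p = ", format(x$p_dns, digits = 3),
      ", RSS = ", sprintf("%.4f", x$rss_dns), "\n",
      "  DNES: r = ", sprintf("%.4f", x$r_dnes),
      ", p = ", format(x$p_dnes, digits = 3),
      ", RSS = ", sprintf("%.4f", x$rss_dnes), "\n", sep = "")
  invisible(x)
}

#' Feature-sensitivity experiments (1-4)
#'
#' Per replicate, the swept variable is drawn uniformly from its range
#' (Experiment 1: `delta_phi` in `[0, pi]`; 2: `lam` in `[0.05, 1]`; 3:
#' `alpha` in `[0, 0.5]`; 4: `beta` in `[0.1, 1]`), a fresh network pair is
#' simulated with the other three variables neutral, and DNS and DNES are
#' computed on the pair. The experiment summary is the Pearson correlation
#' (and OLS RSS) of each index against the variable across replicates.
#'
#' @param id Experiment number, 1 to 4.
#' @param noise_power Observation-noise power (the reference levels are 0.1,
#'   0.01, 0.001, i.e. 10/20/30 dB SNR).
#' @param n_reps Number of replicates (default 200).
#' @param seed Optional seed; under a fixed seed the result is fully
#'   reproducible.
#' @param n_nodes,n_timepoints Network size (default 10 and 10).
#' @return An `experiment_result`: per-replicate `samples`
#'   (`variable`, `dns`, `dnes`) plus `r_dns`, `p_dns`, `rss_dns` and the
#'   DNES counterparts.
#' @export
run_feature_experiment <- function(id, noise_power = 0.001, n_reps = 200L,
                                   seed = NULL, n_nodes = 10L,
                                   n_timepoints = 10L) {
  id <- as.integer(id)
  if (!id %in% 1:4) stop("feature experiments are numbered 1 to 4")
  if (n_reps < 3L) stop("need at least 3 replicates for a correlation")
  varname <- names(FEATURE_RANGES)[id]
  rng <- FEATURE_RANGES[[id]]
  with_seed(seed, {
    vals <- stats::runif(n_reps, rng[1L], rng[2L])
    res <- vapply(vals, function(v) {
      args <- list(n_nodes = n_nodes, n_timepoints = n_timepoints,
                   noise_power = noise_power)
      args[[varname]] <- v
      pair <- make_network_pair(do.call(simulation_spec, args))
      c(dns(pair$net1, pair$net2)$value, dnes(pair$net1, pair$net2)$value)
    }, numeric(2L))
    samples <- data.frame(replicate = seq_len(n_reps), variable = vals,
                          dns = res[1L, ], dnes = res[2L, ])
    new_experiment_result(id, varname, noise_power, samples, seed)
  })
}

#' General randomization experiments (5-6)
#'
#' Both start from an identical, noise-free network pair; network 2 is then
#' randomized. Experiment 5 superimposes zero-mean Gaussian noise of power
#' `sigma` on every edge of network 2, with `sigma` drawn log-uniformly from
#' `sweep_range` (default `[0.001, 10]`). Experiment 6 randomly permutes the
#' order of a fraction `gamma` of network 2's timepoints, with `gamma` drawn
#' uniformly from `sweep_range` (default `[0, 1]`).
#'
#' @param id Experiment number, 5 or 6.
#' @param n_reps Number of replicates (default 1000).
#' @param seed Optional seed.
#' @param sweep_range Length-2 range of the randomization variable.
#' @param n_nodes,n_timepoints Network size (default 10 and 10).
#' @return An `experiment_result` (variable `sigma` or `gamma`).
#' @export
run_general_experiment <- function(id, n_reps = 1000L, seed = NULL,
                                   sweep_range = NULL, n_nodes = 10L,
                                   n_timepoints = 10L) {
  id <- as.integer(id)
  if (!id %in% 5:6) stop("general experiments are numbered 5 and 6")
  if (n_reps < 3L) stop("need at least 3 replicates for a correlation")
  varname <- if (id == 5L) "sigma" else "gamma"
  if (is.null(sweep_range))
    sweep_range <- if (id == 5L) c(0.001, 10) else c(0, 1)
  with_seed(seed, {
    vals <- if (id == 5L) {
      exp(stats::runif(n_reps, log(sweep_range[1L]), log(sweep_range[2L])))
    } else {
      stats::runif(n_reps, sweep_range[1L], sweep_range[2L])
    }
    res <- vapply(vals, function(v) {
      pair <- make_network_pair(
        simulation_spec(n_nodes = n_nodes, n_timepoints = n_timepoints))
      net2 <- pair$net1
      if (id == 5L) {
        m <- n_edges(n_nodes)
        noise <- matrix(stats::rnorm(m * n_timepoints, sd = sqrt(v)),
                        m, n_timepoints)
        w <- net2$weights
        for (t in seq_len(n_timepoints))
          w[t, , ] <- w[t, , ] + edges_to_matrix(noise[, t], n_nodes)
        net2 <- dynamic_network(w)
      } else {
        net2 <- shuffle_timepoints(net2, v)
      }
      c(dns(pair$net1, net2)$value, dnes(pair$net1, net2)$value)
    }, numeric(2L))
    samples <- data.frame(replicate = seq_len(n_reps), variable = vals,
                          dns = res[1L, ], dnes = res[2L, ])
    new_experiment_result(id, varname, 0, samples, seed)
  })
}

#' Bin an experiment's replicates and average each index
#'
#' Utility for monotonicity checks and quick plotting: splits the swept
#' variable's range into equal-width bins and returns per-bin means.
#'
#' @param result An `experiment_result`.
#' @param n_bins Number of equal-width bins.
#' @return A data frame with `bin_mid`, `n`, `dns`, `dnes`.
#' @export
binned_means <- function(result, n_bins = 5L) {
  s <- result$samples
  br <- seq(min(s$variable), max(s$variable), length.out = n_bins + 1L)
  bin <- cut(s$variable, br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    bin_mid = (br[-1L] + br[-length(br)]) / 2,
    n = as.integer(tabulate(bin, n_bins)),
    dns = vapply(seq_len(n_bins),
                 function(b) mean(s$dns[bin == b]), numeric(1L)),
    dnes = vapply(seq_len(n_bins),
                  function(b) mean(s$dnes[bin == b]), numeric(1L)))
  out
}
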