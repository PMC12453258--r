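# Replicate-level validation harness: one call simulates a scenario replicate,
# runs the full pipeline, and returns the recovery metrics used by the
# package's simulation-based validation.

#' Run one validation replicate of the barrier-plus-pulse scenario
#'
#' Simulates the 8 x 12 barrier scenario under the requested sampling scheme
#' and pulse fraction, fits the baseline surface at fixed penalties, runs
#' outlier detection, recipient ranking, the pre-fit source scan and the
#' joint re-fit, and scores recovery against the simulated truth.
#'
#' For `K > 1` the additional edges are fitted iteratively; the support
#' statistic of a prospective (K+1)-th edge is returned as well, so null
#' calibrations can count K support values without paying for the last
#' joint fit.
#'
#' @param seed replicate seed.
#' @param sampling "dense" or "sparse".
#' @param c simulated pulse fraction (0 for the null scenario).
#' @param lambda_w,lambda_q fixed penalty parameters.
#' @param K number of edges to fit.
#' @param maxit inner optimizer iterations.
#' @return list with `metrics` (dest_ok, hops_source, c_hat, Lr per edge,
#'   cov2, r2_baseline, fst_cross), the fitted `edges`, and the inputs.
#' @export
run_validation_replicate <- function(seed, sampling = c("sparse", "dense"),
                                     c = 0.5, lambda_w = 1, lambda_q = 10,
                                     K = 1, maxit = 400) {
  sampling <- match.arg(sampling)
  spec <- scenario_spec(sampling = sampling, c = c, seed = seed)
  sim <- simulate_coalescent_grid(spec)
  asg <- structure(list(deme_of_sample = sim$sample_demes,
                        observed_demes = sort(unique(sim$sample_demes)),
                        counts = as.integer(table(sim$sample_demes))),
                   class = "sample_assignment")
  bundle <- observed_genetic_distances(sim$genotypes, asg)
  fit <- fit_k_edges(bundle, sim$grid, asg, K = K, lambda_w = lambda_w,
                     lambda_q = lambda_q, maxit = maxit)
  edges <- fit$edges
  Lr <- vapply(edges, `[[`, numeric(1), "Lr")
  # support statistic a (K+1)-th edge would start from
  dev_next <- deviation_statistics(bundle$D_hat,
                                   fitted_distances(fit$surface, fit$events))
  metrics <- list(r2_baseline = fit$r2_trajectory[1],
                  r2_trajectory = fit$r2_trajectory,
                  Lr = Lr,
                  Lr_next = if (dev_next$degenerate) NA_real_ else
                    as.numeric(mixture_support(dev_next$x)))
  if (length(edges)) {
    e1 <- edges[[1]]
    hops <- graph_hop_distances(sim$grid, sim$truth$source)
    scan <- e1$scan
    metrics$dest_ok <- e1$dest == sim$truth$dest
    metrics$hops_source <- hops[e1$source]
    metrics$c_hat <- e1$c
    metrics$cov2 <- scan$loglik[scan$node == sim$truth$source] >=
      max(scan$loglik) - 2
  }
  list(metrics = metrics, edges = edges, fit = fit, sim = sim, asg = asg,
       bundle = bundle)
}

#' Mean cross-barrier FST over no-pulse replicates
#'
#' @param seeds replicate seeds.
#' @param sampling sampling scheme used for the FST calibration runs.
#' @return per-seed mean FST between same-row deme pairs flanking the barrier.
#' @export
fst_calibration <- function(seeds = 1:5, sampling = "dense") {
  vapply(seeds, function(s) {
    spec <- scenario_spec(sampling = sampling, c = 0, seed = s)
    sim <- simulate_coalescent_grid(spec)
    cross_barrier_fst(sim, spec$barrier_cols)
  }, numeric(1))
}
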