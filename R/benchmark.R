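#' Simulate/infer/evaluate benchmark over replicate networks
#'
#' Generates `replicates` independent random networks, simulates noisy
#' steady-state single-gene perturbation data for each, infers the network
#' back, and scores directed and undirected PPV and sensitivity against the
#' generating truth (self-loops excluded).
#'
#' @param n_genes,avg_in_degree,noise_sd,n_experiments simulator settings,
#'   see [sim_config()].
#' @param replicates number of replicate networks.
#' @param k,beam_width,workers inference settings, see [nir_config()].
#' @param seed base seed; replicate r uses `seed + r - 1`.
#' @return An object of class `nir_benchmark`: list with `per_replicate`
#'   (data frame of per-replicate, per-mode counts and ratios) and
#'   `summary` (mean and sd of ppv and se per mode).
#' @export
nir_benchmark <- function(n_genes, replicates, avg_in_degree, noise_sd, k,
                          seed = 1L, n_experiments = n_genes,
                          beam_width = k, workers = 1L) {
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("replicates must be a positive integer")
  cfg_inf <- nir_config(k = k, beam_width = beam_width, workers = workers)
  rows <- vector("list", 2L * replicates)
  for (r in seq_len(replicates)) {
    cfg <- sim_config(n_genes = n_genes, avg_in_degree = avg_in_degree,
                      noise_sd = noise_sd, n_experiments = n_experiments,
                      seed = seed + r - 1L)
    truth <- random_network(cfg)
    dat <- steady_state_data(truth, cfg)
    net <- infer_network(dat$expression, dat$perturbation, cfg_inf)
    for (mode in c("directed", "undirected")) {
      rep_df <- as.data.frame(ppv_se(net, truth, mode))
      rep_df <- cbind(data.frame(replicate = r, seed = cfg$seed), rep_df)
      rows[[2L * (r - 1L) + match(mode, c("directed", "undirected"))]] <-
        rep_df
    }
  }
  per_replicate <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_replicate, per_replicate$mode),
    function(d) data.frame(
      mode = d$mode[1],
      ppv_mean = mean(d$ppv, na.rm = TRUE),
      ppv_sd = stats::sd(d$ppv, na.rm = TRUE),
      se_mean = mean(d$se, na.rm = TRUE),
      se_sd = stats::sd(d$se, na.rm = TRUE),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(list(per_replicate = per_replicate, summary = agg,
                 n_genes = as.integer(n_genes), replicates = replicates,
                 k = as.integer(k)),
            class = "nir_benchmark")
}

#' @export
print.nir_benchmark <- function(x, ...) {
  cat(sprintf("nir_benchmark: %d replicates of %d genes, k = %d\n",
              x$replicates, x$n_genes, x$k))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s PPV = %.3f +/- %.3f   Se = %.3f +/- %.3f\n",
                s$mode[i], s$ppv_mean[i], s$ppv_sd[i],
                s$se_mean[i], s$se_sd[i]))
  }
  invisible(x)
}
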