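# Independent least-squares and search oracles used to cross-check the
# Gram/Cholesky fast path.  They work from the raw data matrix through QR
# (lm.fit), never through the package's normal-equation route.

rand_X <- function(n, m, seed) {
  set.seed(seed)
  matrix(stats::rnorm(n * m), n, m)
}

# Hand-built response projection (the documented structure) for a response
# vector y that need not come from a perturbation design.
proj_from <- function(X, y, gene = 1L) {
  structure(list(xty = as.vector(X %*% y), yty = sum(y * y),
                 gene = as.integer(gene)),
            class = "response_projection")
}

# QR least squares of y on the rows of X indexed by subset.
ls_oracle <- function(X, y, subset) {
  fit <- stats::lm.fit(x = t(X[subset, , drop = FALSE]), y = y)
  list(coefficients = unname(fit$coefficients),
       rss = sum(fit$residuals^2))
}

# Exhaustive best-subset search of size k via the QR oracle, with the same
# lexicographic tie rule the search uses.
brute_force_best <- function(X, y, cand, k) {
  combs <- utils::combn(cand, k)
  best <- NULL
  for (c in seq_len(ncol(combs))) {
    s <- combs[, c]
    fit <- ls_oracle(X, y, s)
    if (is.null(best) || fit$rss < best$rss - 1e-12 * max(1, sum(y^2)))
      best <- list(subset = s, rss = fit$rss,
                   coefficients = fit$coefficients)
  }
  best
}

# Re-enactment of the beam bookkeeping (seeding, extension, deduplication)
# on top of the QR oracle; returns the number of candidate evaluations so
# the instrumentation counter of the fast path can be checked against it.
beam_count_oracle <- function(X, y, cand, k, beam_width) {
  count <- 0L
  score <- function(s) ls_oracle(X, y, s)$rss
  beam <- lapply(cand, function(c) list(s = c, rss = {
    count <<- count + 1L; score(c)
  }))
  beam <- beam[order(vapply(beam, `[[`, 0, "rss"))]
  beam <- beam[seq_len(min(beam_width, length(beam)))]
  for (step in seq_len(k)[-1]) {
    seen <- character(0)
    pool <- list()
    for (b in beam) {
      for (c in setdiff(cand, b$s)) {
        ns <- sort(c(b$s, c))
        key <- paste(ns, collapse = ",")
        if (key %in% seen) next
        seen <- c(seen, key)
        count <- count + 1L
        pool[[length(pool) + 1L]] <- list(s = ns, rss = score(ns))
      }
    }
    pool <- pool[order(vapply(pool, `[[`, 0, "rss"))]
    beam <- pool[seq_len(min(beam_width, length(pool)))]
  }
  list(count = count, best = beam[[1]])
}

# Small random simulated instance shared by several tests.
sim_instance <- function(n_genes, avg_in_degree, noise_sd, seed,
                         n_experiments = n_genes) {
  cfg <- sim_config(n_genes = n_genes, avg_in_degree = avg_in_degree,
                    noise_sd = noise_sd, seed = seed,
                    n_experiments = n_experiments)
  truth <- random_network(cfg)
  dat <- steady_state_data(truth, cfg)
  list(cfg = cfg, truth = truth, X = dat$expression, P = dat$perturbation)
}
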