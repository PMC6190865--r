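# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact log model evidence for the VB model (Gaussian coefficient prior
# independent of the Gamma noise precision): marginalise w analytically per
# lambda, then integrate over lambda on a log grid.
exact_log_evidence <- function(y, X, priors, lo = -12, hi = 10, step = 0.02) {
  n <- length(y)
  log_py_lam <- function(lam) {
    S <- diag(n) / lam + X %*% t(X) / priors$coeff_precision
    ch <- chol(S)
    -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
              sum(backsolve(ch, y, transpose = TRUE)^2))
  }
  ts <- seq(lo, hi, by = step)
  lv <- vapply(ts, function(tt) {
    l <- exp(tt)
    log_py_lam(l) +
      stats::dgamma(l, priors$noise_shape, rate = priors$noise_rate, log = TRUE) + tt
  }, numeric(1))
  m <- max(lv)
  log(sum(exp(lv - m)) * step) + m
}

# Exact posterior mean of the group frequency r1 (K = 2) by enumerating all
# 2^N subject-to-model assignments of the Dirichlet-multinomial hierarchy.
exact_group_r1 <- function(lme, alpha0 = c(1, 1)) {
  N <- nrow(lme)
  grids <- as.matrix(expand.grid(rep(list(1:2), N)))
  logw <- apply(grids, 1, function(m) {
    n1 <- sum(m == 1)
    sum(lme[cbind(seq_len(N), m)]) +
      lbeta(alpha0[1] + n1, alpha0[2] + N - n1) - lbeta(alpha0[1], alpha0[2])
  })
  w <- exp(logw - max(logw)); w <- w / sum(w)
  n1s <- apply(grids, 1, function(m) sum(m == 1))
  sum(w * (alpha0[1] + n1s) / (sum(alpha0) + N))
}

# Recursive flood fill for connected-component labelling, the brute-force
# counterpart of the igraph-based extractor.
floodfill_sizes <- function(bin, connectivity = 6) {
  d <- dim(bin)
  off <- switch(as.character(connectivity),
                "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)),
                "18" = {
                  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  o[rowSums(abs(o)) %in% 1:2, ]
                },
                "26" = {
                  o <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
                  o[rowSums(abs(o)) > 0, ]
                })
  seen <- array(FALSE, d)
  sizes <- integer(0)
  for (start in which(bin & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue) > 0L) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      cc <- arrayInd(cur, d)
      for (r in seq_len(nrow(off))) {
        nb <- cc + off[r, , drop = FALSE]
        if (any(nb < 1) || any(nb > d)) next
        lin <- (nb[3] - 1) * d[1] * d[2] + (nb[2] - 1) * d[1] + nb[1]
        if (bin[lin] && !seen[lin]) {
          seen[lin] <- TRUE
          queue <- c(queue, lin)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

# Small simulated group reused by several tests: strong planted effect on a
# coarse grid so VB model recovery is quick and decisive.
tiny_group <- function(n_subjects = 4, assignments = NULL, noise_sd = 0.5,
                       effect_size = 3, seed = 7) {
  simulate_group(n_subjects = n_subjects,
                 n_trials_per_condition = 10,
                 assignments = assignments,
                 effect_size = effect_size, noise_sd = noise_sd,
                 grid_size = c(12, 12), n_time = 8, effect_time = 3:6,
                 channel_layout = 4, effect_channel_block = c(2, 3),
                 seed = seed)
}
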