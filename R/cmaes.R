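# Minimal covariance matrix adaptation evolution strategy (CMA-ES) for
# bounded, low-dimensional black-box minimization, following the standard
# (mu/mu_w, lambda) formulation with cumulative step-size adaptation and
# rank-one plus rank-mu covariance updates. Candidates are clipped to the
# box; the objective receives a whole generation as a matrix so callers can
# evaluate it in batch.
#
# fn: function(matrix lambda x d) -> numeric vector of costs
# returns list(par, value, evaluations)
cma_es_min <- function(fn, x0, sigma0, lower, upper, popsize, max_evaluations,
                       stream) {
  d <- length(x0)
  lambda <- as.integer(popsize)
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mu_eff <- 1 / sum(wts^2)
  cc <- (4 + mu_eff / d) / (d + 4 + 2 * mu_eff / d)
  cs <- (mu_eff + 2) / (d + mu_eff + 5)
  c1 <- 2 / ((d + 1.3)^2 + mu_eff)
  cmu <- min(1 - c1, 2 * (mu_eff - 2 + 1 / mu_eff) / ((d + 2)^2 + mu_eff))
  damps <- 1 + 2 * max(0, sqrt((mu_eff - 1) / (d + 1)) - 1) + cs
  chiN <- sqrt(d) * (1 - 1 / (4 * d) + 1 / (21 * d^2))

  xmean <- pmin(pmax(x0, lower), upper)
  sigma <- sigma0
  pc <- ps <- numeric(d)
  C <- diag(d)
  best_par <- xmean
  best_val <- Inf
  evals <- 0L
  gen <- 0L
  while (evals + lambda <= max_evaluations) {
    gen <- gen + 1L
    eig <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eig$values, 1e-20))
    B <- eig$vectors
    z <- matrix(stream_draw(stream, stats::rnorm, d * lambda), nrow = lambda)
    y <- z %*% t(B %*% diag(D, d))
    xs <- sweep(sigma * y, 2L, xmean, "+")
    xs_clipped <- pmin(pmax(xs, matrix(lower, lambda, d, byrow = TRUE)),
                       matrix(upper, lambda, d, byrow = TRUE))
    costs <- fn(xs_clipped)
    evals <- evals + lambda
    ord <- order(costs)
    if (costs[ord[1L]] < best_val) {
      best_val <- costs[ord[1L]]
      best_par <- xs_clipped[ord[1L], ]
    }
    sel <- ord[seq_len(mu)]
    xold <- xmean
    xmean <- as.numeric(wts %*% xs_clipped[sel, , drop = FALSE])
    ymean <- (xmean - xold) / sigma
    Cinv_sqrt_y <- B %*% ((t(B) %*% ymean) / D)
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mu_eff) * as.numeric(Cinv_sqrt_y)
    hsig <- sqrt(sum(ps^2)) /
      sqrt(1 - (1 - cs)^(2 * gen)) / chiN < 1.4 + 2 / (d + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mu_eff) * ymean
    artmp <- sweep(xs_clipped[sel, , drop = FALSE], 2L, xold, "-") / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * t(artmp) %*% (artmp * wts)
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    if (!is.finite(sigma) || sigma > 1e3) sigma <- sigma0
    if (sigma < 1e-12) break
  }
  list(par = best_par, value = best_val, evaluations = evals)
}
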