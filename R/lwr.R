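#' Locally weighted linear regression forward model
#'
#' The forward model is built uniquely from the experiments logged so far:
#' for a query formulation, stored formulations are weighted by a Gaussian
#' kernel `w_i = exp(-||x_i - x_q||^2 / (2 h^2))` in raw ratio space and a
#' ridge-regularized weighted linear fit (independent per observation
#' dimension) is evaluated at the query. When the effective kernel support
#' falls below `min_points` the prediction falls back to the kernel-weighted
#' mean of the stored observations. Predictions are clipped to be
#' non-negative.
#'
#' @param ds a non-empty [exploration_dataset()]
#' @param query an [oil_formulation()], or an n x 4 matrix of formulations
#'   (one query per row) for batch prediction
#' @param cfg a [forward_model_config()]
#' @return a [behavior_observation()] for a single query, or an n x 2 matrix
#'   (columns speed, count) for a matrix query
#' @export
lwr_predict <- function(ds, query, cfg = forward_model_config()) {
  stopifnot(inherits(ds, "exploration_dataset"))
  if (n_records(ds) == 0L) {
    stop("model unavailable: empty dataset", call. = FALSE)
  }
  single <- !is.matrix(query)
  q <- if (single) matrix(unclass(oil_formulation(query)), nrow = 1L) else
    query
  x <- dataset_formulations(ds)
  y <- dataset_observations(ds)
  pred <- lwr_predict_matrix(x, y, q, cfg)
  if (single) behavior_observation(pred[1L, 1L], pred[1L, 2L]) else pred
}

# core batched LWR: x (n x d), y (n x m), q (k x d) -> (k x m)
lwr_predict_matrix <- function(x, y, q, cfg) {
  n <- nrow(x)
  d <- ncol(x)
  h2 <- 2 * cfg$bandwidth_h^2
  # squared distances n x k
  d2 <- outer(rowSums(x^2), rowSums(q^2), "+") - 2 * tcrossprod(x, q)
  d2[d2 < 0] <- 0
  w <- exp(-d2 / h2)
  pred <- matrix(0, nrow(q), ncol(y))
  pen <- diag(c(0, rep(1, d)), d + 1L) * cfg$ridge_lambda
  for (j in seq_len(nrow(q))) {
    wj <- w[, j]
    sw <- sum(wj)
    if (sw <= 0) {
      wj <- rep(1 / n, n)  # degenerate: all weights underflowed
      sw <- 1
    }
    ess <- sw^2 / sum(wj^2)
    if (ess >= cfg$min_points && n > d) {
      # design centered at the query: the intercept is the prediction
      z <- cbind(1, sweep(x, 2L, q[j, ], "-"))
      zw <- z * wj
      A <- crossprod(zw, z) + pen
      b <- crossprod(zw, y)
      beta <- tryCatch(solve(A, b), error = function(e) NULL)
      if (is.null(beta)) {
        pred[j, ] <- colSums(y * wj) / sw
      } else {
        pred[j, ] <- beta[1L, ]
      }
    } else {
      pred[j, ] <- colSums(y * wj) / sw
    }
  }
  pred[pred < 0] <- 0
  colnames(pred) <- colnames(y)
  pred
}
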