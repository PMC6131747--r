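#' Item and test information
#'
#' Fisher information of a graded-response item at latent level `theta`:
#' `I_i(theta) = lambda^2 * sum_k (P*_k(1-P*_k) - P*_{k+1}(1-P*_{k+1}))^2
#' / P_k`, where `P*_k = P(y >= k)` and `P_k` the category probability.
#' For a binary item this reduces to the 2PL information
#' `lambda^2 P(1-P)`.  Test information is the sum over items; categories
#' with zero probability (infinite sentinel thresholds) contribute
#' nothing.
#'
#' @param params An [item_params()] object.
#' @param theta Numeric vector of latent trait values.
#' @return `item_information`: a `length(theta) x n_items` matrix.
#' @export
item_information <- function(params, theta) {
  stopifnot(inherits(params, "item_params"))
  out <- matrix(0, length(theta), length(params$id),
                dimnames = list(NULL, params$id))
  for (i in seq_along(params$id)) {
    lam <- params$lambda[i]
    if (is.na(lam)) next
    cp <- grm_cum_probs(lam, params$tau[[i]], theta)
    v <- cp * (1 - cp)                       # P*_k (1 - P*_k), k = 0..K
    P <- cp[, -ncol(cp), drop = FALSE] - cp[, -1L, drop = FALSE]
    num <- (v[, -ncol(v), drop = FALSE] - v[, -1L, drop = FALSE])^2
    contrib <- ifelse(P > 1e-12, num / pmax(P, 1e-12), 0)
    out[, i] <- lam^2 * rowSums(contrib)
  }
  out
}

#' @rdname item_information
#' @return `test_information`: a numeric vector, the row sums of the item
#'   information matrix.
#' @export
test_information <- function(params, theta) {
  rowSums(item_information(params, theta))
}

#' Marginal reliability at a latent level
#'
#' `rel(theta) = I(theta) / (I(theta) + 1)`, i.e. the proportion of
#' latent-score variance not due to measurement error when scoring with a
#' unit-variance prior.
#'
#' @inheritParams item_information
#' @return Numeric vector of reliabilities in `[0, 1)`.
#' @export
reliability <- function(params, theta) {
  I <- test_information(params, theta)
  I / (I + 1)
}
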