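#' Residual diagnostics for a unidimensional calibration
#'
#' Compares the observed pairwise polychoric correlations of an
#' instrument's items with the correlations implied by the fitted
#' unidimensional model.  On the logistic latent-response scale each
#' rating discretizes `y*_i = lambda_i * theta + e_i` with
#' `Var(e) = pi^2 / 3`, so the model-implied correlation is
#' `rho_ij = lambda_i * lambda_j / sqrt((lambda_i^2 + pi^2/3) *
#' (lambda_j^2 + pi^2/3))`.  Observed polychorics use the standard
#' two-step estimator: thresholds from the marginal proportions, then
#' one-dimensional maximum likelihood for the correlation under a
#' bivariate-normal latent-response model.  The summary statistic is
#' the root-mean-square residual (RMSR) over item pairs, a
#' unidimensionality diagnostic: data generated by a one-factor model
#' give RMSR near zero, while multidimensional data inflate it.
#'
#' @param table A polytomous [response_table()].
#' @param params Fitted [item_params()] for the instrument's items.
#' @param min_pairs Minimum jointly observed assessments per item pair;
#'   pairs below it (or with a degenerate margin) are skipped with a
#'   warning.
#' @return A list with `pairs` (data.frame: `item_i`, `item_j`,
#'   `observed`, `implied`, `residual`, `n`) and `rmsr`.
#' @export
residual_diagnostics <- function(table, params, min_pairs = 20L) {
  stopifnot(inherits(params, "item_params"))
  Y <- response_matrix(table, params$id)
  J <- ncol(Y)
  s <- pi^2 / 3
  rows <- list()
  skipped <- character(0)
  for (i in seq_len(J - 1L)) {
    for (j in (i + 1L):J) {
      ok <- !is.na(Y[, i]) & !is.na(Y[, j])
      yi <- Y[ok, i]; yj <- Y[ok, j]
      lab <- paste0(params$id[i], ":", params$id[j])
      if (sum(ok) < min_pairs || length(unique(yi)) < 2L ||
          length(unique(yj)) < 2L) {
        skipped <- c(skipped, lab)
        next
      }
      obs <- polychoric_cor(yi, yj)
      if (is.na(obs)) { skipped <- c(skipped, lab); next }
      li <- params$lambda[i]; lj <- params$lambda[j]
      implied <- li * lj / sqrt((li^2 + s) * (lj^2 + s))
      rows[[length(rows) + 1L]] <- data.frame(
        item_i = params$id[i], item_j = params$id[j],
        observed = obs, implied = implied, residual = obs - implied,
        n = sum(ok), stringsAsFactors = FALSE)
    }
  }
  if (length(skipped))
    warning("skipped item pair(s) with too few joint observations or ",
            "degenerate margins: ", paste(skipped, collapse = ", "))
  pairs <- do.call(rbind, rows)
  list(pairs = pairs, rmsr = sqrt(mean(pairs$residual^2)))
}

# Two-step polychoric correlation of two integer-coded ordinal vectors.
# Thresholds come from the marginal cumulative proportions (only
# categories actually observed contribute thresholds); the correlation
# maximizes the bivariate-normal contingency-table likelihood.
polychoric_cor <- function(x, y) {
  thr <- function(v) {
    p <- cumsum(prop.table(table(v)))
    qnorm(p[-length(p)])
  }
  a <- c(-Inf, thr(x), Inf)
  b <- c(-Inf, thr(y), Inf)
  tab <- table(x, y)
  if (length(a) < 3L || length(b) < 3L) return(NA_real_)
  cell_probs <- function(rho) {
    S <- matrix(c(1, rho, rho, 1), 2L)
    # CDF at every threshold grid point, then rectangle differences
    Phi <- matrix(0, length(a), length(b))
    for (u in seq_along(a)) {
      for (v in seq_along(b)) {
        Phi[u, v] <- if (a[u] == -Inf || b[v] == -Inf) {
          0
        } else if (a[u] == Inf && b[v] == Inf) {
          1
        } else if (a[u] == Inf) {
          stats::pnorm(b[v])
        } else if (b[v] == Inf) {
          stats::pnorm(a[u])
        } else {
          mvtnorm::pmvnorm(upper = c(a[u], b[v]), corr = S)[1L]
        }
      }
    }
    P <- Phi[-1L, -1L, drop = FALSE] - Phi[-nrow(Phi), -1L, drop = FALSE] -
      Phi[-1L, -ncol(Phi), drop = FALSE] +
      Phi[-nrow(Phi), -ncol(Phi), drop = FALSE]
    pmax(P, 1e-12)
  }
  nll <- function(rho) -sum(tab * log(cell_probs(rho)))
  optimize(nll, c(-0.995, 0.995))$minimum
}
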