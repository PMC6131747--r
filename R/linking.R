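#' Haebara characteristic-curve linking
#'
#' Finds the affine transform of the latent metric, `theta_ref = A *
#' theta_target + B`, that makes the anchor items' characteristic curves
#' agree between two separately identified calibrations.  The criterion
#' is the weighted sum over quadrature nodes (standard-normal weights on
#' the reference metric) of squared differences between each anchor
#' pair's cumulative response curves, with the target item's parameters
#' expressed on the reference metric (`lambda' = lambda / A`,
#' `tau' = tau + lambda' * B`).  Minimization runs over `(log A, B)` by
#' Nelder-Mead from the identity transform with a BFGS polish, so `A > 0`
#' by construction.
#'
#' With `symmetric = TRUE` the criterion adds the mirror-image term (the
#' reference anchors transformed onto the target metric, weighted on the
#' target metric); the default is the common non-symmetric form.
#'
#' @param anchors_ref [item_params()] for the reference calibration's
#'   anchor items.
#' @param anchors_target [item_params()] for the target calibration's
#'   anchor items, in the pair order of `anchor_map` (or of
#'   `anchors_ref` when no map is given).
#' @param anchor_map Optional data.frame with `reference_item` and
#'   `target_item` columns (one row per anchor pair), as produced by
#'   [build_anchor_maps()].
#' @param quadrature A [grm_quadrature()] for the criterion.
#' @param symmetric Use the symmetrized criterion.
#' @param direction Optional character vector `c(target, reference)`
#'   recording which instrument is mapped onto which.
#' @return An object of class `linking_transform`: list with `A`, `B`,
#'   `direction`, `criterion` (minimized loss), `criterion_identity`
#'   (loss at `(1, 0)`), `converged`, and `anchors` (the pair table
#'   used).
#' @export
haebara_link <- function(anchors_ref, anchors_target, anchor_map = NULL,
                         quadrature = grm_quadrature(),
                         symmetric = FALSE, direction = NULL) {
  stopifnot(inherits(anchors_ref, "item_params"),
            inherits(anchors_target, "item_params"))
  if (is.null(anchor_map)) {
    if (length(anchors_ref) != length(anchors_target))
      stop("without an anchor_map, anchor parameter sets must pair up ",
           "one-to-one in order")
    anchor_map <- data.frame(reference_item = anchors_ref$id,
                             target_item = anchors_target$id,
                             stringsAsFactors = FALSE)
  }
  if (nrow(anchor_map) < 2L)
    stop("Haebara linking needs at least 2 anchor pairs")
  ref <- anchors_ref[anchor_map$reference_item]
  tgt <- anchors_target[anchor_map$target_item]
  nodes <- quadrature$nodes
  w <- quadrature$weights

  pair_loss <- function(a_from, a_to, A, B) {
    # `a_from` transformed onto the metric of `a_to`; squared cumulative
    # -curve differences at `nodes` under weights `w`
    loss <- 0
    for (i in seq_along(a_to$id)) {
      lam_t <- a_from$lambda[i] / A
      tau_t <- a_from$tau[[i]] + lam_t * B
      # compare over the common (smaller) number of cumulative curves
      K1 <- min(length(tau_t), length(a_to$tau[[i]]))
      for (k in seq_len(K1)) {
        d <- plogis(a_to$lambda[i] * nodes - a_to$tau[[i]][k]) -
          plogis(lam_t * nodes - tau_t[k])
        loss <- loss + sum(w * d^2)
      }
    }
    loss
  }
  crit <- function(p) {
    A <- exp(p[1L]); B <- p[2L]
    loss <- pair_loss(tgt, ref, A, B)
    if (symmetric)
      loss <- loss + pair_loss(ref, tgt, 1 / A, -B / A)
    loss
  }
  o1 <- optim(c(0, 0), crit, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-12))
  o2 <- optim(o1$par, crit, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-14))
  best <- if (o2$value <= o1$value) o2 else o1
  structure(list(A = exp(best$par[1L]), B = best$par[2L],
                 direction = direction,
                 criterion = best$value, criterion_identity = crit(c(0, 0)),
                 converged = best$convergence == 0L,
                 anchors = anchor_map),
            class = "linking_transform")
}

#' Identity linking transform
#' @return A `linking_transform` with `A = 1`, `B = 0`.
#' @export
identity_transform <- function() {
  structure(list(A = 1, B = 0, direction = NULL, criterion = 0,
                 criterion_identity = 0, converged = TRUE,
                 anchors = NULL),
            class = "linking_transform")
}

#' @export
print.linking_transform <- function(x, ...) {
  cat("<linking_transform> A = ", format(x$A, digits = 6),
      ", B = ", format(x$B, digits = 6),
      " (criterion ", format(x$criterion, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Re-express item parameters on the reference metric
#'
#' Applies a linking transform to item parameters estimated on a target
#' metric: `lambda' = lambda / A`, `tau'_k = tau_k + lambda' * B`.
#' Threshold ordering and fixed flags are preserved; the characteristic
#' curves are invariant (`P(y >= k | theta)` under the original
#' parameters equals the probability under the transformed parameters at
#' `A * theta + B`).
#'
#' @param params An [item_params()] object.
#' @param transform A `linking_transform`.
#' @return An [item_params()] object on the reference metric.
#' @export
transform_params <- function(params, transform) {
  stopifnot(inherits(params, "item_params"),
            inherits(transform, "linking_transform"), transform$A > 0)
  lam <- params$lambda / transform$A
  tau <- lapply(seq_along(params$id), function(i)
    params$tau[[i]] + lam[i] * transform$B)
  item_params(params$id, lam, tau, params$fixed_lambda, params$fixed_tau)
}

#' Re-express latent scores on the reference metric
#'
#' @param theta Numeric vector of latent scores on the target metric.
#' @param transform A `linking_transform`.
#' @return `A * theta + B`.
#' @export
transform_scores <- function(theta, transform) {
  stopifnot(inherits(transform, "linking_transform"))
  transform$A * theta + transform$B
}
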