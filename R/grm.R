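#' Fixed quadrature over the latent trait
#'
#' Equally spaced nodes with standard-normal weights, normalized to sum
#' to one.  Because the integrands (posterior kernels under a normal
#' prior) are smooth and effectively vanish at the interval ends, this
#' rectangular rule converges super-algebraically in the node count; the
#' default of 61 nodes on \[-6, 6\] reproduces a 2001-point grid to well
#' below 1e-8 in the marginal log-likelihood.
#'
#' @param n Number of nodes.
#' @param range Interval covered by the nodes.
#' @return A list with `nodes` and `weights` of class `grm_quadrature`.
#' @export
grm_quadrature <- function(n = 61L, range = c(-6, 6)) {
  stopifnot(n >= 5L, range[1] < range[2])
  nodes <- seq(range[1], range[2], length.out = n)
  w <- dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "grm_quadrature")
}

# Cumulative probabilities P(y >= k | theta), k = 0..K:
# a length(theta) x (K+1) matrix with first column 1 and last column 0.
grm_cum_probs <- function(lambda, tau, theta) {
  K <- length(tau) + 1L
  out <- matrix(0, length(theta), K + 1L)
  out[, 1L] <- 1
  for (k in seq_along(tau))
    out[, k + 1L] <- plogis(lambda * theta - tau[k])
  out
}

# Category probabilities: length(theta) x K matrix of P(y = k | theta).
grm_cat_probs <- function(lambda, tau, theta) {
  cp <- grm_cum_probs(lambda, tau, theta)
  cp[, -ncol(cp), drop = FALSE] - cp[, -1L, drop = FALSE]
}

#' Item characteristic curves of the graded response model
#'
#' Category response probabilities `P(y = k | theta)` for each item, with
#' `P(y = k) = P(y >= k) - P(y >= k+1)` and
#' `P(y >= k) = plogis(lambda * theta - tau_k)`.
#'
#' @param params An [item_params()] object.
#' @param theta Numeric vector of latent trait values.
#' @param item Optional single item id or index; when supplied, a matrix
#'   `length(theta) x K` is returned directly.
#' @return A named list of probability matrices (rows: `theta`, columns:
#'   categories `0..K-1`), or a single matrix when `item` is given.
#' @export
icc <- function(params, theta, item = NULL) {
  stopifnot(inherits(params, "item_params"))
  if (!is.null(item)) {
    p1 <- params[item]
    return(grm_cat_probs(p1$lambda[1L], p1$tau[[1L]], theta))
  }
  out <- lapply(seq_along(params$id), function(i)
    grm_cat_probs(params$lambda[i], params$tau[[i]], theta))
  names(out) <- params$id
  out
}

# Rating matrix (n x J, integer 0-based, NA allowed) from a response
# table, with items ordered as in `ids`.
response_matrix <- function(table, ids) {
  as.matrix(as.data.frame(table)[, ids, drop = FALSE])
}

# Per-node log-likelihood of every assessment: a Q x n matrix whose
# column j is sum_i log P(y_ji | theta_q); missing responses contribute 0.
node_loglik <- function(Y, params, nodes) {
  Q <- length(nodes)
  A <- matrix(0, Q, nrow(Y))
  for (i in seq_len(ncol(Y))) {
    if (is.na(params$lambda[i])) next  # degenerate item excluded
    logP <- log(pmax(grm_cat_probs(params$lambda[i], params$tau[[i]], nodes),
                     1e-300))
    idx <- Y[, i] + 1L
    obs <- !is.na(idx)
    if (any(obs)) A[, obs] <- A[, obs] + logP[, idx[obs], drop = FALSE]
  }
  A
}

# log-sum-exp down columns of A + log(w)
posterior_pieces <- function(A, weights) {
  B <- A + log(weights)
  mx <- apply(B, 2L, max)
  lse <- mx + log(colSums(exp(sweep(B, 2L, mx))))
  post <- exp(sweep(B, 2L, lse))
  list(loglik = sum(lse), post = post)
}

#' Marginal log-likelihood of a response table
#'
#' Sum over assessments of the log of the integral of the conditional
#' response-pattern probability against the standard-normal latent
#' density, evaluated by fixed quadrature.  Missing responses contribute
#' nothing to an assessment's likelihood term; an all-missing assessment
#' contributes exactly 0.
#'
#' @param table A [response_table()] (or a bare data.frame with the item
#'   columns).
#' @param params An [item_params()] object covering all items present.
#' @param quadrature A [grm_quadrature()].
#' @return The marginal log-likelihood (scalar).
#' @export
grm_loglik <- function(table, params, quadrature = grm_quadrature()) {
  Y <- response_matrix(table, params$id)
  A <- node_loglik(Y, params, quadrature$nodes)
  posterior_pieces(A, quadrature$weights)$loglik
}

#' Expected a posteriori latent trait scores
#'
#' Posterior mean and standard deviation of the latent severity given an
#' assessment's item responses, under a standard-normal prior.  An
#' assessment with no observed items returns the prior: mean 0, SD 1.
#'
#' @inheritParams grm_loglik
#' @return A data.frame with columns `theta` and `se` (posterior SD), one
#'   row per assessment, plus `person_id`/`day` when present in `table`.
#' @export
eap_scores <- function(table, params, quadrature = grm_quadrature()) {
  Y <- response_matrix(table, params$id)
  A <- node_loglik(Y, params, quadrature$nodes)
  post <- posterior_pieces(A, quadrature$weights)$post
  th <- quadrature$nodes
  m <- colSums(post * th)
  v <- colSums(post * th^2) - m^2
  none <- rowSums(!is.na(Y)) == 0L
  m[none] <- 0
  v[none] <- 1
  out <- data.frame(theta = m, se = sqrt(pmax(v, 0)))
  if (all(c("person_id", "day") %in% names(table)))
    out <- cbind(as.data.frame(table)[, c("person_id", "day")], out)
  out
}

# ---- threshold reparameterization -----------------------------------------
# Free thresholds are optimized on an unconstrained scale that preserves
# strict ordering around any fixed thresholds:
#   * a fully free chain uses (tau_1, log-differences);
#   * a run above a fixed value L uses cumulative exp steps up from L;
#   * a run below a fixed value U uses cumulative exp steps down from U;
#   * a run between fixed L < U uses a stick-breaking map into (L, U).
# Infinite sentinel thresholds behave as absent bounds.
tau_codec <- function(tau, fixed) {
  K1 <- length(tau)
  fidx <- which(fixed)
  runs <- list()
  i <- 1L
  while (i <= K1) {
    if (!fixed[i]) {
      j <- i
      while (j < K1 && !fixed[j + 1L]) j <- j + 1L
      lo <- if (any(fidx < i)) tau[max(fidx[fidx < i])] else -Inf
      hi <- if (any(fidx > j)) tau[min(fidx[fidx > j])] else Inf
      runs[[length(runs) + 1L]] <- list(idx = i:j, lo = lo, hi = hi)
      i <- j + 1L
    } else i <- i + 1L
  }
  n_free <- sum(lengths(lapply(runs, `[[`, "idx")))
  encode <- function(tau) {
    z <- numeric(0)
    for (r in runs) {
      v <- tau[r$idx]
      if (!is.finite(r$lo) && !is.finite(r$hi)) {
        z <- c(z, v[1L], log(diff(v)))
      } else if (is.finite(r$lo) && !is.finite(r$hi)) {
        z <- c(z, log(diff(c(r$lo, v))))
      } else if (!is.finite(r$lo) && is.finite(r$hi)) {
        z <- c(z, log(diff(c(v, r$hi))))
      } else {
        p <- (v - r$lo) / (r$hi - r$lo)
        q <- diff(c(0, p, 1))
        z <- c(z, log(q[-length(q)]) - log(q[length(q)]))
      }
    }
    z
  }
  decode <- function(z) {
    out <- tau
    pos <- 0L
    for (r in runs) {
      m <- length(r$idx)
      zi <- z[pos + seq_len(m)]
      pos <- pos + m
      v <- if (!is.finite(r$lo) && !is.finite(r$hi)) {
        cumsum(c(zi[1L], exp(zi[-1L])))
      } else if (is.finite(r$lo) && !is.finite(r$hi)) {
        r$lo + cumsum(exp(zi))
      } else if (!is.finite(r$lo) && is.finite(r$hi)) {
        r$hi - rev(cumsum(rev(exp(zi))))
      } else {
        w <- exp(zi)
        r$lo + (r$hi - r$lo) * cumsum(w) / (sum(w) + 1)
      }
      out[r$idx] <- v
    }
    out
  }
  list(encode = encode, decode = decode, n_free = n_free)
}

# Project naive threshold starting values into the ordering constraints
# implied by fixed thresholds.
sanitize_tau_start <- function(tau, fixed) {
  gap <- 0.05
  K1 <- length(tau)
  fidx <- which(fixed)
  for (k in seq_len(K1)) {
    if (fixed[k]) next
    lo <- if (any(fidx < k)) tau[max(fidx[fidx < k])] else -Inf
    hi <- if (any(fidx > k)) tau[min(fidx[fidx > k])] else Inf
    prev <- if (k > 1L) tau[k - 1L] else -Inf
    lo <- max(lo, prev)
    v <- tau[k]
    if (!is.finite(v)) v <- if (is.finite(lo)) lo + gap else 0
    if (is.finite(lo) && v <= lo + gap / 2) v <- lo + gap
    if (is.finite(hi) && v >= hi - gap / 2) {
      v <- if (is.finite(lo)) (max(lo, hi - 10 * gap) + hi) / 2 else hi - gap
    }
    tau[k] <- v
  }
  tau
}

# ---- EM fit ----------------------------------------------------------------

#' Fit a graded response model by marginal maximum likelihood
#'
#' EM estimation with a standard-normal latent prior and fixed
#' quadrature.  The E-step computes each assessment's posterior over the
#' quadrature nodes; the M-step maximizes each item's expected complete
#' -data log-likelihood with a quasi-Newton search on an unconstrained
#' reparameterization that keeps thresholds strictly ordered, including
#' around fixed thresholds.  Because each M-step starts from the current
#' parameter values, the marginal log-likelihood never decreases.
#' Binary items make the model a two-parameter logistic model.
#'
#' Per-parameter constraints are supplied as an [item_params()] object
#' covering any subset of the items, with `fixed_lambda`/`fixed_tau`
#' flags; fixed values are returned unchanged (bit-identical).  Items
#' whose observed responses all fall in a single category are flagged as
#' degenerate and excluded from the likelihood; boundary categories never
#' observed get infinite sentinel thresholds and are excluded from
#' estimation.
#'
#' @param table A [response_table()] (binary or polytomous).
#' @param spec The matching [instrument_spec()].
#' @param constraints Optional [item_params()] carrying fixed parameter
#'   values and flags (and starting values for free parameters).
#' @param quadrature A [grm_quadrature()].
#' @param tol Convergence tolerance on the largest absolute parameter
#'   change between EM iterations.
#' @param max_iter Maximum EM iterations; non-convergence is flagged on
#'   the result, not raised.
#' @param items Optional subset of item ids to fit (defaults to all items
#'   in `spec`).
#' @return An object of class `grm_calibration`: a list with `params`
#'   ([item_params()]), `loglik`, `n_iter`, `converged`, `quadrature`,
#'   `trace` (per-iteration log-likelihood), and `degenerate` (ids of
#'   excluded items).
#' @examples
#' spec <- instrument_spec("toy", data.frame(
#'   id = c("a", "b"), domain = c("da", "db"),
#'   n_categories = c(3L, 2L), cut = 1L))
#' truth <- item_params(c("a", "b"), c(1.5, 1.0), list(c(-0.5, 1), 0.2))
#' theta <- data.frame(person_id = 1:300, day = 1, theta = rnorm(300))
#' tab <- simulate_responses(theta, truth, spec, seed = 1)
#' fit <- fit_grm(tab, spec)
#' fit$params
#' @export
fit_grm <- function(table, spec, constraints = NULL,
                    quadrature = grm_quadrature(), tol = 1e-4,
                    max_iter = 500L, items = NULL) {
  stopifnot(inherits(spec, "instrument_spec"))
  ids <- if (is.null(items)) spec$items$id else items
  Kvec <- spec$items$n_categories[match(ids, spec$items$id)]
  if (anyNA(Kvec)) stop("items not in spec: ",
                        paste(ids[is.na(Kvec)], collapse = ", "))
  Y <- response_matrix(table, ids)
  J <- length(ids)
  n <- nrow(Y)
  if (J < 2L && is.null(constraints))
    stop("need at least 2 items (or constraints) to identify the model")

  # initialize parameters: constraints override, marginal-proportion
  # starts elsewhere
  lambda <- rep(1, J)
  fixed_lambda <- rep(FALSE, J)
  tau <- vector("list", J)
  fixed_tau <- vector("list", J)
  degenerate <- character(0)
  for (i in seq_len(J)) {
    K <- Kvec[i]
    y <- Y[, i]
    obs <- y[!is.na(y)]
    ks <- seq_len(K - 1L)
    pge <- vapply(ks, function(k) mean(obs >= k), 0)
    t0 <- qlogis(pmin(pmax(1 - pge, 0.002), 0.998))
    t0 <- pmin(pmax(t0, -4), 4)
    for (k in seq_along(t0)[-1L])
      if (t0[k] <= t0[k - 1L]) t0[k] <- t0[k - 1L] + 0.1
    fl <- FALSE
    ft <- rep(FALSE, K - 1L)
    if (!is.null(constraints) && ids[i] %in% constraints$id) {
      ci <- match(ids[i], constraints$id)
      fl <- constraints$fixed_lambda[ci]
      if (fl) lambda[i] <- constraints$lambda[ci]
      ctau <- constraints$tau[[ci]]
      cft <- constraints$fixed_tau[[ci]]
      if (length(ctau) != K - 1L)
        stop("constraints for item '", ids[i], "': expected ",
             K - 1L, " thresholds, got ", length(ctau))
      ft <- cft
      t0[ft] <- ctau[ft]
    }
    # boundary categories never observed: pin sentinel thresholds
    if (length(obs)) {
      lo <- min(obs); hi <- max(obs)
      if (lo == hi && !(fl && all(ft))) {
        degenerate <- c(degenerate, ids[i])
        lambda[i] <- NA_real_
        tau[[i]] <- t0; fixed_tau[[i]] <- ft; fixed_lambda[i] <- fl
        next
      }
      if (lo > 0L) { sk <- ks[ks <= lo] ; sk <- sk[!ft[sk]]
                     t0[sk] <- -Inf; ft[sk] <- TRUE }
      if (hi < K - 1L) { sk <- ks[ks > hi]; sk <- sk[!ft[sk]]
                         t0[sk] <- Inf; ft[sk] <- TRUE }
    }
    tau[[i]] <- sanitize_tau_start(t0, ft)
    fixed_tau[[i]] <- ft
    fixed_lambda[i] <- fl
  }
  if (length(degenerate))
    warning("item(s) with all observed responses in one category ",
            "excluded from the fit: ", paste(degenerate, collapse = ", "))

  params <- item_params(ids, lambda, tau, fixed_lambda, fixed_tau)
  nodes <- quadrature$nodes
  free_item <- vapply(seq_len(J), function(i) {
    !is.na(params$lambda[i]) &&
      (!params$fixed_lambda[i] || !all(params$fixed_tau[[i]]))
  }, TRUE)

  codecs <- lapply(seq_len(J), function(i) {
    if (!free_item[i]) return(NULL)
    tau_codec(params$tau[[i]], params$fixed_tau[[i]])
  })

  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    A <- node_loglik(Y, params, nodes)
    ep <- posterior_pieces(A, quadrature$weights)
    trace <- c(trace, ep$loglik)
    if (!any(free_item)) { converged <- TRUE; break }
    delta <- 0
    for (i in which(free_item)) {
      K <- Kvec[i]
      yi <- Y[, i]
      obs <- which(!is.na(yi))
      Ymat <- matrix(0, n, K)
      Ymat[cbind(obs, yi[obs] + 1L)] <- 1
      r <- ep$post %*% Ymat                       # Q x K expected counts
      cd <- codecs[[i]]
      lam_free <- !params$fixed_lambda[i]
      par0 <- c(if (lam_free) params$lambda[i], cd$encode(params$tau[[i]]))
      nll <- function(p) {
        lam <- if (lam_free) p[1L] else params$lambda[i]
        tv <- cd$decode(if (lam_free) p[-1L] else p)
        P <- grm_cat_probs(lam, tv, nodes)
        -sum(r * log(pmax(P, 1e-300)))
      }
      opt <- if (length(par0) == 1L) {
        optim(par0, nll, method = "Brent",
              lower = par0 - 15, upper = par0 + 15)
      } else {
        optim(par0, nll, method = "BFGS",
              control = list(maxit = 200, reltol = 1e-12))
      }
      lam_new <- if (lam_free) opt$par[1L] else params$lambda[i]
      tau_new <- cd$decode(if (lam_free) opt$par[-1L] else opt$par)
      delta <- max(delta, abs(lam_new - params$lambda[i]),
                   abs(tau_new - params$tau[[i]])[is.finite(tau_new)],
                   na.rm = TRUE)
      params$lambda[i] <- lam_new
      params$tau[[i]] <- tau_new
    }
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  # final log-likelihood at the converged parameters
  A <- node_loglik(Y, params, nodes)
  loglik <- posterior_pieces(A, quadrature$weights)$loglik
  trace <- c(trace, loglik)
  structure(list(params = params, loglik = loglik, n_iter = iter,
                 converged = converged, quadrature = quadrature,
                 trace = trace, degenerate = degenerate,
                 instrument = spec$name),
            class = "grm_calibration")
}

#' @export
print.grm_calibration <- function(x, ...) {
  cat("<grm_calibration> ", x$instrument, ": ", length(x$params),
      " items, loglik ", format(x$loglik, digits = 8), ", ",
      x$n_iter, " EM iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}
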