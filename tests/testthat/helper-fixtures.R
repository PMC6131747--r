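# Brute-force oracle: marginal log-likelihood and EAP scores by dense-grid
# numerical integration, independent of the EM engine's quadrature code path.
dense_oracle <- function(table, params, grid_n = 2001, range = c(-6, 6)) {
  th <- seq(range[1], range[2], length.out = grid_n)
  w <- dnorm(th)
  w <- w / sum(w)
  Y <- as.matrix(as.data.frame(table)[, params$id, drop = FALSE])
  ll <- 0
  eap <- esd <- numeric(nrow(Y))
  for (j in seq_len(nrow(Y))) {
    L <- rep(1, grid_n)
    for (i in seq_along(params$id)) {
      y <- Y[j, i]
      if (is.na(y)) next
      lam <- params$lambda[i]
      tau <- params$tau[[i]]
      cp <- cbind(1, vapply(tau, function(t) plogis(lam * th - t),
                            numeric(grid_n)), 0)
      L <- L * (cp[, y + 1L] - cp[, y + 2L])
    }
    m <- sum(w * L)
    ll <- ll + log(m)
    eap[j] <- sum(w * L * th) / m
    esd[j] <- sqrt(sum(w * L * th^2) / m - eap[j]^2)
  }
  list(loglik = ll, eap = eap, esd = esd)
}

toy_spec <- function() {
  instrument_spec("toy", data.frame(
    id = c("a", "b", "c"), domain = c("d1", "d2", "d3"),
    shared = NA_character_, n_categories = c(4L, 3L, 2L), cut = 1L))
}

toy_params <- function() {
  item_params(c("a", "b", "c"), c(1.5, 2.0, 0.8),
              list(c(-1, 0.5, 2), c(0, 1.5), 0.3))
}

# independent theta draws (no person clustering) for single-instrument fits
flat_theta <- function(n, shift = 0) {
  data.frame(person_id = seq_len(n), day = 1L, theta = rnorm(n) + shift)
}

# The default synthetic study and its fitted harmonized model are shared
# across test files (computed once; deterministic at the fixture seed).
.fixtures <- new.env(parent = emptyenv())
default_pipeline <- function() {
  if (is.null(.fixtures$model)) {
    .fixtures$study <- simulate_study(generator_config(seed = 42))
    .fixtures$model <- run_pipeline(.fixtures$study$data,
                                    bundled_instruments())
  }
  list(study = .fixtures$study, model = .fixtures$model)
}
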