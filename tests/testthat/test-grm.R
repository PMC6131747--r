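test_that("marginal likelihood and EAP match dense-grid integration", {
  set.seed(17)
  p <- toy_params()
  spec <- toy_spec()
  tab <- simulate_responses(flat_theta(40), p, spec, missing_rate = 0.15)
  o <- dense_oracle(tab, p)
  expect_lt(abs(grm_loglik(tab, p) - o$loglik), 1e-6)
  e <- eap_scores(tab, p)
  expect_lt(max(abs(e$theta - o$eap)), 1e-4)
  expect_lt(max(abs(e$se - o$esd)), 1e-4)
  # theta-independent single item: loglik has the closed form n*log(1/2)
  p0 <- item_params("a", 0, list(0))
  t0 <- data.frame(person_id = 1:10, day = 1L, a = rep(c(0L, 1L), 5))
  expect_equal(grm_loglik(t0, p0), 10 * log(0.5), tolerance = 1e-12)
  # an all-missing assessment contributes nothing
  tab_aug <- as.data.frame(tab)
  tab_aug <- rbind(tab_aug, data.frame(person_id = "x", day = 1L,
                                       a = NA_integer_, b = NA_integer_,
                                       c = NA_integer_))
  expect_equal(grm_loglik(tab_aug, p), grm_loglik(tab, p), tolerance = 1e-12)
  e2 <- eap_scores(tab_aug, p)
  expect_equal(unlist(e2[nrow(e2), c("theta", "se")], use.names = FALSE),
               c(0, 1))
  # monotonicity: an all-top-category assessment scores above the mean
  top <- data.frame(person_id = 1L, day = 1L, a = 3L, b = 2L, c = 1L)
  expect_gt(eap_scores(top, p)$theta, 0)
})

test_that("category curves have the closed logistic form and limits", {
  m <- icc(item_params("x", 1, list(0)), 0, item = "x")
  expect_equal(as.numeric(m), c(0.5, 0.5))
  m2 <- icc(item_params("x", 2, list(c(-1, 1))), 0, item = "x")
  expect_equal(as.numeric(m2), c(1 - plogis(1), plogis(1) - plogis(-1),
                                 plogis(-1)), tolerance = 1e-12)
  grid <- seq(-4, 4, by = 0.5)
  probs <- icc(toy_params(), grid)
  for (P in probs) expect_equal(rowSums(P), rep(1, length(grid)))
  lo <- icc(toy_params(), -60, item = "a")
  expect_equal(as.numeric(lo), c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("EM increases the likelihood and recovers generating parameters", {
  set.seed(31)
  lam_true <- c(1.5, 1.0, 2.0, 0.8)
  tau_true <- list(c(-1, 0, 2), c(0.5, 1.5), c(-0.5, 1), 0)
  truth <- item_params(paste0("i", 1:4), lam_true, tau_true)
  spec <- instrument_spec("sim", data.frame(
    id = truth$id, domain = truth$id, shared = NA_character_,
    n_categories = vapply(tau_true, length, 1L) + 1L, cut = 1L))
  tab <- simulate_responses(flat_theta(2000), truth, spec)
  fit <- fit_grm(tab, spec)
  expect_true(fit$converged)
  # monotone EM: no decrease beyond numerical tolerance
  expect_gt(min(diff(fit$trace)), -1e-8)
  # recovery: errors bounded well below parameter scale at n = 2000
  expect_lt(mean(abs(fit$params$lambda - lam_true)), 0.15)
  expect_lt(mean(abs(unlist(fit$params$tau) - unlist(tau_true))), 0.15)
  # loglik at the estimate beats the truth's (MLE property, same quadrature)
  expect_gte(fit$loglik, grm_loglik(tab, truth) - 1e-6)
})

test_that("constraints are honored bit-identically", {
  set.seed(32)
  truth <- toy_params()
  spec <- toy_spec()
  tab <- simulate_responses(flat_theta(600), truth, spec)
  # fully fixed: nothing moves, loglik equals the standalone computation
  cons <- truth
  cons$fixed_lambda[] <- TRUE
  cons$fixed_tau <- lapply(cons$tau, function(t) rep(TRUE, length(t)))
  ff <- fit_grm(tab, spec, constraints = cons)
  expect_identical(ff$params$lambda, truth$lambda)
  expect_identical(ff$params$tau, truth$tau)
  expect_equal(ff$loglik, grm_loglik(tab, truth), tolerance = 1e-12)
  # slope and first threshold fixed, remaining thresholds free and ordered
  cons2 <- truth
  cons2$fixed_lambda[] <- TRUE
  cons2$fixed_tau <- lapply(cons2$tau, function(t)
    c(TRUE, rep(FALSE, length(t) - 1L)))
  pf <- fit_grm(tab, spec, constraints = cons2)
  for (i in 1:3) {
    expect_identical(pf$params$lambda[i], truth$lambda[i])
    expect_identical(pf$params$tau[[i]][1], truth$tau[[i]][1])
    tt <- pf$params$tau[[i]]
    expect_false(is.unsorted(tt[is.finite(tt)], strictly = TRUE))
  }
  # a middle fixed threshold with free neighbours stays put and ordered
  cons3 <- truth["a"]
  cons3$fixed_lambda[] <- TRUE
  cons3$fixed_tau <- list(c(FALSE, TRUE, FALSE))
  pf3 <- fit_grm(tab, spec, constraints = cons3)
  expect_identical(pf3$params$tau[[1]][2], truth$tau[[1]][2])
  expect_false(is.unsorted(pf3$params$tau[[1]], strictly = TRUE))
})

test_that("degenerate items are flagged and excluded from scoring", {
  spec <- toy_spec()
  tab <- data.frame(person_id = 1:30, day = 1L,
                    a = rep(0L, 30),                     # constant item
                    b = rep(c(0L, 1L, 2L), 10),
                    c = rep(c(0L, 1L), 15))
  expect_warning(fit <- fit_grm(response_table(tab, spec), spec),
                 "one category")
  expect_equal(fit$degenerate, "a")
  expect_true(is.na(fit$params$lambda[1]))
  # scoring still works, ignoring the degenerate item
  e <- eap_scores(response_table(tab, spec), fit$params)
  expect_true(all(is.finite(e$theta)))
})

test_that("quadrature refinement leaves the likelihood unchanged", {
  set.seed(33)
  truth <- toy_params()
  spec <- toy_spec()
  tab <- simulate_responses(flat_theta(300), truth, spec)
  l49 <- grm_loglik(tab, truth, grm_quadrature(49))
  l101 <- grm_loglik(tab, truth, grm_quadrature(101))
  expect_lt(abs(l49 - l101), 1e-6)
})

test_that("information follows the GRM formula and is additive", {
  # binary item at its location: lambda^2 / 4
  expect_equal(as.numeric(item_information(item_params("x", 1.7, list(0.85)),
                                           0.5)), 1.7^2 / 4)
  # additivity
  p <- toy_params()
  grid <- c(-2, 0, 1, 3)
  expect_equal(test_information(p, grid),
               rowSums(item_information(p, grid)))
  # matches the curvature of the expected log-likelihood
  p1 <- item_params("x", 1.8, list(c(-0.5, 0.7, 2.1)))
  for (t0 in c(-2, 0, 1, 2.5)) {
    h <- 1e-4
    el <- function(t) {
      P0 <- icc(p1, t0, item = "x")
      sum(P0 * log(icc(p1, t, item = "x")))
    }
    numeric_info <- -(el(t0 + h) - 2 * el(t0) + el(t0 - h)) / h^2
    expect_equal(as.numeric(item_information(p1, t0)), numeric_info,
                 tolerance = 1e-4)
  }
  # reliability vanishes in the tails of a finite test
  expect_lt(reliability(p, 25), 1e-6)
})

test_that("slope/location conversion round-trips", {
  p <- item_params(c("u", "v"), c(2, 1.3), list(c(1, 3), c(-0.5, 0.2, 1)))
  d <- fa_to_irt(p)
  expect_equal(d$b[d$item == "u"], c(0.5, 1.5))
  back <- irt_to_fa(d)
  expect_equal(back$lambda, p$lambda, tolerance = 1e-12)
  expect_equal(back$tau, p$tau, tolerance = 1e-12)
  expect_error(fa_to_irt(item_params("w", 0, list(1))), "non-positive slope")
})
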