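test_that("test characteristic curves are monotone with correct limits", {
  p <- toy_params()
  expect_lt(tcc(p, -30), 1e-8)
  expect_gt(tcc(p, 30), 6 - 1e-8)            # max score 3 + 2 + 1
  expect_equal(tcc(item_params("x", 1, list(0)), 0), 0.5)
  grid <- seq(-6, 6, by = 0.05)
  expect_false(is.unsorted(tcc(p, grid)))
  # matches Monte-Carlo mean sum scores at fixed severities
  spec <- toy_spec()
  set.seed(61)
  for (th0 in c(-2, -0.5, 0.5, 1.5, 3)) {
    thd <- data.frame(person_id = 1:4000, day = 1L, theta = th0)
    tt <- simulate_responses(thd, p, spec)
    sc <- sum_score(tt, spec)$score
    se <- sd(sc) / sqrt(length(sc))
    expect_lt(abs(mean(sc) - tcc(p, th0)), 3 * se + 1e-9)
  }
})

test_that("TCC inversion round-trips and truncates at the boundaries", {
  p <- toy_params()
  th <- invert_tcc(p, tcc(p, 1.7))
  expect_lt(abs(th - 1.7), 1e-5)
  expect_false(attr(th, "truncated"))
  z <- invert_tcc(p, 0)
  expect_equal(as.numeric(z), -6)
  expect_true(attr(z, "truncated"))
  expect_error(invert_tcc(p, 7), "outside")
  expect_error(invert_tcc(p, -1), "outside")
})

test_that("crosswalks are self-consistent and monotone", {
  m <- default_pipeline()$model
  # self-crosswalk returns the identity away from the truncated boundary
  cw_self <- crosswalk(m, "MDAS", targets = "MDAS")
  free <- !cw_self$truncated
  expect_true(all(cw_self$MDAS[free] == cw_self$source_score[free]))
  # cross-instrument tables: theta and every target column non-decreasing
  for (src in c("CAM-S-LF", "DRS-R-98")) {
    cw <- crosswalk(m, src)
    expect_false(is.unsorted(cw$theta))
    for (tn in setdiff(names(m$params), src)) {
      expect_false(is.unsorted(cw[[paste0(tn, "_raw")]]))
      expect_false(is.unsorted(cw[[tn]]))
      expect_true(all(cw[[tn]] >= 0 & cw[[tn]] <= m$specs[[tn]]$max_score))
    }
  }
})

test_that("reliability report and item-person map expose the study structure", {
  m <- default_pipeline()$model
  rep <- reliability_report(m)
  # a test containing more items dominates a subset of itself pointwise
  grid <- seq(-3, 6, by = 0.5)
  expect_true(all(test_information(m$params[["CAM-S-LF"]], grid) >=
                    test_information(m$params[["CAM-S-SF"]], grid) - 1e-9))
  expect_true(all(rep$curves$reliability >= 0 & rep$curves$reliability < 1))
  ipm <- item_person_map(m)
  # flag arithmetic: b = tau / lambda against the 4-SD rule
  toy <- m
  toy$params <- list(one = item_params("z", 2, list(c(2, 8.2))))
  toy$scores <- list(one = data.frame(person_id = 1, day = 1,
                                      theta = 0, se = 1))
  toy_map <- item_person_map(toy)
  expect_equal(toy_map$locations$b, c(1, 4.1))
  expect_equal(toy_map$locations$flagged, c(FALSE, TRUE))
  # flags recompute identically from the serialized model
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  m2 <- read_model_json(f)
  ipm2 <- item_person_map(m2)
  expect_identical(ipm$locations[c("instrument", "item", "k", "flagged")],
                   ipm2$locations[c("instrument", "item", "k", "flagged")])
})

test_that("score correlations behave as designed under shared and independent traits", {
  m <- default_pipeline()$model
  cc <- score_correlations(m)
  expect_equal(diag(cc), setNames(rep(1, 4), names(m$params)))
  expect_true(isSymmetric(cc))
  # negative control: responses driven by independent severities decorrelate
  set.seed(62)
  specs <- bundled_instruments(c("DRS-R-98", "MDAS", "CAM-S-LF"))
  tp <- default_true_params(specs)
  m0 <- m
  m0$scores <- lapply(names(specs), function(nm) {
    th <- flat_theta(400)                     # fresh independent draw each
    tab <- simulate_responses(th, tp[[nm]], specs[[nm]])
    eap_scores(tab, m$params[[nm]], m$quadrature)
  })
  names(m0$scores) <- names(specs)
  cc0 <- score_correlations(m0)
  expect_true(all(abs(cc0[upper.tri(cc0)]) < 0.2))
  # too few common assessments is an error
  mshort <- m
  mshort$scores <- lapply(m$scores, function(s) s[1:2, ])
  expect_error(score_correlations(mshort), "fewer than 3")
})

test_that("residual diagnostics separate one-factor fit from misfit", {
  set.seed(63)
  spec <- bundled_instruments("MDAS")[[1]]
  tp <- default_true_params(bundled_instruments("MDAS"))[[1]]
  tab <- simulate_responses(flat_theta(3000), tp, spec)
  fit_ok <- suppressWarnings(residual_diagnostics(tab, tp))
  expect_lt(fit_ok$rmsr, 0.05)
  expect_true(all(abs(fit_ok$pairs$implied) <= 1))
  # two independent factors forced into one: residuals inflate
  tab2 <- simulate_responses(flat_theta(3000), tp, spec)
  mixed <- as.data.frame(tab)
  second <- spec$items$id[6:10]
  mixed[second] <- as.data.frame(tab2)[second]
  mixed <- response_table(mixed, spec)
  fit_bad <- fit_grm(mixed, spec)
  rd_bad <- suppressWarnings(residual_diagnostics(mixed, fit_bad$params))
  expect_gt(rd_bad$rmsr, 2 * fit_ok$rmsr)
  # zero-slope items imply zero latent-response correlation
  p0 <- item_params(c("u", "v"), c(0, 1.5), list(0.2, 0.5))
  t0 <- data.frame(person_id = 1:400, day = 1L,
                   u = rbinom(400, 1, 0.5), v = rbinom(400, 1, 0.4))
  rd0 <- residual_diagnostics(t0, p0, min_pairs = 10L)
  expect_equal(rd0$pairs$implied, 0)
})
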