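#' Default generating item parameters for the bundled instruments
#'
#' One parameter set per shared symptom domain, shared across
#' instruments so that anchor items truly measure the same thing in the
#' generated data; instrument-specific items get their own values.
#' Slopes range over roughly 1.2-2.2.  Threshold placement reproduces
#' the qualitative structure of hospital delirium assessments: cognitive
#' items (attention, orientation, memory) have the lowest first
#' thresholds, psychotic and behavioral symptoms (delusions, perceptual
#' disturbance, psychomotor disturbance) have first thresholds 2+ SD
#' above the latent mean, and several domains place their most severe
#' category beyond 4 SD (`b = tau / lambda > 4`), so top categories are
#' rare even in severe delirium and expected sum scores sit near the
#' low levels typical of hospital cohorts.  Mild sleep disturbance is
#' common (first threshold below 0), which is why the sleep item
#' dichotomizes at its second threshold.
#'
#' Three-category ("absent/mild/marked") items take the first and third
#' threshold values of their domain, except cut-2 items which keep the
#' first two so anchor cut thresholds agree across instruments; binary
#' items take the first.
#'
#' @param specs Named list of [instrument_spec()] objects.
#' @return Named list of [item_params()] objects, one per instrument.
#' @export
default_true_params <- function(specs = bundled_instruments(c("DRS-R-98", "MDAS", "CAM-S-LF"))) {
  base <- list(
    attention              = list(lambda = 2.0, tau = c(1.0, 2.4, 3.8)),
    orientation            = list(lambda = 2.2, tau = c(1.2, 2.6, 4.0)),
    memory                 = list(lambda = 1.8, tau = c(0.8, 2.2, 3.6)),
    disorganized_thinking  = list(lambda = 2.0, tau = c(1.8, 3.2, 4.6)),
    perceptual_disturbance = list(lambda = 1.6, tau = c(2.7, 3.9, 6.6)),
    delusions              = list(lambda = 1.5, tau = c(2.9, 4.1, 6.3)),
    sleep_wake             = list(lambda = 1.2, tau = c(-0.3, 2.2, 5.0)),
    psychomotor_agitation  = list(lambda = 1.3, tau = c(2.2, 3.5, 5.6)),
    psychomotor_retardation = list(lambda = 1.3, tau = c(1.9, 3.2, 4.5)),
    psychomotor_activity   = list(lambda = 1.3, tau = c(2.0, 3.3, 4.7)),
    consciousness          = list(lambda = 1.7, tau = c(2.8, 4.0, 5.2)),
    lability_of_affect     = list(lambda = 1.2, tau = c(2.5, 3.7, 5.3)),
    language               = list(lambda = 1.6, tau = c(2.0, 3.3, 6.6)),
    long_term_memory       = list(lambda = 1.5, tau = c(1.6, 3.1, 4.4)),
    visuospatial           = list(lambda = 1.6, tau = c(1.5, 3.0, 6.5)),
    digit_span             = list(lambda = 1.7, tau = c(1.4, 3.2, 7.0)),
    acute_onset            = list(lambda = 1.0, tau = c(2.5))
  )
  out <- lapply(specs, function(spec) {
    lam <- numeric(nrow(spec$items))
    tau <- vector("list", nrow(spec$items))
    for (j in seq_len(nrow(spec$items))) {
      d <- spec$items$domain[j]
      if (is.null(base[[d]]))
        stop("no default generating parameters for domain '", d, "'")
      K <- spec$items$n_categories[j]
      lam[j] <- base[[d]]$lambda
      # Three-category ("absent / mild / marked") items take the first
      # and third base thresholds: a "marked" rating corresponds to a
      # moderate-to-severe symptom, not merely a moderate one.  Cut-2
      # items (sleep) instead keep the first two, so the
      # dichotomization-cut threshold of every anchor item is identical
      # across instruments (cut-1 items share tau_1, the sleep item
      # shares tau_2).
      tau[[j]] <- if (K == 3L && length(base[[d]]$tau) == 3L &&
                      spec$items$cut[j] == 1L) {
        base[[d]]$tau[c(1L, 3L)]
      } else {
        base[[d]]$tau[seq_len(K - 1L)]
      }
    }
    item_params(spec$items$id, lam, tau)
  })
  names(out) <- names(specs)
  out
}

#' Configuration for the synthetic study generator
#'
#' The defaults emulate a hospital cohort contributing clustered daily
#' delirium assessments: 352 persons each rated on 1-15 hospital days,
#' with lengths of stay drawn from a geometric distribution truncated at
#' 15 days whose mean (about 3.3 rated days) yields roughly 1178
#' assessments in expectation.  The latent severity of person `p` on day
#' `d` is `theta = u_p + e_pd` with `u_p ~ N(0, icc)` and
#' `e_pd ~ N(0, 1 - icc)`, so the marginal latent variance is exactly 1
#' (matching the identification of the calibration models) and the
#' within-person correlation equals `icc`.  Missing ratings are MCAR.
#'
#' @param n_persons Number of persons.
#' @param max_days Maximum rated days per person.
#' @param stay_p Success probability of the truncated-geometric
#'   length-of-stay distribution (larger = shorter stays).
#' @param icc Within-person correlation of latent severity, in `[0, 1]`.
#' @param missing_rate Probability that an individual rating is missing,
#'   in `[0, 0.5]`.
#' @param true_params Named list of generating [item_params()] per
#'   instrument; defaults to [default_true_params()] for `specs`.
#' @param specs Named list of [instrument_spec()] objects.
#' @param seed Integer seed; every simulation from this config is
#'   deterministic given it.
#' @param ar1 Optional AR(1) autocorrelation for the daily deviations
#'   (`NULL` for the default exchangeable structure).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_persons = 352L, max_days = 15L,
                             stay_p = 0.3, icc = 0.5,
                             missing_rate = 0.02,
                             specs = bundled_instruments(c("DRS-R-98", "MDAS", "CAM-S-LF")),
                             true_params = default_true_params(specs),
                             seed = 1L, ar1 = NULL) {
  stopifnot(n_persons >= 1L, max_days >= 1L, stay_p > 0, stay_p < 1,
            icc >= 0, icc <= 1, missing_rate >= 0, missing_rate <= 0.5,
            all(names(true_params) == names(specs)))
  structure(list(n_persons = as.integer(n_persons),
                 max_days = as.integer(max_days), stay_p = stay_p,
                 icc = icc, missing_rate = missing_rate,
                 specs = specs, true_params = true_params,
                 seed = as.integer(seed), ar1 = ar1),
            class = "generator_config")
}

#' Simulate the latent severity of every assessment
#'
#' Draws each person's random intercept and daily deviations; the
#' marginal distribution of `theta` is standard normal and observations
#' within a person correlate at `icc` (exchangeable by default, AR(1)
#' when `config$ar1` is set).
#'
#' @param config A [generator_config()].
#' @return A data.frame `person_id`, `day`, `theta`, one row per
#'   assessment.
#' @export
simulate_theta <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  # truncated geometric length of stay on 1..max_days
  stay <- pmin(1L + stats::rgeom(config$n_persons, config$stay_p),
               config$max_days)
  person <- rep(seq_len(config$n_persons), stay)
  day <- unlist(lapply(stay, seq_len))
  u <- rnorm(config$n_persons, 0, sqrt(config$icc))
  sd_e <- sqrt(1 - config$icc)
  if (is.null(config$ar1)) {
    e <- rnorm(length(person), 0, sd_e)
  } else {
    rho <- config$ar1
    e <- unlist(lapply(stay, function(s) {
      z <- rnorm(s)
      out <- numeric(s)
      out[1L] <- z[1L]
      for (t in seq_len(s)[-1L])
        out[t] <- rho * out[t - 1L] + sqrt(1 - rho^2) * z[t]
      out * sd_e
    }))
  }
  data.frame(person_id = sprintf("P%04d", person), day = day,
             theta = u[person] + e)
}

#' Simulate item responses given latent severities
#'
#' Draws each rating from the graded response model
#' `P(y >= k | theta) = plogis(lambda * theta - tau_k)` by locating a
#' uniform draw among the cumulative probabilities, then masks ratings
#' missing completely at random.
#'
#' @param theta A data.frame from [simulate_theta()] (columns
#'   `person_id`, `day`, `theta`).
#' @param params Generating [item_params()] for the instrument.
#' @param spec The [instrument_spec()].
#' @param missing_rate MCAR missingness probability per rating.
#' @param seed Optional seed (set when calling outside
#'   [simulate_study()]).
#' @return A [response_table()].
#' @export
simulate_responses <- function(theta, params, spec, missing_rate = 0,
                               seed = NULL) {
  stopifnot(inherits(params, "item_params"),
            inherits(spec, "instrument_spec"))
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_along(params$id))
    if (is.unsorted(params$tau[[i]], strictly = TRUE))
      stop("item '", params$id[i], "': thresholds must be strictly increasing")
  n <- nrow(theta)
  out <- data.frame(person_id = theta$person_id, day = theta$day)
  for (j in seq_len(nrow(spec$items))) {
    id <- spec$items$id[j]
    i <- match(id, params$id)
    cp <- grm_cum_probs(params$lambda[i], params$tau[[i]], theta$theta)
    u <- runif(n)
    # rating = number of cumulative curves the uniform falls below
    y <- rowSums(u < cp[, -1L, drop = FALSE])
    if (missing_rate > 0) y[runif(n) < missing_rate] <- NA_integer_
    out[[id]] <- as.integer(y)
  }
  response_table(out, spec)
}

#' Simulate a complete multi-instrument study
#'
#' Generates the common-person design the co-calibration pipeline
#' assumes: every instrument is rated on the identical person-days,
#' driven by the same latent severity draw, so the instruments'
#' sum scores correlate through the shared trait.  Returns the
#' generating truth alongside the data for recovery testing.
#'
#' @param config A [generator_config()].
#' @return A list of class `synthetic_study` with `data` (named list of
#'   [response_table()]), `theta` (assessment-level truth), `params`
#'   (generating parameters), `specs`, and `config`.
#' @export
simulate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  th <- simulate_theta(config)          # seeds the RNG stream
  data <- list()
  for (nm in names(config$specs)) {
    data[[nm]] <- simulate_responses(th, config$true_params[[nm]],
                                     config$specs[[nm]],
                                     missing_rate = config$missing_rate)
  }
  structure(list(data = data, theta = th, params = config$true_params,
                 specs = config$specs, config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> ", length(unique(x$theta$person_id)),
      " persons, ", nrow(x$theta), " assessments, ",
      length(x$data), " instruments\n", sep = "")
  invisible(x)
}

#' Write a synthetic study to CSV files plus a JSON truth file
#'
#' One CSV per instrument (wide response tables) and `truth.json`
#' holding the latent severities and generating parameters; reruns from
#' the same config are byte-identical.
#'
#' @param study A `synthetic_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(study$data)) {
    fn <- file.path(dir, paste0(gsub("[^A-Za-z0-9]+", "_", nm), ".csv"))
    utils::write.csv(as.data.frame(study$data[[nm]]), fn,
                     row.names = FALSE, na = "")
  }
  truth <- list(
    theta = study$theta,
    params = lapply(study$params, function(p)
      lapply(seq_along(p$id), function(i)
        list(item_id = p$id[i], lambda = p$lambda[i], tau = p$tau[[i]])))
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}
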