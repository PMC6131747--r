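#' Test characteristic curve
#'
#' The expected instrument sum score at each latent level:
#' `E[X | theta] = sum_i sum_k k * P_ik(theta)`.  Monotone increasing in
#' `theta`, approaching 0 and the instrument maximum in the limits
#' (items with infinite sentinel thresholds for unobserved top
#' categories cap the attainable expectation below the theoretical
#' maximum).
#'
#' @param params Polytomous [item_params()] on a common metric.
#' @param theta Numeric vector of latent trait values.
#' @return Numeric vector of expected sum scores.
#' @export
tcc <- function(params, theta) {
  stopifnot(inherits(params, "item_params"))
  out <- numeric(length(theta))
  for (i in seq_along(params$id)) {
    if (is.na(params$lambda[i])) next
    cp <- grm_cum_probs(params$lambda[i], params$tau[[i]], theta)
    # sum_k k * (P*_k - P*_{k+1}) telescopes to sum_k P*_k, k >= 1
    out <- out + rowSums(cp[, -c(1L, ncol(cp)), drop = FALSE])
  }
  out
}

#' Invert the test characteristic curve
#'
#' Finds the latent level whose expected sum score equals `score`, by
#' bisection to `tol`.  Scores at or beyond the curve's value at
#' `-theta_max`/`theta_max` are truncated to those bounds and flagged.
#'
#' @param params Polytomous [item_params()].
#' @param score Target sum score(s), within `[0, max attainable]`.
#' @param theta_max Search bound on the latent metric.
#' @param tol Bisection tolerance.
#' @return Numeric vector of latent levels with attribute `truncated`
#'   (logical vector).
#' @export
invert_tcc <- function(params, score, theta_max = 6, tol = 1e-6) {
  max_score <- sum(vapply(params$tau, function(t) sum(is.finite(t)), 0))
  if (any(score < 0 | score > max_score))
    stop("score outside [0, ", max_score, "]")
  lo_val <- tcc(params, -theta_max)
  hi_val <- tcc(params, theta_max)
  th <- numeric(length(score))
  trunc <- logical(length(score))
  for (s in seq_along(score)) {
    if (score[s] <= lo_val) {
      th[s] <- -theta_max; trunc[s] <- TRUE
    } else if (score[s] >= hi_val) {
      th[s] <- theta_max; trunc[s] <- TRUE
    } else {
      th[s] <- uniroot(function(x) tcc(params, x) - score[s],
                       c(-theta_max, theta_max), tol = tol)$root
    }
  }
  attr(th, "truncated") <- trunc
  th
}

#' Sum-score crosswalk between instruments on a common metric
#'
#' For each integer score of the source instrument, finds the equated
#' latent intensity through the source's test characteristic curve and
#' reads off the expected score of every target instrument at that
#' intensity, both raw and rounded half-up.
#'
#' @param model A `harmonized_model` from [run_pipeline()].
#' @param source Source instrument name.
#' @param targets Target instrument names; defaults to all others in
#'   the model.
#' @param theta_max Truncation bound for the inverse curve.
#' @return A data.frame of class `crosswalk_table`: `source_score`,
#'   `theta`, `truncated`, then `<target>_raw` and `<target>` (rounded)
#'   columns.
#' @export
crosswalk <- function(model, source, targets = NULL, theta_max = 6) {
  stopifnot(inherits(model, "harmonized_model"),
            source %in% names(model$params))
  if (is.null(targets)) targets <- setdiff(names(model$params), source)
  scores <- 0:model$specs[[source]]$max_score
  sp <- model$params[[source]]
  attainable <- sum(vapply(sp$tau, function(t) sum(is.finite(t)), 0))
  scores <- scores[scores <= attainable]
  th <- invert_tcc(sp, scores, theta_max = theta_max)
  out <- data.frame(source_score = scores, theta = as.numeric(th),
                    truncated = attr(th, "truncated"))
  for (tn in targets) {
    raw <- tcc(model$params[[tn]], out$theta)
    out[[paste0(tn, "_raw")]] <- raw
    out[[tn]] <- pmin(round_half_up(raw), model$specs[[tn]]$max_score)
  }
  attr(out, "source") <- source
  class(out) <- c("crosswalk_table", "data.frame")
  out
}

#' Information and reliability curves per instrument
#'
#' Tabulates test information and reliability `I/(I+1)` on a latent
#' grid, and measures the width of the region where reliability reaches
#' at least 0.70 for each instrument.
#'
#' @param model A `harmonized_model`.
#' @param theta Grid of latent values (default `[-3, 6]` in steps of
#'   0.01, covering the range over which hospital samples spread).
#' @param rel_threshold Reliability level defining the measured width.
#' @return A list with `curves` (long data.frame: `instrument`, `theta`,
#'   `information`, `reliability`) and `rel_width` (named vector: the
#'   total grid length with reliability at or above `rel_threshold`).
#' @export
reliability_report <- function(model, theta = seq(-3, 6, by = 0.01),
                               rel_threshold = 0.70) {
  stopifnot(inherits(model, "harmonized_model"))
  step <- if (length(theta) > 1L) diff(theta[1:2]) else NA_real_
  curves <- do.call(rbind, lapply(names(model$params), function(nm) {
    I <- test_information(model$params[[nm]], theta)
    data.frame(instrument = nm, theta = theta, information = I,
               reliability = I / (I + 1), stringsAsFactors = FALSE)
  }))
  widths <- vapply(names(model$params), function(nm) {
    r <- curves$reliability[curves$instrument == nm]
    sum(r >= rel_threshold) * step
  }, 0)
  list(curves = curves, rel_width = widths)
}

#' Item-person map
#'
#' Locates every item category on the common metric (`b_k = tau_k /
#' lambda`, the latent level where rating at or above `k` reaches
#' probability one half) next to the distribution of estimated person
#' severities, and flags categories located more than `flag_sd` SD above
#' the latent mean — categories that even severely delirious patients
#' rarely reach.
#'
#' @param model A `harmonized_model`.
#' @param flag_sd Flagging threshold in latent SD units.
#' @return A list with `locations` (data.frame: `instrument`, `item`,
#'   `k`, `b`, `flagged`) and `scores` (data.frame: `instrument`,
#'   `theta` of each scored assessment).  Items with non-positive or
#'   degenerate slopes are excluded with a warning.
#' @export
item_person_map <- function(model, flag_sd = 4) {
  stopifnot(inherits(model, "harmonized_model"))
  locations <- do.call(rbind, lapply(names(model$params), function(nm) {
    p <- model$params[[nm]]
    drop <- is.na(p$lambda) | p$lambda <= 0
    if (any(drop)) {
      warning("instrument '", nm, "': excluding item(s) with ",
              "non-positive slope: ", paste(p$id[drop], collapse = ", "))
      p <- p[!drop]
    }
    d <- fa_to_irt(p)
    data.frame(instrument = nm, item = d$item, k = d$k, b = d$b,
               flagged = is.finite(d$b) & d$b > flag_sd,
               stringsAsFactors = FALSE)
  }))
  scores <- do.call(rbind, lapply(names(model$scores), function(nm)
    data.frame(instrument = nm, theta = model$scores[[nm]]$theta,
               stringsAsFactors = FALSE)))
  list(locations = locations[is.finite(locations$b), ], scores = scores)
}

#' Correlations of factor scores across instruments
#'
#' Pearson correlations of the per-assessment EAP severity scores over
#' assessments scored on both instruments of each pair.
#'
#' @param model A `harmonized_model`.
#' @return A symmetric correlation matrix.
#' @export
score_correlations <- function(model) {
  stopifnot(inherits(model, "harmonized_model"))
  nms <- names(model$scores)
  key <- function(s) paste(s$person_id, s$day, sep = "\r")
  keys <- Reduce(intersect, lapply(model$scores, key))
  if (length(keys) < 3L)
    stop("fewer than 3 assessments scored on all instruments")
  m <- vapply(nms, function(nm) {
    s <- model$scores[[nm]]
    s$theta[match(keys, key(s))]
  }, numeric(length(keys)))
  cor(m, use = "pairwise.complete.obs")
}
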