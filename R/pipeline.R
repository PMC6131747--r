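#' Step 1: calibrate the dichotomized shared items of each instrument
#'
#' Fits an independent two-parameter logistic model to each instrument,
#' restricted to its items whose coarse shared-domain label belongs to
#' the set common to all instruments, on dichotomized responses.  These
#' instrument-specific calibrations establish the measurement model that
#' the later steps constrain and link.
#'
#' @param data Named list of [response_table()] objects (polytomous),
#'   one per instrument.
#' @param specs Named list of matching [instrument_spec()] objects.
#' @param domains Optional shared-domain set; defaults to
#'   [shared_domains()] of `specs`.
#' @param quadrature,tol,max_iter Passed to [fit_grm()].
#' @return Named list of `grm_calibration` objects (binary parameters).
#' @export
step1_shared <- function(data, specs, domains = NULL,
                         quadrature = grm_quadrature(), tol = 1e-4,
                         max_iter = 500L) {
  stopifnot(all(names(data) %in% names(specs)))
  if (is.null(domains)) domains <- shared_domains(specs[names(data)])
  out <- lapply(names(data), function(nm) {
    spec <- specs[[nm]]
    ids <- spec$items$id[!is.na(spec$items$shared) &
                           spec$items$shared %in% domains]
    if (length(ids) < 2L)
      stop("instrument '", nm, "' has fewer than 2 shared items")
    fit_grm(dichotomize(data[[nm]], spec), dichotomize_spec(spec),
            quadrature = quadrature, tol = tol, max_iter = max_iter,
            items = ids)
  })
  names(out) <- names(data)
  out
}

#' Step 2: calibrate all dichotomized items with shared items fixed
#'
#' Refits each instrument on all of its dichotomized items, holding the
#' shared items' slope and threshold at their step-1 estimates so the
#' metric established by the shared items carries over; only the
#' non-shared items' parameters are estimated.
#'
#' @param data,specs,quadrature,tol,max_iter As in [step1_shared()].
#' @param step1 The result of [step1_shared()].
#' @return Named list of `grm_calibration` objects (binary parameters,
#'   all items).
#' @export
step2_all_items <- function(data, specs, step1,
                            quadrature = grm_quadrature(), tol = 1e-4,
                            max_iter = 500L) {
  out <- lapply(names(data), function(nm) {
    spec <- specs[[nm]]
    cons <- step1[[nm]]$params
    cons$fixed_lambda[] <- TRUE
    cons$fixed_tau <- lapply(cons$fixed_tau, function(f) rep(TRUE, length(f)))
    fit_grm(dichotomize(data[[nm]], spec), dichotomize_spec(spec),
            constraints = cons, quadrature = quadrature, tol = tol,
            max_iter = max_iter)
  })
  names(out) <- names(data)
  out
}

#' Step 3: Haebara-link each target instrument to the reference
#'
#' Estimates the affine metric transform mapping each non-reference
#' instrument onto the reference (DRS-R-98) metric from the anchor
#' pairs' step-2 binary parameters, and re-expresses all of the target's
#' item parameters on the reference metric.  The reference instrument
#' gets the identity transform.
#'
#' @param step2 The result of [step2_all_items()].
#' @param anchor_maps An `anchor_maps` object from [build_anchor_maps()].
#' @param quadrature Quadrature for the Haebara criterion.
#' @param symmetric Use the symmetrized Haebara criterion.
#' @return A list with `transforms` (named list of `linking_transform`)
#'   and `params` (named list of binary [item_params()] on the common
#'   metric).
#' @export
step3_link <- function(step2, anchor_maps,
                       quadrature = grm_quadrature(),
                       symmetric = FALSE) {
  reference <- attr(anchor_maps, "reference")
  stopifnot(reference %in% names(step2))
  transforms <- list()
  params <- list()
  transforms[[reference]] <- identity_transform()
  params[[reference]] <- step2[[reference]]$params
  for (nm in setdiff(names(step2), reference)) {
    map <- anchor_maps[[nm]]
    tr <- haebara_link(step2[[reference]]$params, step2[[nm]]$params,
                       anchor_map = map, quadrature = quadrature,
                       symmetric = symmetric,
                       direction = c(target = nm, reference = reference))
    transforms[[nm]] <- tr
    params[[nm]] <- transform_params(step2[[nm]]$params, tr)
  }
  list(transforms = transforms, params = params)
}

#' Step 4: polytomous recalibration on the common metric
#'
#' Fits the graded response model to each instrument's original
#' polytomous items, fixing every item's slope and one threshold at the
#' values linked in step 3, and freely estimating the remaining
#' thresholds.  The fixed threshold is, by default, the threshold at the
#' item's dichotomization cut: the binary parameter carried through
#' steps 1-3 is by construction the cut-point threshold, so for
#' sleep/wake items (cut 2) the fixed threshold is the second one.
#' `fix_first = TRUE` fixes the first threshold instead, regardless of
#' the cut.  Binary items have nothing left to estimate and pass
#' through.
#'
#' @param data,specs,quadrature,tol,max_iter As in [step1_shared()].
#' @param step3 The result of [step3_link()].
#' @param fix_first Fix threshold 1 rather than the cut threshold.
#' @return Named list of `grm_calibration` objects (polytomous
#'   parameters on the common metric).
#' @export
step4_polytomous <- function(data, specs, step3,
                             quadrature = grm_quadrature(), tol = 1e-4,
                             max_iter = 500L, fix_first = FALSE) {
  out <- lapply(names(data), function(nm) {
    spec <- specs[[nm]]
    bin <- step3$params[[nm]]
    cons_tau <- vector("list", nrow(spec$items))
    cons_ft <- vector("list", nrow(spec$items))
    for (j in seq_len(nrow(spec$items))) {
      K <- spec$items$n_categories[j]
      cut <- if (fix_first) 1L else spec$items$cut[j]
      bi <- match(spec$items$id[j], bin$id)
      tv <- rep(NA_real_, K - 1L)
      ft <- rep(FALSE, K - 1L)
      tv[cut] <- bin$tau[[bi]][1L]
      ft[cut] <- TRUE
      cons_tau[[j]] <- tv
      cons_ft[[j]] <- ft
    }
    cons <- item_params(spec$items$id,
                        bin$lambda[match(spec$items$id, bin$id)],
                        cons_tau, fixed_lambda = TRUE,
                        fixed_tau = cons_ft)
    fit_grm(data[[nm]], spec, constraints = cons,
            quadrature = quadrature, tol = tol, max_iter = max_iter)
  })
  names(out) <- names(data)
  out
}

#' Run the four-step co-calibration pipeline
#'
#' Executes shared-item calibration, constrained all-item calibration,
#' Haebara linking to the reference instrument, and polytomous
#' recalibration, then scores every assessment on the common metric by
#' EAP.  When a short-form spec is supplied whose items are a subset of
#' a fitted instrument, it is scored from the parent calibration
#' restricted to its items rather than calibrated separately.
#'
#' @param data Named list of polytomous [response_table()] objects.
#' @param specs Named list of [instrument_spec()] objects covering
#'   `names(data)` (and any short forms).
#' @param reference Name of the reference instrument (default DRS-R-98).
#' @param anchor_domains Optional per-target anchor domain lists; for
#'   the bundled instruments defaults to [bundled_anchor_domains()].
#' @param short_forms Named list mapping a short-form spec name to its
#'   parent instrument name; defaults to `list("CAM-S-SF" = "CAM-S-LF")`
#'   when those specs are present.
#' @param quadrature A [grm_quadrature()].
#' @param tol,max_iter EM control settings passed to [fit_grm()].
#' @param symmetric Use the symmetrized Haebara criterion in step 3.
#' @param fix_first Step-4 threshold constraint choice; see
#'   [step4_polytomous()].
#' @return An object of class `harmonized_model`: list with `params`
#'   (per-instrument polytomous [item_params()] on the common metric),
#'   `scores` (per-instrument EAP score data.frames), `transforms`,
#'   `steps` (all intermediate calibrations), `specs`, `anchor_maps`,
#'   `reference`, and `log` (per-step iteration/log-likelihood records).
#' @examples
#' \donttest{
#' study <- simulate_study(generator_config(n_persons = 120, seed = 1))
#' model <- run_pipeline(study$data, bundled_instruments())
#' score_correlations(model)
#' crosswalk(model, "CAM-S-LF", targets = "DRS-R-98")
#' }
#' @export
run_pipeline <- function(data, specs, reference = "DRS-R-98",
                         anchor_domains = NULL, short_forms = NULL,
                         quadrature = grm_quadrature(), tol = 1e-4,
                         max_iter = 500L, symmetric = FALSE,
                         fix_first = FALSE) {
  stopifnot(length(data) >= 2L, reference %in% names(data),
            all(names(data) %in% names(specs)))
  if (is.null(anchor_domains)) {
    bundled <- bundled_anchor_domains()
    anchor_domains <- bundled[intersect(names(bundled), names(data))]
    if (!length(anchor_domains)) anchor_domains <- NULL
  }
  if (is.null(short_forms)) {
    short_forms <- list()
    if ("CAM-S-SF" %in% names(specs) && "CAM-S-LF" %in% names(data) &&
        !"CAM-S-SF" %in% names(data))
      short_forms <- list("CAM-S-SF" = "CAM-S-LF")
  }
  maps <- build_anchor_maps(specs[names(data)], reference = reference,
                            anchor_domains = anchor_domains)

  s1 <- step1_shared(data, specs, quadrature = quadrature, tol = tol,
                     max_iter = max_iter)
  s2 <- step2_all_items(data, specs, s1, quadrature = quadrature,
                        tol = tol, max_iter = max_iter)
  s3 <- step3_link(s2, maps, quadrature = quadrature,
                   symmetric = symmetric)
  s4 <- step4_polytomous(data, specs, s3, quadrature = quadrature,
                         tol = tol, max_iter = max_iter,
                         fix_first = fix_first)

  params <- lapply(s4, `[[`, "params")
  scores <- lapply(names(data), function(nm)
    eap_scores(data[[nm]], params[[nm]], quadrature))
  names(scores) <- names(data)

  for (sf in names(short_forms)) {
    parent <- short_forms[[sf]]
    sspec <- specs[[sf]]
    params[[sf]] <- params[[parent]][sspec$items$id]
    scores[[sf]] <- eap_scores(data[[parent]], params[[sf]], quadrature)
  }

  log <- lapply(list(step1 = s1, step2 = s2, step4 = s4), function(st)
    data.frame(instrument = names(st),
               n_iter = vapply(st, `[[`, 0L, "n_iter"),
               loglik = vapply(st, `[[`, 0, "loglik"),
               converged = vapply(st, `[[`, TRUE, "converged"),
               row.names = NULL))
  log$step3 <- data.frame(
    instrument = names(s3$transforms),
    A = vapply(s3$transforms, `[[`, 0, "A"),
    B = vapply(s3$transforms, `[[`, 0, "B"),
    criterion = vapply(s3$transforms, `[[`, 0, "criterion"),
    row.names = NULL)

  structure(list(params = params, scores = scores,
                 transforms = s3$transforms,
                 steps = list(step1 = s1, step2 = s2, step3 = s3,
                              step4 = s4),
                 specs = specs[unique(c(names(data), names(short_forms)))],
                 anchor_maps = maps, reference = reference,
                 short_forms = short_forms, quadrature = quadrature,
                 log = log),
            class = "harmonized_model")
}

#' @export
print.harmonized_model <- function(x, ...) {
  cat("<harmonized_model> reference:", x$reference, "\n")
  for (nm in names(x$params))
    cat("  ", nm, ": ", length(x$params[[nm]]), " items",
        if (nm %in% names(x$short_forms)) " (short form, scored from parent)",
        "\n", sep = "")
  invisible(x)
}
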