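#' Serialize a harmonized model to JSON
#'
#' Writes the per-instrument item parameters (common metric), linking
#' transforms, reference label, short-form mapping, and quadrature
#' settings.  Factor scores are recomputed from data rather than
#' stored.  All report tables regenerate identically from the
#' round-tripped model.
#'
#' @param model A `harmonized_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "harmonized_model"))
  enc_tau <- function(t) ifelse(is.finite(t), t,
                                ifelse(t > 0, "+inf", "-inf"))
  obj <- list(
    reference = model$reference,
    quadrature = list(n = length(model$quadrature$nodes),
                      range = range(model$quadrature$nodes)),
    short_forms = model$short_forms,
    transforms = lapply(model$transforms, function(t)
      list(A = t$A, B = t$B, criterion = t$criterion,
           anchors_used = if (!is.null(t$anchors)) t$anchors$domain)),
    instruments = lapply(names(model$params), function(nm) {
      p <- model$params[[nm]]
      spec <- model$specs[[nm]]
      list(name = nm, max_score = spec$max_score,
           items = lapply(seq_along(p$id), function(i)
             list(item_id = p$id[i],
                  domain = spec$items$domain[match(p$id[i], spec$items$id)],
                  cut = spec$items$cut[match(p$id[i], spec$items$id)],
                  n_categories = length(p$tau[[i]]) + 1L,
                  lambda = p$lambda[i],
                  tau = as.list(enc_tau(p$tau[[i]])))))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Reload a serialized harmonized model
#'
#' Restores the parameter/transform portion of a model written by
#' [write_model_json()]; the returned object supports every report
#' operation that does not need assessment-level scores
#' ([tcc()], [crosswalk()], [reliability_report()],
#' [item_person_map()]).
#'
#' @param path File written by [write_model_json()].
#' @return A `harmonized_model` (without `scores` or step artifacts).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dec_tau <- function(t) vapply(t, function(v) {
    if (identical(v, "+inf")) Inf
    else if (identical(v, "-inf")) -Inf
    else as.numeric(v)
  }, 0)
  params <- list()
  specs <- list()
  for (ins in obj$instruments) {
    ids <- vapply(ins$items, function(it) it$item_id, "")
    params[[ins$name]] <- item_params(
      ids,
      vapply(ins$items, function(it)
        if (is.null(it$lambda)) NA_real_ else as.numeric(it$lambda), 0),
      lapply(ins$items, function(it) dec_tau(it$tau)))
    specs[[ins$name]] <- instrument_spec(ins$name, data.frame(
      id = ids,
      domain = vapply(ins$items, function(it) it$domain, ""),
      shared = NA_character_,
      n_categories = vapply(ins$items, function(it)
        as.integer(it$n_categories), 1L),
      cut = vapply(ins$items, function(it) as.integer(it$cut), 1L),
      stringsAsFactors = FALSE))
  }
  transforms <- lapply(obj$transforms, function(t) {
    tr <- identity_transform()
    tr$A <- as.numeric(t$A); tr$B <- as.numeric(t$B)
    tr$criterion <- as.numeric(t$criterion)
    tr
  })
  qn <- obj$quadrature
  structure(list(params = params, scores = NULL,
                 transforms = transforms, steps = NULL, specs = specs,
                 anchor_maps = NULL, reference = obj$reference,
                 short_forms = obj$short_forms,
                 quadrature = grm_quadrature(as.integer(qn$n),
                                             as.numeric(qn$range)),
                 log = NULL),
            class = "harmonized_model")
}
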