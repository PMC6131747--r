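#' Anchor domain lists for the bundled instruments
#'
#' The pairwise anchor sets used to equate each target instrument to the
#' DRS-R-98 reference.  The MDAS is linked through six domains
#' (disorganized thinking, orientation, perceptual disturbance, sleep/wake
#' disturbance, delusions, memory); its attention and psychomotor-activity
#' items are not anchors because their content maps imperfectly onto the
#' DRS-R-98 counterparts (the MDAS psychomotor item pools agitation and
#' retardation into a single rating).  The CAM-S is linked through seven
#' domains (attention, disorganized thinking, orientation, perceptual
#' disturbance, psychomotor agitation, sleep/wake disturbance, psychomotor
#' retardation).
#'
#' @return A named list of character vectors of fine-grained domain
#'   labels, one per target instrument.
#' @export
bundled_anchor_domains <- function() {
  list(
    "MDAS" = c("disorganized_thinking", "orientation",
               "perceptual_disturbance", "sleep_wake", "delusions",
               "memory"),
    "CAM-S-LF" = c("attention", "disorganized_thinking", "orientation",
                   "perceptual_disturbance", "psychomotor_agitation",
                   "sleep_wake", "psychomotor_retardation")
  )
}

#' Shared-domain set common to a list of instruments
#'
#' The coarse `shared` labels carried by every instrument in `specs`.
#' For the bundled DRS-R-98, MDAS, and CAM-S long form this is a set of
#' seven domains: attention, disorganized thinking, memory, orientation,
#' perceptual disturbance, psychomotor disturbance, and sleep/wake
#' disturbance.
#'
#' @param specs A list of [instrument_spec()] objects.
#' @return Sorted character vector of shared-domain labels.
#' @export
shared_domains <- function(specs) {
  sets <- lapply(specs, function(s) unique(s$items$shared[!is.na(s$items$shared)]))
  sort(Reduce(intersect, sets))
}

#' Build anchor-item maps against a reference instrument
#'
#' Pairs each target instrument's items with reference-instrument items
#' that share a fine-grained domain label.  By default every domain
#' present in both instruments is used; `anchor_domains` restricts each
#' target to an explicit list (as [bundled_anchor_domains()] does for the
#' bundled configuration).
#'
#' @param specs Named list of [instrument_spec()] objects including the
#'   reference.
#' @param reference Name of the reference instrument.
#' @param anchor_domains Optional named list (by target instrument) of
#'   domain labels to anchor on.
#' @return An object of class `anchor_maps`: a named list with one
#'   data.frame per target (`domain`, `reference_item`, `target_item`)
#'   plus attributes `reference` and `shared_domains` (the three-way
#'   shared set across all instruments in `specs`).
#' @export
build_anchor_maps <- function(specs, reference = "DRS-R-98",
                              anchor_domains = NULL) {
  stopifnot(is.list(specs), reference %in% names(specs))
  ref <- specs[[reference]]
  targets <- setdiff(names(specs), reference)
  maps <- list()
  for (tn in targets) {
    tgt <- specs[[tn]]
    doms <- if (!is.null(anchor_domains) && !is.null(anchor_domains[[tn]])) {
      want <- anchor_domains[[tn]]
      absent_ref <- setdiff(want, ref$items$domain)
      absent_tgt <- setdiff(want, tgt$items$domain)
      if (length(absent_ref) || length(absent_tgt))
        stop("anchor domain(s) ",
             paste(unique(c(absent_ref, absent_tgt)), collapse = ", "),
             " not present in both '", reference, "' and '", tn, "'")
      want
    } else {
      intersect(tgt$items$domain, ref$items$domain)
    }
    if (length(doms)) {
      maps[[tn]] <- data.frame(
        domain = doms,
        reference_item = ref$items$id[match(doms, ref$items$domain)],
        target_item = tgt$items$id[match(doms, tgt$items$domain)],
        stringsAsFactors = FALSE)
    } else {
      maps[[tn]] <- data.frame(domain = character(), reference_item = character(),
                               target_item = character(), stringsAsFactors = FALSE)
    }
  }
  structure(maps, reference = reference,
            shared_domains = shared_domains(specs),
            class = "anchor_maps")
}

#' @export
print.anchor_maps <- function(x, ...) {
  cat("<anchor_maps> reference:", attr(x, "reference"), "\n")
  for (tn in names(x))
    cat("  ", tn, ": ", nrow(x[[tn]]), " anchor pairs\n", sep = "")
  cat("  shared domains (all instruments): ",
      length(attr(x, "shared_domains")), "\n", sep = "")
  invisible(x)
}
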