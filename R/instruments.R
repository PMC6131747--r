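#' Instrument specifications
#'
#' An `instrument_spec` describes one rating instrument: its items, the
#' number of ordered response categories per item, the fine-grained symptom
#' domain of each item (the join key for pairwise anchor matching), the
#' coarse shared-domain label (used to determine the set of items common
#' to all instruments), and the dichotomization cut of each item.
#'
#' Ratings are integer codes `0 .. categories-1`, 0 meaning the symptom is
#' not present.  The dichotomization cut `c` maps ratings `< c` to 0 and
#' `>= c` to 1; the default cut of 1 contrasts "not present" with "any
#' symptom".  Sleep/wake disturbance uses cut 2 ("not present or mild" vs
#' "moderate or severe"), because mild sleep disturbance is near-universal
#' in hospitalized older adults and carries little severity information.
#'
#' @param name Instrument label.
#' @param items A data.frame with columns `id`, `domain`, `shared`
#'   (NA when the item is not part of the three-way shared set),
#'   `n_categories`, and `cut`.
#' @return An object of class `instrument_spec` with fields `name`,
#'   `items`, and `max_score` (the sum over items of `n_categories - 1`).
#' @seealso [load_instrument_spec()], [bundled_instruments()]
#' @export
instrument_spec <- function(name, items) {
  stopifnot(is.character(name), length(name) == 1L, is.data.frame(items))
  required <- c("id", "domain", "n_categories", "cut")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols))
    stop("instrument '", name, "': missing item fields: ",
         paste(missing_cols, collapse = ", "))
  if (!"shared" %in% names(items)) items$shared <- NA_character_
  items <- items[, c("id", "domain", "shared", "n_categories", "cut")]
  items$id <- as.character(items$id)
  items$domain <- as.character(items$domain)
  items$shared <- as.character(items$shared)
  items$n_categories <- as.integer(items$n_categories)
  items$cut <- as.integer(items$cut)
  if (anyDuplicated(items$id))
    stop("instrument '", name, "': duplicate item ids")
  if (any(items$n_categories < 2L))
    stop("instrument '", name, "': every item needs at least 2 categories")
  bad_cut <- items$cut < 1L | items$cut > items$n_categories - 1L
  if (any(bad_cut))
    stop("instrument '", name, "': dichotomization cut out of range for ",
         paste(items$id[bad_cut], collapse = ", "))
  rownames(items) <- NULL
  structure(
    list(name = name, items = items,
         max_score = sum(items$n_categories - 1L)),
    class = "instrument_spec"
  )
}

#' Load an instrument specification from YAML or JSON
#'
#' The file schema is `{name, items: [{id, domain, shared?, categories,
#' cut?}]}`; `cut` defaults to 1 and `shared` to absent.  `max_score` is
#' always computed from the item list, never read from the file.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An [instrument_spec()].
#' @export
load_instrument_spec <- function(path) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$name)) stop("instrument file ", path, ": missing field 'name'")
  if (is.null(raw$items) || !length(raw$items))
    stop("instrument file ", path, ": missing or empty field 'items'")
  rows <- lapply(seq_along(raw$items), function(i) {
    it <- raw$items[[i]]
    for (f in c("id", "domain", "categories")) {
      if (is.null(it[[f]]))
        stop("instrument file ", path, ": item ", i, " missing field '", f, "'")
    }
    data.frame(id = as.character(it$id),
               domain = as.character(it$domain),
               shared = if (is.null(it$shared)) NA_character_ else as.character(it$shared),
               n_categories = as.integer(it$categories),
               cut = if (is.null(it$cut)) 1L else as.integer(it$cut),
               stringsAsFactors = FALSE)
  })
  instrument_spec(as.character(raw$name), do.call(rbind, rows))
}

#' Bundled instrument definitions
#'
#' Loads the instrument specifications shipped with the package:
#' the 13-item DRS-R-98 (four categories per item, score range 0-39),
#' the 10-item MDAS (four categories, 0-30), the 10-item CAM-S long form
#' (three categories plus a binary acute-onset/fluctuation feature, 0-19),
#' and the 4-item CAM-S short form (0-7).
#'
#' @param which Character vector of instruments to load; defaults to all.
#' @return A named list of [instrument_spec()] objects.
#' @examples
#' specs <- bundled_instruments()
#' vapply(specs, `[[`, integer(1), "max_score")
#' shared_domains(specs[c("DRS-R-98", "MDAS", "CAM-S-LF")])
#' @export
bundled_instruments <- function(which = c("DRS-R-98", "MDAS", "CAM-S-LF", "CAM-S-SF")) {
  files <- c(`DRS-R-98` = "drs_r98.yaml", MDAS = "mdas.yaml",
             `CAM-S-LF` = "cams_long.yaml", `CAM-S-SF` = "cams_short.yaml")
  which <- match.arg(which, names(files), several.ok = TRUE)
  out <- lapply(which, function(w) {
    load_instrument_spec(system.file("extdata", "instruments", files[[w]],
                                     package = "delharm", mustWork = TRUE))
  })
  names(out) <- which
  out
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat("<instrument_spec> ", x$name, "\n", sep = "")
  cat("  ", nrow(x$items), " items, sum-score range 0-", x$max_score, "\n", sep = "")
  shared <- sum(!is.na(x$items$shared))
  cat("  ", shared, " items in shared domains\n", sep = "")
  invisible(x)
}

#' Restrict an instrument to a subset of its items
#'
#' Used to derive reduced forms that are scored from a parent calibration
#' (e.g. the CAM-S short form from the long form).
#'
#' @param spec An [instrument_spec()].
#' @param item_ids Items to keep, in the order given.
#' @param name Name for the reduced instrument.
#' @return An [instrument_spec()].
#' @export
subset_spec <- function(spec, item_ids, name = spec$name) {
  stopifnot(inherits(spec, "instrument_spec"))
  missing_items <- setdiff(item_ids, spec$items$id)
  if (length(missing_items))
    stop("items not in '", spec$name, "': ", paste(missing_items, collapse = ", "))
  instrument_spec(name, spec$items[match(item_ids, spec$items$id), ])
}

# Binary version of a spec: every item becomes 2-category with cut 1.
# Item ids, domains and shared labels are preserved so anchor maps apply
# unchanged to dichotomized data.
#' Dichotomized version of an instrument specification
#'
#' @param spec An [instrument_spec()].
#' @return An [instrument_spec()] in which every item has two categories.
#' @export
dichotomize_spec <- function(spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  items <- spec$items
  items$n_categories <- 2L
  items$cut <- 1L
  instrument_spec(spec$name, items)
}
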