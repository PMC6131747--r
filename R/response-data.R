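#' Response tables
#'
#' A `response_table` holds one instrument's integer item ratings in wide
#' format: one row per assessment (person-day), columns `person_id`, `day`,
#' then one column per item in the instrument's item order.  Ratings are
#' integers in `0 .. n_categories - 1`; `NA` marks a missing rating.  The
#' unit of analysis is the assessment, not the person: the same person
#' contributes one row per hospital day rated.
#'
#' @param data A data.frame in wide format (`person_id`, `day`, item
#'   columns) or long format (`person_id`, `day`, `item_id`, `rating`).
#' @param spec The [instrument_spec()] the data belong to.
#' @param format `"wide"` or `"long"`.
#' @return A data.frame of class `response_table` with attribute
#'   `instrument` set to `spec$name`.
#' @export
response_table <- function(data, spec, format = c("wide", "long")) {
  stopifnot(inherits(spec, "instrument_spec"), is.data.frame(data))
  format <- match.arg(format)
  if (format == "long") {
    need <- c("person_id", "day", "item_id", "rating")
    if (!all(need %in% names(data)))
      stop("long format requires columns: ", paste(need, collapse = ", "))
    unknown <- setdiff(unique(data$item_id), spec$items$id)
    if (length(unknown))
      stop("unknown item ids for '", spec$name, "': ",
           paste(unknown, collapse = ", "))
    key <- paste(data$person_id, data$day, sep = "\r")
    if (anyDuplicated(paste(key, data$item_id)))
      stop("duplicate (person, day, item) entries in long data")
    ukey <- unique(key)
    ids <- spec$items$id
    m <- matrix(NA_integer_, nrow = length(ukey), ncol = length(ids),
                dimnames = list(NULL, ids))
    m[cbind(match(key, ukey), match(data$item_id, ids))] <-
      as.integer(data$rating)
    first <- match(ukey, key)
    data <- data.frame(person_id = data$person_id[first],
                       day = data$day[first], m, check.names = FALSE)
  }
  if (!all(c("person_id", "day") %in% names(data)))
    stop("wide format requires columns person_id and day")
  missing_items <- setdiff(spec$items$id, names(data))
  if (length(missing_items))
    stop("missing item columns for '", spec$name, "': ",
         paste(missing_items, collapse = ", "))
  out <- data[, c("person_id", "day", spec$items$id)]
  if (any(out$day < 1, na.rm = TRUE)) stop("day indices must be >= 1")
  if (anyDuplicated(paste(out$person_id, out$day)))
    stop("duplicate (person_id, day) assessments for '", spec$name, "'")
  for (j in seq_len(nrow(spec$items))) {
    id <- spec$items$id[j]
    v <- out[[id]]
    if (!is.numeric(v)) stop("item column '", id, "' is not numeric; ",
                             "use recode_missing() for raw coded data")
    bad <- which(!is.na(v) & (v < 0 | v > spec$items$n_categories[j] - 1L |
                                v != floor(v)))
    if (length(bad))
      stop("item '", id, "': rating out of range 0..",
           spec$items$n_categories[j] - 1L, " in row(s) ",
           paste(head(bad, 5L), collapse = ", "))
    out[[id]] <- as.integer(v)
  }
  rownames(out) <- NULL
  structure(out, instrument = spec$name,
            class = c("response_table", "data.frame"))
}

#' Recode raw item codes, mapping administrative codes to missing
#'
#' Field data carry non-numeric administrative codes ("uncertain",
#' "refused", "don't know") alongside integer ratings; these are set to
#' missing.  Any remaining non-numeric or out-of-range code is an error,
#' reported with row and item.
#'
#' @param raw A wide data.frame (`person_id`, `day`, one column per item)
#'   whose item columns may be character or numeric.
#' @param spec The [instrument_spec()].
#' @param missing_codes Character vector of codes to treat as missing.
#' @return A validated [response_table()].
#' @export
recode_missing <- function(raw, spec,
                           missing_codes = c("", "NA", "uncertain",
                                             "refused", "dont_know")) {
  stopifnot(inherits(spec, "instrument_spec"), is.data.frame(raw))
  missing_items <- setdiff(spec$items$id, names(raw))
  if (length(missing_items))
    stop("missing item columns: ", paste(missing_items, collapse = ", "))
  out <- raw
  for (j in seq_len(nrow(spec$items))) {
    id <- spec$items$id[j]
    v <- out[[id]]
    if (is.factor(v)) v <- as.character(v)
    if (is.character(v)) {
      v <- trimws(v)
      v[v %in% missing_codes] <- NA_character_
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad))
        stop("item '", id, "': unrecognized code(s) ",
             paste(unique(v[bad]), collapse = ", "), " in row(s) ",
             paste(head(bad, 5L), collapse = ", "))
      v <- num
    } else {
      v[!is.na(v) & v %in% suppressWarnings(as.numeric(missing_codes))] <- NA
    }
    K <- spec$items$n_categories[j]
    bad <- which(!is.na(v) & (v < 0 | v > K - 1 | v != floor(v)))
    if (length(bad))
      stop("item '", id, "': rating out of range 0..", K - 1L,
           " in row(s) ", paste(head(bad, 5L), collapse = ", "),
           " (value(s) ", paste(unique(v[bad]), collapse = ", "),
           " not listed as missing codes)")
    out[[id]] <- as.integer(v)
  }
  response_table(out, spec)
}

#' Instrument sum scores
#'
#' The overall severity score of an instrument is the sum of its item
#' ratings.  By default an assessment with any missing item gets a missing
#' total, so severity is never silently understated; `prorate = TRUE`
#' instead scales the mean observed item score to the full item count
#' (rounded half-up) and flags the result with a `prorated` column.
#'
#' @param table A [response_table()].
#' @param spec The matching [instrument_spec()].
#' @param prorate Use mean-item proration for partially missing
#'   assessments instead of returning `NA`.
#' @return A data.frame `person_id`, `day`, `score` (and `prorated` when
#'   `prorate = TRUE`).
#' @export
sum_score <- function(table, spec, prorate = FALSE) {
  stopifnot(inherits(spec, "instrument_spec"))
  m <- as.matrix(table[, spec$items$id, drop = FALSE])
  n_obs <- rowSums(!is.na(m))
  total <- rowSums(m, na.rm = TRUE)
  complete <- n_obs == nrow(spec$items)
  out <- data.frame(person_id = table$person_id, day = table$day)
  if (prorate) {
    score <- ifelse(n_obs == 0, NA_real_,
                    round_half_up(total / n_obs * nrow(spec$items)))
    out$score <- pmin(score, spec$max_score)
    out$prorated <- n_obs > 0 & !complete
  } else {
    out$score <- ifelse(complete, total, NA_real_)
  }
  out
}

#' Dichotomize item ratings at each item's cut
#'
#' Ratings below the item's dichotomization cut become 0 and ratings at or
#' above it become 1; missing stays missing.  With the default cut of 1
#' this contrasts "not present" with "any symptom"; sleep/wake items carry
#' cut 2 ("not present or mild" vs "moderate or severe").  The operation
#' is idempotent on its own output.
#'
#' @param table A [response_table()].
#' @param spec The matching [instrument_spec()].
#' @return A [response_table()] validated against [dichotomize_spec()].
#' @export
dichotomize <- function(table, spec) {
  stopifnot(inherits(spec, "instrument_spec"))
  out <- as.data.frame(table)
  for (j in seq_len(nrow(spec$items))) {
    id <- spec$items$id[j]
    out[[id]] <- as.integer(out[[id]] >= spec$items$cut[j])
  }
  response_table(out, dichotomize_spec(spec))
}

# Half-up rounding to the nearest integer (round() rounds half to even,
# which would bias crosswalk scores at .5 boundaries).
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)
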