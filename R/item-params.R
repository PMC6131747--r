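#' Item parameter sets for the graded response model
#'
#' Parameters live on the logistic latent metric (no 1.7 scaling): the
#' probability of rating at or above category `k` is
#' `P(y >= k | theta) = plogis(lambda * theta - tau[k])` for
#' `k = 1 .. K-1`.  `lambda` is the item slope (factor loading on the
#' logit metric); `tau` the ordered thresholds.  Unobservable boundary
#' categories may carry `-Inf`/`+Inf` sentinel thresholds.  The
#' `fixed_lambda`/`fixed_tau` flags declare which parameters a fit must
#' hold at their stored values.
#'
#' @param id Character vector of item ids.
#' @param lambda Numeric vector of slopes (`NA` for items flagged as
#'   degenerate).
#' @param tau List of numeric threshold vectors, strictly increasing.
#' @param fixed_lambda Logical vector (recycled).
#' @param fixed_tau List of logical vectors matching `tau` (recycled from
#'   a single logical).
#' @return An object of class `item_params`.
#' @export
item_params <- function(id, lambda, tau, fixed_lambda = FALSE,
                        fixed_tau = FALSE) {
  id <- as.character(id)
  n <- length(id)
  stopifnot(length(lambda) == n, length(tau) == n)
  lambda <- as.numeric(lambda)
  tau <- lapply(tau, as.numeric)
  if (is.logical(fixed_lambda)) fixed_lambda <- rep_len(fixed_lambda, n)
  if (is.logical(fixed_tau) && !is.list(fixed_tau))
    fixed_tau <- lapply(tau, function(t) rep_len(fixed_tau[1L], length(t)))
  stopifnot(length(fixed_tau) == n)
  for (i in seq_len(n)) {
    ti <- tau[[i]]
    if (length(ti) < 1L)
      stop("item '", id[i], "': needs at least one threshold")
    fin <- ti[is.finite(ti)]
    if (length(fin) > 1L && any(diff(ti[!is.na(ti)]) <= 0))
      stop("item '", id[i], "': thresholds must be strictly increasing")
    if (length(fixed_tau[[i]]) != length(ti))
      stop("item '", id[i], "': fixed_tau length mismatch")
  }
  structure(list(id = id, lambda = lambda, tau = tau,
                 fixed_lambda = fixed_lambda, fixed_tau = fixed_tau),
            class = "item_params")
}

#' @export
length.item_params <- function(x) length(x$id)

#' @export
`[.item_params` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  if (anyNA(i)) stop("unknown item id(s)")
  item_params(x$id[i], x$lambda[i], x$tau[i],
              x$fixed_lambda[i], x$fixed_tau[i])
}

#' @export
print.item_params <- function(x, digits = 3, ...) {
  cat("<item_params> ", length(x), " items (logistic metric)\n", sep = "")
  print(as.data.frame(x, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.item_params <- function(x, ..., digits = NULL) {
  K <- max(vapply(x$tau, length, 1L))
  m <- do.call(rbind, lapply(x$tau, function(t)
    c(t, rep(NA_real_, K - length(t)))))
  colnames(m) <- paste0("tau", seq_len(K))
  d <- data.frame(item = x$id, lambda = x$lambda, m,
                  stringsAsFactors = FALSE)
  if (!is.null(digits)) d[-1] <- lapply(d[-1], round, digits = digits)
  d
}

#' Combine item parameter sets
#' @param ... `item_params` objects.
#' @return A single `item_params` object.
#' @export
c.item_params <- function(...) {
  xs <- list(...)
  item_params(
    unlist(lapply(xs, `[[`, "id")),
    unlist(lapply(xs, `[[`, "lambda")),
    do.call(c, lapply(xs, `[[`, "tau")),
    unlist(lapply(xs, `[[`, "fixed_lambda")),
    do.call(c, lapply(xs, `[[`, "fixed_tau"))
  )
}

#' Convert factor-analytic parameters to IRT slope/location form
#'
#' On the logistic metric the IRT discrimination is `a = lambda` and the
#' category locations are `b_k = tau_k / lambda` (the latent level at
#' which rating at or above `k` has probability one half).
#'
#' @param params An [item_params()] object with positive slopes.
#' @return A data.frame `item`, `a`, `k`, `b` with one row per threshold.
#' @seealso [irt_to_fa()]
#' @export
fa_to_irt <- function(params) {
  stopifnot(inherits(params, "item_params"))
  if (any(!is.na(params$lambda) & params$lambda <= 0))
    stop("IRT locations b_k = tau_k / lambda are undefined for items ",
         "with non-positive slope")
  do.call(rbind, lapply(seq_along(params$id), function(i) {
    data.frame(item = params$id[i], a = params$lambda[i],
               k = seq_along(params$tau[[i]]),
               b = params$tau[[i]] / params$lambda[i],
               stringsAsFactors = FALSE)
  }))
}

#' Convert IRT slope/location parameters back to factor-analytic form
#'
#' @param irt A data.frame as returned by [fa_to_irt()].
#' @return An [item_params()] object.
#' @export
irt_to_fa <- function(irt) {
  ids <- unique(irt$item)
  item_params(
    ids,
    irt$a[match(ids, irt$item)],
    lapply(ids, function(id) {
      rows <- irt[irt$item == id, ]
      rows <- rows[order(rows$k), ]
      rows$a[1L] * rows$b
    })
  )
}

#' Write item parameters to JSON
#'
#' @param params An [item_params()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  # infinite sentinel thresholds encode as "+inf"/"-inf" (JSON has no Inf)
  enc <- function(t) as.list(ifelse(is.finite(t), t,
                                    ifelse(t > 0, "+inf", "-inf")))
  recs <- lapply(seq_along(params$id), function(i) {
    list(item_id = params$id[i], lambda = params$lambda[i],
         tau = enc(params$tau[[i]]),
         fixed_lambda = params$fixed_lambda[i],
         fixed_tau = params$fixed_tau[[i]])
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read item parameters from JSON
#'
#' @param path File written by [write_params_json()].
#' @return An [item_params()] object.
#' @export
read_params_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  null_na <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  dec <- function(x) {
    if (identical(x, "+inf")) return(Inf)
    if (identical(x, "-inf")) return(-Inf)
    null_na(x)
  }
  item_params(
    vapply(recs, function(r) as.character(r$item_id), ""),
    vapply(recs, function(r) null_na(r$lambda), 1.0),
    lapply(recs, function(r) vapply(r$tau, dec, 1.0)),
    vapply(recs, function(r) isTRUE(r$fixed_lambda), TRUE),
    lapply(recs, function(r) vapply(r$fixed_tau, isTRUE, TRUE))
  )
}
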