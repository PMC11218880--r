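#' Detect wrong-patient retract-and-reorder (RAR) events
#'
#' A RAR event — the validated near-miss proxy for wrong-patient order entry —
#' is an order retracted within 10 minutes of placement and re-placed by the
#' *same provider* as the *same order* (identical order code) on a *different
#' patient* within 10 minutes of the retraction.
#'
#' Matching is one-to-one and greedy earliest-first: retractions are processed
#' in retraction-time order (ties broken by `order_id`), and each claims the
#' earliest-placed compatible reorder not already consumed by an earlier
#' retraction (ties again by `order_id`). Both windows are open at 0 s —
#' zero-latency pairs are record artifacts — and closed at the window bound.
#' The input row order never affects the result.
#'
#' @param orders A tibble of order events with columns `order_id`,
#'   `patient_id`, `provider_id`, `order_code`, `placed_time`, `retract_time`
#'   (`NA` when never retracted). Timestamps either POSIXct or ISO-8601
#'   strings.
#' @param w_retract_s Maximum placement-to-retraction latency in seconds
#'   (default 600).
#' @param w_reorder_s Maximum retraction-to-reorder latency in seconds
#'   (default 600).
#' @return A tibble of RAR events sorted by retraction time: the retracted
#'   (wrong-patient) and reorder order ids, provider, both patient ids, and
#'   both latencies in seconds.
#' @examples
#' orders <- tibble::tibble(
#'   order_id = c("a", "b"), patient_id = c("P1", "P2"),
#'   provider_id = "D1", order_code = "C1",
#'   placed_time = lubridate::as_datetime(c(0, 700)),
#'   retract_time = lubridate::as_datetime(c(500, NA))
#' )
#' detect_rar_events(orders)
#' @export
detect_rar_events <- function(orders, w_retract_s = 600, w_reorder_s = 600) {
  stopifnot(w_retract_s > 0, w_reorder_s > 0)
  orders <- validate_orders(orders)
  n <- nrow(orders)
  empty <- empty_rar_events()
  if (n == 0L) {
    return(empty)
  }

  placed <- as.numeric(orders$placed_time)
  retracted <- as.numeric(orders$retract_time)
  lat <- retracted - placed
  is_retraction <- !is.na(lat) & lat > 0 & lat <= w_retract_s
  if (!any(is_retraction)) {
    return(empty)
  }

  key <- paste0(orders$provider_id, "\r", orders$order_code)
  r_idx <- which(is_retraction)
  r_idx <- r_idx[order(retracted[r_idx], orders$order_id[r_idx])]

  active_keys <- unique(key[r_idx])
  pool_rows <- which(key %in% active_keys)
  pool_by_key <- split(pool_rows, key[pool_rows])
  consumed <- logical(n)

  out_r <- integer(0)
  out_o <- integer(0)
  for (i in r_idx) {
    cand <- pool_by_key[[key[i]]]
    gap <- placed[cand] - retracted[i]
    ok <- !consumed[cand] & gap > 0 & gap <= w_reorder_s &
      orders$patient_id[cand] != orders$patient_id[i]
    if (!any(ok)) next
    cand <- cand[ok]
    pick <- cand[order(placed[cand], orders$order_id[cand])][1L]
    consumed[pick] <- TRUE
    out_r <- c(out_r, i)
    out_o <- c(out_o, pick)
  }
  if (length(out_r) == 0L) {
    return(empty)
  }
  tibble::tibble(
    retracted_order_id = orders$order_id[out_r],
    reorder_order_id = orders$order_id[out_o],
    provider_id = orders$provider_id[out_r],
    wrong_patient_id = orders$patient_id[out_r],
    correct_patient_id = orders$patient_id[out_o],
    place_to_retract_s = lat[out_r],
    retract_to_reorder_s = placed[out_o] - retracted[out_r]
  )
}

empty_rar_events <- function() {
  tibble::tibble(
    retracted_order_id = character(), reorder_order_id = character(),
    provider_id = character(), wrong_patient_id = character(),
    correct_patient_id = character(), place_to_retract_s = numeric(),
    retract_to_reorder_s = numeric()
  )
}

validate_orders <- function(orders) {
  req <- c("order_id", "patient_id", "provider_id", "order_code",
           "placed_time", "retract_time")
  missing <- setdiff(req, names(orders))
  if (length(missing) > 0L) {
    stop("data-integrity error: orders missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(orders$order_id)) {
    dup <- orders$order_id[duplicated(orders$order_id)][1L]
    stop("data-integrity error: duplicate order_id '", dup, "'", call. = FALSE)
  }
  for (col in c("placed_time", "retract_time")) {
    orders[[col]] <- parse_time_col(orders[[col]], col)
  }
  orders
}

parse_time_col <- function(x, col) {
  if (lubridate::is.POSIXct(x)) {
    return(lubridate::with_tz(x, "UTC"))
  }
  was_na <- is.na(x) | (is.character(x) & !is.na(x) & x == "")
  out <- suppressWarnings(lubridate::as_datetime(x, tz = "UTC"))
  bad <- which(is.na(out) & !was_na)
  if (length(bad) > 0L) {
    stop("parse error: unparseable timestamp in `", col, "` at row ", bad[1L],
         call. = FALSE)
  }
  out
}

#' Retracted-order ids of detected RAR events
#'
#' The retracted orders are the wrong-patient orders; their ids flag the order
#' sessions counted as RAR sessions.
#'
#' @param events A tibble from [detect_rar_events()].
#' @return Character vector of unique retracted order ids.
#' @export
rar_order_ids <- function(events) {
  unique(events$retracted_order_id)
}

#' Read an order log / write detected RAR events as CSV
#'
#' @param path CSV path. Orders use the generator dialect (ISO-8601 UTC
#'   timestamps, empty fields for missing values).
#' @return `read_orders()` a tibble of orders; `write_rar_events()` the path,
#'   invisibly.
#' @export
read_orders <- function(path) {
  orders <- readr::read_csv(
    path,
    col_types = readr::cols(
      order_id = readr::col_character(),
      patient_id = readr::col_character(),
      provider_id = readr::col_character(),
      order_code = readr::col_character(),
      placed_time = readr::col_character(),
      retract_time = readr::col_character(),
      .default = readr::col_character()
    ),
    na = ""
  )
  validate_orders(orders)
}

#' @param events A tibble from [detect_rar_events()].
#' @rdname read_orders
#' @export
write_rar_events <- function(events, path) {
  readr::write_csv(events, path, na = "")
  invisible(path)
}
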