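# Independent quadratic brute-force RAR detector used as the oracle.
# Enumerates every (retraction, reorder) candidate pair and applies greedy
# earliest-first one-to-one matching; no sorting/indexing shortcuts shared
# with the production detector.
brute_force_rar <- function(orders, w_retract_s = 600, w_reorder_s = 600) {
  placed <- as.numeric(orders$placed_time)
  retracted <- as.numeric(orders$retract_time)
  pi <- integer(0)
  pj <- integer(0)
  for (i in seq_len(nrow(orders))) {
    lat <- retracted[i] - placed[i]
    if (is.na(lat) || lat <= 0 || lat > w_retract_s) next
    gap <- placed - retracted[i]
    j <- which(!is.na(gap) & gap > 0 & gap <= w_reorder_s &
                 orders$provider_id == orders$provider_id[i] &
                 orders$order_code == orders$order_code[i] &
                 orders$patient_id != orders$patient_id[i])
    pi <- c(pi, rep(i, length(j)))
    pj <- c(pj, j)
  }
  if (length(pi) == 0L) {
    return(rarwatch::detect_rar_events(orders[0, ]))
  }
  ord <- order(retracted[pi], orders$order_id[pi], placed[pj],
               orders$order_id[pj])
  used_r <- used_j <- logical(nrow(orders))
  keep_i <- keep_j <- integer(0)
  for (k in ord) {
    if (used_r[pi[k]] || used_j[pj[k]]) next
    used_r[pi[k]] <- TRUE
    used_j[pj[k]] <- TRUE
    keep_i <- c(keep_i, pi[k])
    keep_j <- c(keep_j, pj[k])
  }
  o <- order(retracted[keep_i], orders$order_id[keep_i])
  keep_i <- keep_i[o]
  keep_j <- keep_j[o]
  tibble::tibble(
    retracted_order_id = orders$order_id[keep_i],
    reorder_order_id = orders$order_id[keep_j],
    provider_id = orders$provider_id[keep_i],
    wrong_patient_id = orders$patient_id[keep_i],
    correct_patient_id = orders$patient_id[keep_j],
    place_to_retract_s = retracted[keep_i] - placed[keep_i],
    retract_to_reorder_s = placed[keep_j] - retracted[keep_i]
  )
}

# Dense random small logs: few providers/patients/codes, tight time range,
# latencies straddling the 600 s boundary, ~half the orders retracted.
random_small_log <- function(n, seed) {
  set.seed(seed)
  t0 <- lubridate::as_datetime("2021-06-01", tz = "UTC")
  placed <- t0 + round(stats::runif(n, 0, 3 * 3600))
  retract_lat <- sample(c(NA, 1, 50, 300, 599, 600, 601, 900), n,
                        replace = TRUE)
  tibble::tibble(
    order_id = sprintf("o%03d", sample.int(999, n)),
    patient_id = sample(paste0("P", 1:4), n, replace = TRUE),
    provider_id = sample(paste0("D", 1:3), n, replace = TRUE),
    order_code = sample(paste0("C", 1:3), n, replace = TRUE),
    placed_time = placed,
    retract_time = placed + retract_lat,
    sign_time = placed
  )
}

expect_same_events <- function(a, b) {
  key <- function(x) paste(x$retracted_order_id, x$reorder_order_id)
  expect_identical(nrow(a), nrow(b))
  expect_setequal(key(a), key(b))
}
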