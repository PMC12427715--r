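#' Panel-release thresholds for microbial counts
#'
#' Release criteria for ready-to-eat, low-moisture dates: per analyte, a
#' count at or below the acceptance limit is accepted, a count above it but
#' at or below the reject threshold is held for investigation, and anything
#' above the reject threshold excludes the lot. Defaults: total viable
#' count (TVC) accept <= 5.0, reject > 6.0 log CFU/g; yeast enumeration
#' (YE) accept <= 4.0, reject > 5.0 log CFU/g. The hold band shares its
#' lower bound with the acceptance limit; half-open intervals resolve the
#' overlap (a count exactly at the limit is accepted).
#'
#' @param tvc_accept,tvc_reject TVC limits (log CFU/g).
#' @param ye_accept,ye_reject YE limits (log CFU/g).
#' @return A `release_policy` list.
#' @export
release_policy <- function(tvc_accept = 5.0, tvc_reject = 6.0,
                           ye_accept = 4.0, ye_reject = 5.0) {
  if (tvc_reject <= tvc_accept || ye_reject <= ye_accept) {
    abort("reject thresholds must exceed acceptance limits")
  }
  structure(list(tvc_accept = tvc_accept, tvc_reject = tvc_reject,
                 ye_accept = ye_accept, ye_reject = ye_reject),
            class = "release_policy")
}

categorize_count <- function(x, accept, reject) {
  ifelse(x <= accept, "accept", ifelse(x <= reject, "hold", "reject"))
}

#' Release decision for microbial counts
#'
#' Applies the per-analyte thresholds to TVC and YE counts and combines them
#' by worst case: reject dominates hold dominates accept. Vectorized; input
#' is a data frame with `tvc_log` and `ye_log` columns (log CFU/g, `>= 0`).
#'
#' @param counts Data frame with `tvc_log` and `ye_log` columns.
#' @param policy A [release_policy()].
#' @return The input as a tibble plus `tvc_category`, `ye_category`,
#'   `category` (overall) and `reasons` (semicolon-separated violations,
#'   `""` when accepted).
#' @examples
#' release_decision(tibble::tibble(tvc_log = c(4, 5.5, 4), ye_log = c(3, 3, 5.5)))
#' @export
release_decision <- function(counts, policy = release_policy()) {
  check_columns(counts, c("tvc_log", "ye_log"), "microbial counts")
  check_finite(counts$tvc_log, "tvc_log")
  check_finite(counts$ye_log, "ye_log")
  if (any(counts$tvc_log < 0) || any(counts$ye_log < 0)) {
    abort("log CFU/g counts must be non-negative")
  }
  out <- tibble::as_tibble(counts)
  out$tvc_category <- categorize_count(out$tvc_log, policy$tvc_accept, policy$tvc_reject)
  out$ye_category <- categorize_count(out$ye_log, policy$ye_accept, policy$ye_reject)
  severity <- c(accept = 1L, hold = 2L, reject = 3L)
  overall <- pmax(severity[out$tvc_category], severity[out$ye_category])
  out$category <- names(severity)[overall]
  out$reasons <- purrr::map2_chr(out$tvc_category, out$ye_category, function(tc, yc) {
    r <- c(if (tc != "accept") sprintf("TVC %s", tc),
           if (yc != "accept") sprintf("YE %s", yc))
    paste(r, collapse = "; ")
  })
  out
}

#' Screen a batch of microbial composites
#'
#' Applies [release_decision()] to every composite of a candidate batch. Any
#' reject excludes the batch from service immediately; any hold (with no
#' reject) flags the batch for re-plating and a handling-records review;
#' otherwise the batch is released.
#'
#' @inheritParams release_decision
#' @return A list: `decisions` (per-composite tibble), `batch_status`
#'   (`"released"`, `"flagged"` or `"excluded"`), and counts per category.
#' @export
screen_batch <- function(counts, policy = release_policy()) {
  if (nrow(counts) == 0) abort("empty batch: no microbial composites to screen")
  decisions <- release_decision(counts, policy)
  n_reject <- sum(decisions$category == "reject")
  n_hold <- sum(decisions$category == "hold")
  status <- if (n_reject > 0) "excluded" else if (n_hold > 0) "flagged" else "released"
  list(
    decisions = decisions,
    batch_status = status,
    n_accept = sum(decisions$category == "accept"),
    n_hold = n_hold,
    n_reject = n_reject
  )
}
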