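#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted block-design GLM
#'
#' One row per channel, chromophore and model term, with estimate and
#' standard error.
#'
#' @param x A `cctc_glm` from [glm_hrf()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cctc_glm <- function(x, ...) {
  x$coefficients
}

#' One-row-per-channel GLM summary
#'
#' Peak response, time-to-peak and residual variance per channel and
#' chromophore.
#'
#' @param x A `cctc_glm`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.cctc_glm <- function(x, ...) {
  peaks <- x$hrf |>
    dplyr::group_by(.data$channel, .data$chromophore) |>
    dplyr::summarise(
      peak_response = .data$response[which.max(abs(.data$response))],
      time_to_peak = .data$time[which.max(abs(.data$response))],
      .groups = "drop")
  dplyr::left_join(peaks, x$residual_var,
                   by = c("channel", "chromophore"))
}

#' Tidy the region-change analysis
#'
#' @param x A `region_change` from [post_pre_change()].
#' @param ... Unused.
#' @return The per-region change tibble.
#' @export
tidy.region_change <- function(x, ...) {
  x$regions
}

#' One-row summary of the region-change test
#'
#' @param x A `region_change`.
#' @param ... Unused.
#' @return A tibble with the Welch statistic, p-value, alpha and decision.
#' @export
glance.region_change <- function(x, ...) {
  if (is.null(x$test)) {
    return(tibble(statistic = NA_real_, p.value = NA_real_,
                  alpha = x$alpha, significant = NA))
  }
  tibble(statistic = unname(x$test$statistic),
         p.value = x$test$p.value,
         alpha = x$alpha, significant = x$significant)
}
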