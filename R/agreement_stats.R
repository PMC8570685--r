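# Method-agreement statistics for validating automated against manual
# scoring: Bland-Altman bias with 95% limits of agreement, and Pearson
# correlation.

#' Bland-Altman agreement
#'
#' Differences are `automatic - manual`; bias is their mean and the 95%
#' limits of agreement are `bias +/- 1.96 * SD` with the sample (n-1) SD.
#'
#' @param auto,manual Equal-length numeric vectors (n >= 2), one value per
#'   video (e.g. percent time immobile).
#' @return A `bland_altman` tibble of per-pair rows (`mean_pair`, `diff`),
#'   with attributes `bias`, `loa_low`, `loa_high`, `n`; [glance()] returns
#'   them as a one-row tibble.
#' @examples
#' glance(bland_altman(c(12, 18, 33), c(10, 20, 30)))
#' @export
bland_altman <- function(auto, manual) {
  check_paired(auto, manual, min_n = 2)
  d <- auto - manual
  bias <- mean(d)
  s <- sd(d)
  structure(
    tibble(mean_pair = (auto + manual) / 2, diff = d),
    bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
    n = length(d),
    class = c("bland_altman", class(tibble()))
  )
}

#' @rdname bland_altman
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble(
    bias = attr(x, "bias"),
    loa_low = attr(x, "loa_low"),
    loa_high = attr(x, "loa_high"),
    n = attr(x, "n")
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "<bland_altman> n = %d, bias = %.4g, 95%% limits of agreement [%.4g, %.4g]\n",
    attr(x, "n"), attr(x, "bias"), attr(x, "loa_low"), attr(x, "loa_high")
  ))
  NextMethod()
}

#' Pearson correlation between automated and manual values
#'
#' Product-moment correlation with a two-sided p-value from the t transform
#' on n - 2 degrees of freedom.
#'
#' @param auto,manual Equal-length numeric vectors (n >= 3) with non-zero
#'   variance.
#' @return A one-row tibble: `r`, `r_squared`, `p_value`, `n`.
#' @export
pearson_agreement <- function(auto, manual) {
  check_paired(auto, manual, min_n = 3)
  if (sd(auto) == 0 || sd(manual) == 0) {
    stop_immobilitr("correlation undefined: an input has zero variance",
      class = "immobilitr_error_zero_variance"
    )
  }
  ct <- stats::cor.test(auto, manual, method = "pearson")
  r <- unname(ct$estimate)
  tibble(r = r, r_squared = r^2, p_value = ct$p.value, n = length(auto))
}

#' Full agreement report
#'
#' @inheritParams pearson_agreement
#' @return A one-row tibble combining [bland_altman()] and
#'   [pearson_agreement()] fields.
#' @export
agreement_report <- function(auto, manual) {
  dplyr::bind_cols(
    glance(bland_altman(auto, manual))[, c("bias", "loa_low", "loa_high")],
    pearson_agreement(auto, manual)
  )
}

check_paired <- function(auto, manual, min_n) {
  if (length(auto) != length(manual)) {
    stop_immobilitr("auto and manual must have the same length",
      class = "immobilitr_error_length_mismatch"
    )
  }
  if (length(auto) < min_n || anyNA(auto) || anyNA(manual)) {
    stop_immobilitr(
      sprintf("need at least %d complete pairs", min_n),
      class = "immobilitr_error_too_few"
    )
  }
  invisible(TRUE)
}
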