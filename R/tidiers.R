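#' Tidy an AIC-selected balance-feature association
#'
#' @param x An `rfpkm_assoc` from [fit_linear_and_log()].
#' @param ... Unused.
#' @return A one-row tibble with `feature`, `transform`, `r`, `p`,
#'   `ci_low`, `ci_high`, `t`, `df`, `aic_linear`, `aic_log`, `n`,
#'   `computable`.
#' @export
tidy.rfpkm_assoc <- function(x, ...) {
  tibble::new_tibble(list(
    feature = x$feature,
    transform = x$transform,
    r = x$test$r, p = x$test$p,
    ci_low = x$test$ci_low, ci_high = x$test$ci_high,
    t = x$test$t, df = x$test$df,
    aic_linear = x$aic_linear, aic_log = x$aic_log,
    n = x$n, computable = x$test$computable
  ), nrow = 1L)
}

#' One-line model summary of a balance-feature association
#'
#' @inheritParams tidy.rfpkm_assoc
#' @return A one-row tibble with the chosen transform, both AICs and n.
#' @export
glance.rfpkm_assoc <- function(x, ...) {
  tibble::tibble(
    transform = x$transform,
    aic_linear = x$aic_linear,
    aic_log = x$aic_log,
    delta_aic = x$aic_log - x$aic_linear,
    n = x$n
  )
}
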