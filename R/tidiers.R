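#' Tidy a divergence-UCR correlation
#'
#' @param x A `div_ucr_cor` object.
#' @param ... Unused.
#' @return One-row tibble with `estimate`, `p.value`, `df`, `n_bins`,
#'   `degenerate`.
#' @export
tidy.div_ucr_cor <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, p.value = x$p.value,
                 df = x$df, n_bins = x$n_bins, degenerate = x$degenerate)
}

#' @rdname tidy.div_ucr_cor
#' @export
glance.div_ucr_cor <- function(x, ...) tidy(x, ...)

#' Tidy a correction account
#'
#' @param x A `correction_account` object.
#' @param ... Unused.
#' @return Long tibble with `type`, `fate`, `n`.
#' @export
tidy.correction_account <- function(x, ...) {
  tidyr::pivot_longer(x$summary, c("removed", "retained", "introduced"),
                      names_to = "fate", values_to = "n")
}

#' @rdname tidy.correction_account
#' @return For `glance()`: one-row tibble with totals, the removed fraction
#'   of raw errors, and the introduced-error rate per template base.
#' @export
glance.correction_account <- function(x, ...) {
  removed <- sum(x$summary$removed)
  retained <- sum(x$summary$retained)
  introduced <- sum(x$summary$introduced)
  tibble::tibble(
    n_reads = x$n_reads, template_bases = x$template_bases,
    raw_errors = x$raw_error_count, removed = removed, retained = retained,
    introduced = introduced,
    removed_fraction = if (removed + retained > 0)
      removed / (removed + retained) else NA_real_,
    introduced_rate = introduced / x$template_bases)
}
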