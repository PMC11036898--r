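#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a candidate model fit
#'
#' One row per coefficient with Wald-type statistics.
#'
#' @param x An `mb_model_fit` from [fit_candidate_models()].
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.mb_model_fit <- function(x, ...) {
  stat <- x$coefficients / x$se
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(x$se),
                 statistic = unname(stat),
                 p.value = 2 * stats::pnorm(-abs(unname(stat))))
}

#' One-row summary of a candidate model fit
#'
#' @param x An `mb_model_fit`.
#' @param ... Unused.
#' @return A tibble: `model`, `logLik`, `AIC`, `nobs.params`, `converged`.
#' @export
glance.mb_model_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logLik = x$loglik, AIC = x$aic,
                 n_params = x$n_params, converged = x$converged)
}

#' Tidy a PERMANOVA table
#'
#' @param x An `mb_permanova` from [permanova()].
#' @param ... Unused.
#' @return The underlying tibble with broom-style names.
#' @export
tidy.mb_permanova <- function(x, ...) {
  tibble::as_tibble(x) %>%
    dplyr::rename(statistic = "pseudo_f", p.value = "p")
}

#' One-row PERMANOVA summary (first term)
#'
#' @param x An `mb_permanova`.
#' @param ... Unused.
#' @return A tibble: `term`, `r.squared`, `statistic`, `p.value`,
#'   `n_permutations`.
#' @export
glance.mb_permanova <- function(x, ...) {
  first <- x[1, ]
  tibble::tibble(term = first$term, r.squared = first$r2,
                 statistic = first$pseudo_f, p.value = first$p,
                 n_permutations = first$n_permutations)
}

#' @export
print.mb_permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS, ", x$n_permutations[1], " permutations)\n",
      sep = "")
  NextMethod()
}
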