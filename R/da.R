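#' Fit the four candidate per-ASV count models
#'
#' Fits a gaussian (identity-link, no offset), a Poisson (log link, library
#' -size offset), a negative binomial (log link, offset, dispersion by
#' maximum likelihood) and a zero-inflated negative binomial (NB count part
#' with offset plus an intercept-only logit zero part, fit by
#' expectation-maximization) to the SAME raw count response, so their AIC
#' values are directly comparable. AIC is `-2 loglik + 2 k` with `k`
#' counting every estimated quantity: `p + 1` for gaussian (residual
#' variance), `p` for Poisson, `p + 1` for NB (dispersion), `p + 2` for
#' ZINB (dispersion and zero-inflation intercept). Fits that fail to
#' converge are flagged and excluded from AIC selection.
#'
#' @param y Non-negative integer counts, one per sample.
#' @param X Design matrix (including intercept; group plus covariates).
#' @param offset Per-sample log library size for the count models.
#' @return A list of `mb_model_fit` objects (model, coefficients, se,
#'   loglik, n_params, aic, converged), one per candidate.
#' @export
fit_candidate_models <- function(y, X, offset = rep(0, length(y))) {
  stopifnot(length(y) == nrow(X), all(y >= 0), all(y == round(y)))
  if (all(y == 0)) stop("degenerate response: all counts zero", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient", call. = FALSE)
  list(
    gaussian = fit_gaussian(y, X),
    poisson = fit_poisson(y, X, offset),
    negbin = fit_negbin(y, X, offset),
    zinb = fit_zinb(y, X, offset)
  )
}

new_model_fit <- function(model, coefficients, se, loglik, n_params, converged,
                          extra = list()) {
  structure(c(list(model = model, coefficients = coefficients, se = se,
                   loglik = loglik, n_params = n_params,
                   aic = -2 * loglik + 2 * n_params, converged = converged),
              extra),
            class = "mb_model_fit")
}

fit_gaussian <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  n <- length(y)
  p <- ncol(X)
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  ll <- -n / 2 * (log(2 * pi * sigma2_ml) + 1)
  se <- sqrt(diag(chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])) *
               rss / (n - p))
  names(se) <- colnames(X)
  new_model_fit("gaussian", stats::setNames(fit$coefficients, colnames(X)), se,
                ll, p + 1, TRUE, list(df_residual = n - p))
}

fit_poisson <- function(y, X, offset) {
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offset)
  )
  mu <- fit$fitted.values
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  p <- ncol(X)
  R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
  se <- sqrt(diag(chol2inv(R)))
  names(se) <- colnames(X)
  new_model_fit("poisson", stats::setNames(fit$coefficients, colnames(X)), se,
                ll, p, fit$converged && all(is.finite(fit$coefficients)))
}

fit_negbin <- function(y, X, offset) {
  ok <- TRUE
  fit <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(y ~ 0 + X + offset(offset)),
      warning = function(w) {
        if (grepl("iteration limit|alternation", conditionMessage(w))) ok <<- FALSE
        invokeRestart("muffleWarning")
      }),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_model_fit("negbin", stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                         stats::setNames(rep(NA_real_, ncol(X)), colnames(X)),
                         -Inf, ncol(X) + 1, FALSE))
  }
  cf <- stats::setNames(stats::coef(fit), colnames(X))
  se <- stats::setNames(sqrt(diag(stats::vcov(fit))), colnames(X))
  new_model_fit("negbin", cf, se, fit$twologlik / 2, ncol(X) + 1,
                ok && fit$converged,
                list(theta = fit$theta))
}

zinb_loglik <- function(y, mu, theta, pi0) {
  is0 <- y == 0
  ll0 <- log(pi0 + (1 - pi0) * stats::dnbinom(0, mu = mu[is0], size = theta))
  llpos <- log(1 - pi0) + stats::dnbinom(y[!is0], mu = mu[!is0], size = theta,
                                         log = TRUE)
  sum(ll0) + sum(llpos)
}

# EM for ZINB: NB count model with offset + intercept-only structural-zero part.
# The M-step interleaves a few IRLS steps for the count coefficients with a
# guarded Newton step for log(theta); iterated to the joint optimum through
# the EM loop (generalized EM), monitored on the observed-data log-likelihood.
fit_zinb <- function(y, X, offset, tol = 1e-8, max_iter = 500) {
  p <- ncol(X)
  na_fit <- function() new_model_fit(
    "zinb", stats::setNames(rep(NA_real_, p), colnames(X)),
    stats::setNames(rep(NA_real_, p), colnames(X)), -Inf, p + 2, FALSE)
  if (!any(y == 0)) {
    # no zeros: zero part unidentifiable; count part equals the NB fit, pi -> 0
    nb <- fit_negbin(y, X, offset)
    if (!nb$converged) return(na_fit())
    return(new_model_fit("zinb", nb$coefficients, nb$se,
                         nb$loglik, p + 2, TRUE,
                         list(theta = nb$theta, pi0 = 0)))
  }
  # cheap Poisson start
  g0 <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, family = stats::poisson(), offset = offset)),
    error = function(e) NULL)
  beta <- if (!is.null(g0) && all(is.finite(g0$coefficients))) g0$coefficients else
    c(log(mean(y) + 0.5) - mean(offset), rep(0, p - 1))
  theta <- 1
  pi0 <- max(0.01, min(0.9, mean(y == 0) / 2))
  eta <- pmin(drop(X %*% beta) + offset, 30)
  mu <- exp(eta)
  ll <- zinb_loglik(y, mu, theta, pi0)
  is0 <- y == 0
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step: posterior probability of a structural zero
    z <- numeric(length(y))
    p_nb0 <- stats::dnbinom(0, mu = mu[is0], size = theta)
    z[is0] <- pi0 / (pi0 + (1 - pi0) * p_nb0)
    pi0 <- min(max(mean(z), 1e-8), 1 - 1e-8)
    w <- 1 - z
    # M-step, count part: weighted NB IRLS steps for beta ...
    for (inner in 1:3) {
      vr <- mu + mu^2 / theta
      wi <- w * mu^2 / vr
      zr <- eta - offset + (y - mu) / mu
      beta <- tryCatch(
        qr.coef(qr(X * sqrt(wi)), sqrt(wi) * zr),
        error = function(e) rep(NA_real_, p))
      if (!all(is.finite(beta))) return(na_fit())
      eta <- pmin(drop(X %*% beta) + offset, 30)
      mu <- exp(eta)
    }
    # ... and one guarded Newton step for u = log(theta)
    dth <- sum(w * (digamma(y + theta) - digamma(theta) + log(theta) + 1 -
                      log(theta + mu) - (y + theta) / (theta + mu)))
    d2th <- sum(w * (trigamma(y + theta) - trigamma(theta) + 1 / theta -
                       2 / (theta + mu) + (y + theta) / (theta + mu)^2))
    du <- theta * dth
    d2u <- theta^2 * d2th + theta * dth
    if (is.finite(du) && is.finite(d2u) && d2u < 0) {
      step <- min(max(-du / d2u, -1), 1)    # damped step on log scale
      theta <- exp(log(theta) + step)
    }
    theta <- min(max(theta, 1e-3), 1e6)
    ll_new <- zinb_loglik(y, mu, theta, pi0)
    if (!is.finite(ll_new)) return(na_fit())
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  se <- zinb_se(y, X, offset, beta, theta, pi0)
  new_model_fit("zinb", stats::setNames(beta, colnames(X)),
                stats::setNames(se, colnames(X)), ll, p + 2, converged,
                list(theta = theta, pi0 = pi0))
}

# standard errors from a numeric Hessian of the full ZINB log-likelihood
zinb_se <- function(y, X, offset, beta, theta, pi0) {
  p <- length(beta)
  par <- c(beta, log(theta), stats::qlogis(min(max(pi0, 1e-8), 1 - 1e-8)))
  nll <- function(par) {
    mu <- exp(drop(X %*% par[seq_len(p)]) + offset)
    -zinb_loglik(y, mu, exp(par[p + 1]), stats::plogis(par[p + 2]))
  }
  se <- tryCatch({
    H <- stats::optimHess(par, nll)
    V <- solve(H)
    sqrt(pmax(diag(V)[seq_len(p)], 0))
  }, error = function(e) rep(NA_real_, p))
  se
}

#' Select the best candidate model by AIC
#'
#' Converged fit with minimal AIC; ties broken by fewer parameters, then by
#' the fixed order poisson, negbin, zinb, gaussian.
#'
#' @param fits List of `mb_model_fit` objects from [fit_candidate_models()].
#' @return The winning `mb_model_fit`.
#' @export
select_model <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$aic), fits)
  if (!length(fits)) stop("no converged candidate fit", call. = FALSE)
  order_pref <- c(poisson = 1, negbin = 2, zinb = 3, gaussian = 4)
  aic <- vapply(fits, `[[`, numeric(1), "aic")
  k <- vapply(fits, `[[`, numeric(1), "n_params")
  pref <- order_pref[vapply(fits, `[[`, character(1), "model")]
  fits[[order(aic, k, pref)[1]]]
}

#' Multi-model differential abundance
#'
#' For every ASV in an (already prevalence-filtered) count table, fits the
#' four candidate models with [fit_candidate_models()], selects by AIC, and
#' reports the two-sided Wald p-value for the EIM-vs-control group
#' coefficient of the winning model. The log2 fold change is the group
#' coefficient divided by `ln 2` for the log-link models, and
#' `log2((mean_EIM + 0.5) / (mean_C + 0.5))` for the gaussian model;
#' `mean_diff` is the difference of raw group mean counts. p-values are
#' BH-adjusted across all tested ASVs. ASVs whose candidates all fail are
#' collected in the `skipped` attribute rather than aborting the run.
#'
#' @param counts Prevalence-filtered sample-by-ASV count matrix.
#' @param meta Metadata with `sample_id`, `group` (`"EIM"`/`"C"`) and any
#'   covariate columns.
#' @param covariates Character vector of metadata columns to adjust for
#'   (e.g. disease subtype, IBD surgery).
#' @return A tibble of class `mb_da`: `asv_id`, `chosen_model`, `log2_fc`,
#'   `mean_diff`, `p`, `q`, sorted by `q`.
#' @export
differential_abundance <- function(counts, meta, covariates = character()) {
  counts <- as_count_matrix(counts)
  meta <- as.data.frame(meta)
  meta <- meta[match(rownames(counts), meta$sample_id), , drop = FALSE]
  miss <- setdiff(c("group", covariates), names(meta))
  if (length(miss)) {
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  meta$group <- factor(meta$group, levels = c("C", "EIM"))
  rhs <- paste(c("group", covariates), collapse = " + ")
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = meta)
  offset <- log(rowSums(counts))
  is_eim <- meta$group == "EIM"

  rows <- vector("list", ncol(counts))
  skipped <- character(0)
  for (j in seq_len(ncol(counts))) {
    y <- counts[, j]
    rec <- tryCatch({
      fit <- select_model(fit_candidate_models(y, X, offset))
      cf <- fit$coefficients["groupEIM"]
      se <- fit$se["groupEIM"]
      m_eim <- mean(y[is_eim])
      m_c <- mean(y[!is_eim])
      if (fit$model == "gaussian") {
        pval <- 2 * stats::pt(-abs(cf / se), df = fit$df_residual)
        lfc <- log2((m_eim + 0.5) / (m_c + 0.5))
      } else {
        pval <- 2 * stats::pnorm(-abs(cf / se))
        lfc <- cf / log(2)
      }
      tibble::tibble(asv_id = colnames(counts)[j], chosen_model = fit$model,
                     log2_fc = unname(lfc), mean_diff = m_eim - m_c,
                     p = unname(pval))
    }, error = function(e) NULL)
    if (is.null(rec)) skipped <- c(skipped, colnames(counts)[j]) else rows[[j]] <- rec
  }
  out <- dplyr::bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out <- dplyr::arrange(out, .data$q, .data$p)
  attr(out, "skipped") <- skipped
  class(out) <- c("mb_da", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return FDR-adjusted q-values in input order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Significance and effect-size filter for DA records
#'
#' Keeps records with `q < q_threshold` and `|log2_fc| > lfc_threshold`
#' (defaults: FDR 0.05 and a log2 fold change of 1).
#'
#' @param records Tibble from [differential_abundance()].
#' @param q_threshold,lfc_threshold Cutoffs.
#' @return The filtered tibble.
#' @export
effect_filter <- function(records, q_threshold = 0.05, lfc_threshold = 1) {
  dplyr::filter(records, .data$q < q_threshold, abs(.data$log2_fc) > lfc_threshold)
}
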