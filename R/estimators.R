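# Univariable two-sample MR estimators. All take harmonized instruments: a
# data frame with beta_x, se_x, beta_y, se_y (output of harmonize(), kept
# rows only; dropped rows are discarded here defensively).

prepare_instruments <- function(h, min_n = 1L) {
  if (!is.null(h$action)) h <- h[!startsWith(h$action, "dropped"), ]
  h <- h[stats::complete.cases(h[, c("beta_x", "beta_y", "se_y")]), ]
  if (nrow(h) < min_n) {
    stop("need at least ", min_n, " harmonized instruments, got ", nrow(h),
         call. = FALSE)
  }
  if (any(h$beta_x == 0)) {
    stop("degenerate instrument with zero exposure effect", call. = FALSE)
  }
  h
}

mr_estimate <- function(method, beta, se, pval, n_snps, Q = NA_real_,
                        Q_pval = NA_real_, I2 = NA_real_, H = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_pval = NA_real_) {
  structure(list(
    method = method, beta = beta, se = se, pval = pval,
    odds_ratio = exp(beta), or_lci95 = exp(beta - stats::qnorm(0.975) * se),
    or_uci95 = exp(beta + stats::qnorm(0.975) * se),
    n_snps = n_snps, Q = Q, Q_pval = Q_pval, I2 = I2, H = H,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_pval = egger_intercept_pval
  ), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "<mr_estimate> %s: beta = %.4f (se %.4f), OR = %.3f, p = %.3g, nsnp = %d\n",
    x$method, x$beta, x$se, x$odds_ratio, x$pval, x$n_snps))
  if (!is.na(x$Q)) {
    cat(sprintf("  heterogeneity: Q = %.3f (p = %.3g), I2 = %.3f, H = %.3f\n",
                x$Q, x$Q_pval, x$I2, x$H))
  }
  if (x$method == "egger") {
    cat(sprintf("  intercept = %.4f (p = %.3g)\n", x$egger_intercept,
                x$egger_intercept_pval))
  }
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' The main causal estimator: the weighted mean of per-SNP Wald ratios
#' `b_j = beta_y_j / beta_x_j` with weights `w_j = (beta_x_j / se_y_j)^2`
#' (the reciprocal of the first-order ratio variance). The fixed-effects
#' standard error is `(sum w_j)^(-1/2)`; under the multiplicative
#' random-effects model it is inflated by `max(1, sqrt(Q / (n - 1)))`, so it
#' is never deflated below the fixed-effects value. The p-value uses the
#' normal reference.
#'
#' @param h harmonized instruments (see [harmonize()]); at least one SNP,
#'   all exposure effects non-zero.
#' @param effects_model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate` with heterogeneity statistics when `n >= 2`.
#' @export
mr_ivw <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  h <- prepare_instruments(h, min_n = 1L)
  b <- h$beta_y / h$beta_x
  w <- (h$beta_x / h$se_y)^2
  beta <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  n <- nrow(h)
  het <- heterogeneity(h, beta)
  if (effects_model == "multiplicative_random" && n >= 2L) {
    se <- se * max(1, sqrt(het[["Q"]] / (n - 1)))
  }
  pval <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("ivw", beta, se, pval, n, Q = het[["Q"]],
              Q_pval = het[["Q_pval"]], I2 = het[["I2"]], H = het[["H"]])
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with an intercept, weights `1/se_y^2`, after orienting every instrument
#' so its exposure effect is positive. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy. Standard errors use
#' the same multiplicative random-effects inflation as [mr_ivw()] (factor
#' `max(1, sqrt(Q_resid / (n - 2)))`); p-values use the t reference with
#' `n - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An `mr_estimate` with intercept fields; the `Q` reported is the
#'   residual heterogeneity about the Egger fit.
#' @export
mr_egger <- function(h, effects_model = c("multiplicative_random", "fixed")) {
  effects_model <- match.arg(effects_model)
  h <- prepare_instruments(h, min_n = 3L)
  n <- nrow(h)
  # Orientation: flip (beta_x, beta_y) pairs so all exposure effects > 0.
  flip <- sign(h$beta_x)
  x <- h$beta_x * flip
  y <- h$beta_y * flip
  w <- 1 / h$se_y^2

  X <- cbind(intercept = 1, slope = x)
  XtW <- t(X * w)
  XtWX_inv <- solve(XtW %*% X)
  coefs <- drop(XtWX_inv %*% (XtW %*% y))
  resid <- y - drop(X %*% coefs)
  Q <- sum(w * resid^2)
  scale <- if (effects_model == "multiplicative_random") {
    max(1, sqrt(Q / (n - 2)))
  } else 1
  ses <- sqrt(diag(XtWX_inv)) * scale
  pvals <- 2 * stats::pt(-abs(coefs / ses), df = n - 2)

  mr_estimate("egger", coefs[["slope"]], ses[["slope"]], pvals[["slope"]],
              n, Q = Q, Q_pval = stats::pchisq(Q, n - 2, lower.tail = FALSE),
              I2 = max(0, (Q - (n - 2)) / Q), H = sqrt(Q / (n - 2)),
              egger_intercept = coefs[["intercept"]],
              egger_intercept_se = ses[["intercept"]],
              egger_intercept_pval = pvals[["intercept"]])
}

# Weighted median of values `b` with weights `w`: interpolate the inverse of
# the standardized cumulative weight function at 0.5, placing each sorted
# value at the midpoint of its weight mass.
weighted_median_point <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(b[1])
  if (0.5 >= cum[length(cum)]) return(b[length(b)])
  below <- max(which(cum < 0.5))
  b[below] + (b[below + 1] - b[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median estimator
#'
#' The weighted median of per-SNP Wald ratios, weights proportional to the
#' inverse first-order ratio variance `beta_x^2 / se_y^2`. Consistent when
#' at least half of the total weight comes from valid instruments. The
#' standard error comes from a seeded parametric bootstrap: exposure and
#' outcome effects are resampled from normal distributions centred on their
#' estimates with their reported standard errors.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (mandatory, for
#'   reproducibility of the stochastic standard error).
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed) {
  if (missing(seed)) stop("weighted-median bootstrap requires a seed",
                          call. = FALSE)
  h <- prepare_instruments(h, min_n = 3L)
  b <- h$beta_y / h$beta_x
  w <- (h$beta_x / h$se_y)^2
  beta <- weighted_median_point(b, w)

  se_x <- if (all(is.finite(h$se_x))) h$se_x else rep(0, nrow(h))
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(h), h$beta_x, se_x)
      by <- stats::rnorm(nrow(h), h$beta_y, h$se_y)
      bad <- bx == 0
      if (any(bad)) bx[bad] <- h$beta_x[bad]
      weighted_median_point(by / bx, (bx / h$se_y)^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pval <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  het <- heterogeneity(h, beta)
  mr_estimate("weighted_median", beta, se, pval, nrow(h), Q = het[["Q"]],
              Q_pval = het[["Q_pval"]], I2 = het[["I2"]], H = het[["H"]])
}

# Evaluate `expr` under a local RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Heterogeneity statistics across per-SNP causal estimates
#'
#' Cochran's `Q = sum w_j (b_j - beta_hat)^2` over Wald ratios `b_j` with
#' inverse-variance weights `w_j = (beta_x_j/se_y_j)^2`; its p-value from the
#' chi-square reference with `n - 1` degrees of freedom;
#' `I2 = max(0, (Q - (n-1))/Q)`; `H = sqrt(Q / (n-1))`.
#'
#' @param h harmonized instruments.
#' @param beta_hat pooled causal estimate the ratios are contrasted with.
#' @return Named numeric vector `(Q, Q_pval, I2, H)`; all `NA` when fewer
#'   than two instruments.
#' @export
heterogeneity <- function(h, beta_hat) {
  if (!is.null(h$action)) h <- h[!startsWith(h$action, "dropped"), ]
  n <- nrow(h)
  if (n < 2L) {
    return(c(Q = NA_real_, Q_pval = NA_real_, I2 = NA_real_, H = NA_real_))
  }
  b <- h$beta_y / h$beta_x
  w <- (h$beta_x / h$se_y)^2
  Q <- sum(w * (b - beta_hat)^2)
  c(Q = Q,
    Q_pval = stats::pchisq(Q, df = n - 1, lower.tail = FALSE),
    I2 = max(0, (Q - (n - 1)) / Q),
    H = sqrt(Q / (n - 1)))
}

#' Run all univariable estimators on one instrument set
#'
#' @param h harmonized instruments.
#' @param n_boot,seed weighted-median bootstrap settings.
#' @param effects_model passed to [mr_ivw()] and [mr_egger()].
#' @return A tidy data frame, one row per method (`ivw` always; `egger` and
#'   `weighted_median` when at least three instruments are available), with
#'   columns `method`, `nsnp`, `beta`, `se`, `pval`, `or`, `or_lci95`,
#'   `or_uci95`, `Q`, `Q_pval`, `I2`, `H`, `egger_intercept`,
#'   `egger_intercept_pval`.
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = 1,
                           effects_model = "multiplicative_random") {
  hk <- prepare_instruments(h, min_n = 1L)
  ests <- list(mr_ivw(hk, effects_model = effects_model))
  if (nrow(hk) >= 3L) {
    ests <- c(ests, list(mr_egger(hk, effects_model = effects_model),
                         mr_weighted_median(hk, n_boot = n_boot, seed = seed)))
  }
  do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, nsnp = e$n_snps, beta = e$beta, se = e$se,
               pval = e$pval, or = e$odds_ratio, or_lci95 = e$or_lci95,
               or_uci95 = e$or_uci95, Q = e$Q, Q_pval = e$Q_pval, I2 = e$I2,
               H = e$H, egger_intercept = e$egger_intercept,
               egger_intercept_pval = e$egger_intercept_pval,
               stringsAsFactors = FALSE)
  }))
}
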