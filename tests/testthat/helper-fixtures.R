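# Shared fixtures and independent oracles for the test suite. Oracles use
# different code paths from the implementation on purpose.

# Minimal association set from parallel vectors.
make_assoc <- function(snp, beta, se, pval = NULL, ea = "A", oa = "G",
                       eaf = 0.3, chr = "1", pos = NULL, n = 1e5,
                       trait_id = "trait", category = "test", ...) {
  k <- length(snp)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(pos)) pos <- seq_len(k) * 3e7
  assoc_set(data.frame(snp = snp, chr = rep_len(chr, k),
                       pos = pos, ea = rep_len(ea, k), oa = rep_len(oa, k),
                       eaf = rep_len(eaf, k), beta = beta, se = se,
                       pval = pval, n = n, stringsAsFactors = FALSE),
            trait_id = trait_id, category = category, ...)
}

# Harmonized-instrument frame built directly (already aligned).
make_instruments <- function(beta_x, beta_y, se_y, se_x = 1e-6) {
  data.frame(snp = sprintf("rs%03d", seq_along(beta_x)),
             beta_x = beta_x, se_x = rep_len(se_x, length(beta_x)),
             beta_y = beta_y, se_y = se_y, stringsAsFactors = FALSE)
}

# Independent weighted-median oracle: invert the piecewise-linear cumulative
# weight function (knots at the sorted values, midpoint mass placement)
# with stats::approx instead of the implementation's index arithmetic.
oracle_weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(b[1])
  if (0.5 >= cum[length(cum)]) return(b[length(b)])
  stats::approx(cum, b, xout = 0.5, ties = "ordered")$y
}

# Independent marginal-likelihood oracle: evaluate the multivariate normal
# density of y under N(0, I + sigma^2 X_S X_S') by building the full m x m
# covariance (no Woodbury), dropping the same -m/2 log(2 pi) constant.
oracle_log_marginal <- function(y, X, S, sigma) {
  m <- length(y)
  V <- diag(m)
  if (length(S) > 0L) {
    Xs <- X[, S, drop = FALSE]
    V <- V + sigma^2 * Xs %*% t(Xs)
  }
  ch <- chol(V)
  z <- backsolve(ch, y, transpose = TRUE)
  -sum(log(diag(ch))) - 0.5 * sum(z^2)
}

# Brute-force model posteriors for small K: enumerate subsets with the
# oracle marginal likelihood and Bernoulli inclusion priors.
oracle_posteriors <- function(input, config) {
  y <- input$beta_y / input$se_y
  X <- input$beta_x / input$se_y
  s <- sqrt(colMeans(X^2)); s[s == 0] <- 1
  X <- sweep(X, 2, s, "/")
  K <- ncol(X)
  max_size <- if (is.null(config$max_model_size)) min(K, 12) else config$max_model_size
  subsets <- list(integer(0))
  for (size in seq_len(max_size)) {
    subsets <- c(subsets, utils::combn(K, size, simplify = FALSE))
  }
  lp <- vapply(subsets, function(S) {
    oracle_log_marginal(y, X, S, config$prior_sigma) +
      length(S) * log(config$prior_inclusion_prob) +
      (K - length(S)) * log(1 - config$prior_inclusion_prob)
  }, numeric(1))
  pp <- exp(lp - max(lp)); pp <- pp / sum(pp)
  # oracle MIP/MACE with per-model least-squares estimates
  mip <- mace <- numeric(K)
  for (i in seq_along(subsets)) {
    S <- subsets[[i]]
    if (length(S) == 0L) next
    est <- drop(solve(crossprod(X[, S, drop = FALSE]),
                      crossprod(X[, S, drop = FALSE], y))) / s[S]
    for (j in seq_along(S)) {
      mip[S[j]] <- mip[S[j]] + pp[i]
      mace[S[j]] <- mace[S[j]] + pp[i] * est[j]
    }
  }
  list(subsets = subsets, pp = pp, mip = mip, mace = mace)
}

# Small deterministic BMA inputs built directly on the summary scale.
make_bma_fixture <- function(m = 40, K = 3, theta = c(0.3, 0, 0), seed = 1,
                             rho = 0.5, se_y = 0.03) {
  set.seed(seed)
  X <- matrix(rnorm(m * K, 0, 0.1), m, K)
  # induce correlation between exposure columns via a shared component
  shared <- rnorm(m, 0, 0.1)
  X <- sqrt(1 - rho) * X + sqrt(rho) * matrix(shared, m, K)
  y <- drop(X %*% theta) + rnorm(m, 0, se_y)
  bma_input(sprintf("rs%03d", seq_len(m)), X, y, rep(se_y, m),
            exposure_ids = paste0("met_", seq_len(K)))
}

default_params <- function(seed = 1, n_boot = 200) {
  p <- study_params(seed = seed)
  p$estimators$n_boot <- n_boot
  p
}
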