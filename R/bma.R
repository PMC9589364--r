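# Bayesian model averaging multivariable MR over correlated exposures.
#
# Working scale: instruments are inverse-variance standardized, y_tilde_j =
# beta_y_j / se_y_j and X_tilde_jk = beta_x_jk / se_y_j, so the weighted
# multivariable regression of outcome on exposure associations (no
# intercept, weights 1/se_y^2) becomes ordinary regression with unit error
# variance. Exposure columns are then scaled to unit weighted root mean
# square so marginal inclusion probabilities are comparable across traits
# with different instrument strengths; estimates are back-transformed for
# reporting.

#' MR-BMA configuration
#'
#' @param prior_inclusion_prob prior probability that any one exposure has a
#'   direct causal effect (default 0.1).
#' @param prior_sigma prior standard deviation of a causal effect on the
#'   standardized scale (default 0.5).
#' @param max_model_size largest exposure subset considered; `NULL` (default)
#'   resolves to `min(K, 12)` at run time.
#' @param search `"exhaustive"` (all subsets; required for `K <= 20`) or
#'   `"stochastic"` (seeded shotgun search over the model space).
#' @param n_search_iter iterations of the stochastic search (default 1000).
#' @param pp_threshold posterior-probability cutoff for reporting best
#'   models and for influence diagnostics (default 0.02).
#' @param q_threshold per-SNP Cochran Q contribution above which an
#'   instrument is flagged as an outlier (default 10).
#' @param cooks_threshold Cook's distance cutoff, or `"auto"` for the median
#'   of the F distribution with `(|S|, m - |S|)` degrees of freedom.
#' @param n_permutations permutation replicates for empirical p-values
#'   (default 100).
#' @param seed integer seed for every stochastic component (mandatory).
#' @return A list of class `bma_config`.
#' @export
bma_config <- function(prior_inclusion_prob = 0.1, prior_sigma = 0.5,
                       max_model_size = NULL, search = c("exhaustive",
                                                         "stochastic"),
                       n_search_iter = 1000, pp_threshold = 0.02,
                       q_threshold = 10, cooks_threshold = "auto",
                       n_permutations = 100, seed = 1) {
  search <- match.arg(search)
  stopifnot(prior_inclusion_prob > 0, prior_inclusion_prob < 1,
            prior_sigma > 0, pp_threshold > 0, pp_threshold < 1,
            q_threshold > 0, n_permutations >= 1)
  structure(list(
    prior_inclusion_prob = prior_inclusion_prob, prior_sigma = prior_sigma,
    max_model_size = max_model_size, search = search,
    n_search_iter = n_search_iter, pp_threshold = pp_threshold,
    q_threshold = q_threshold, cooks_threshold = cooks_threshold,
    n_permutations = n_permutations, seed = as.integer(seed)
  ), class = "bma_config")
}

#' Construct an MR-BMA input
#'
#' @param snp_ids character vector of m instrument ids.
#' @param beta_x m x K matrix of exposure associations (columns named by
#'   exposure id).
#' @param beta_y,se_y outcome associations and standard errors (length m).
#' @param exposure_ids optional column names for `beta_x`.
#' @return A list of class `bma_input`.
#' @export
bma_input <- function(snp_ids, beta_x, beta_y, se_y, exposure_ids = NULL) {
  beta_x <- as.matrix(beta_x)
  if (!is.null(exposure_ids)) colnames(beta_x) <- exposure_ids
  if (is.null(colnames(beta_x))) {
    colnames(beta_x) <- paste0("exposure_", seq_len(ncol(beta_x)))
  }
  stopifnot(length(snp_ids) == nrow(beta_x),
            length(beta_y) == nrow(beta_x),
            length(se_y) == nrow(beta_x), all(se_y > 0))
  structure(list(snp_ids = as.character(snp_ids), beta_x = beta_x,
                 beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                 exposure_ids = colnames(beta_x)),
            class = "bma_input")
}

#' Assemble the MR-BMA input from univariable screen results
#'
#' Exposures with an IVW p-value below `include_p` (against the given
#' outcome) enter the model. Their instruments are pooled and the union is
#' strictly re-clumped (r2 < `r2_threshold` within `window_kb`), using each
#' SNP's minimum p-value across the included exposures to order the greedy
#' pass. Exposure and outcome effects at the retained SNPs are aligned to a
#' common effect allele; an exposure with no measured association at a
#' retained SNP contributes 0 to its column (logged), or the SNP is dropped
#' under `missing_mode = "drop_incomplete"`.
#'
#' @param univariable tidy screen results (columns `trait_id`, `method`,
#'   `pval`) for the outcome of interest, e.g. from
#'   [run_univariable_screen()] filtered to one outcome; `NULL` includes
#'   every exposure.
#' @param exposures named list of [assoc_set()] objects.
#' @param outcome an [assoc_set()].
#' @param ld an [ld_matrix()] or `NULL`.
#' @param include_p IVW p-value filter for exposure inclusion (default 0.05).
#' @param p_threshold,r2_threshold,window_kb,f_threshold instrument selection
#'   parameters (see [select_instruments()]).
#' @param missing_mode `"impute_zero"` (default) or `"drop_incomplete"`.
#' @param palindrome_policy,eaf_window passed to the allele aligner.
#' @return A `bma_input`, with attributes `n_imputed_zero` (count of
#'   imputed exposure cells) and `included_exposures`; `NULL` with a warning
#'   when fewer than two exposures qualify.
#' @export
build_bma_input <- function(univariable, exposures, outcome, ld = NULL,
                            include_p = 0.05, p_threshold = 5e-8,
                            r2_threshold = 0.001, window_kb = 10000,
                            f_threshold = 10,
                            missing_mode = c("impute_zero",
                                             "drop_incomplete"),
                            palindrome_policy = "infer_by_eaf",
                            eaf_window = 0.08) {
  missing_mode <- match.arg(missing_mode)
  ids <- names(exposures)
  if (is.null(ids)) {
    ids <- vapply(exposures, attr, "", "trait_id")
    names(exposures) <- ids
  }
  if (!is.null(univariable)) {
    ivw <- univariable[univariable$method == "ivw", , drop = FALSE]
    pass <- ivw$trait_id[!is.na(ivw$pval) & ivw$pval < include_p]
    ids <- ids[ids %in% pass]
  }
  if (length(ids) < 2L) {
    warning("fewer than two exposures pass the inclusion filter; ",
            "MR-BMA stage skipped")
    return(NULL)
  }
  exposures <- exposures[ids]

  sets <- lapply(exposures, select_instruments, ld = ld,
                 p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb, f_threshold = f_threshold)
  pool <- unique(unlist(lapply(sets, function(s) s$instruments$snp)))
  if (length(pool) == 0L) {
    warning("no instruments across included exposures; MR-BMA stage skipped")
    return(NULL)
  }

  # Per-SNP metadata and minimum exposure p across included traits, for the
  # greedy re-clump of the combined set.
  min_p <- rep(Inf, length(pool))
  meta <- data.frame(snp = pool, chr = NA_character_, pos = NA_real_,
                     ea = NA_character_, oa = NA_character_,
                     eaf = NA_real_, stringsAsFactors = FALSE)
  for (ex in exposures) {
    idx <- match(ex$snp, pool)
    hit <- !is.na(idx)
    min_p[idx[hit]] <- pmin(min_p[idx[hit]], ex$pval[hit])
    fill <- hit & is.na(meta$ea[idx])
    meta[idx[fill], c("chr", "ea", "oa")] <-
      data.frame(ex$chr[fill], ex$ea[fill], ex$oa[fill],
                 stringsAsFactors = FALSE)
    meta$pos[idx[fill]] <- ex$pos[fill]
    meta$eaf[idx[fill]] <- ex$eaf[fill]
  }
  meta$pval <- min_p
  cl <- ld_clump(meta, ld, r2_threshold = r2_threshold,
                 window_kb = window_kb)
  meta <- meta[match(sort(cl$kept), meta$snp), , drop = FALSE]

  # Outcome alignment to the reference (first-seen exposure) alleles; SNPs
  # the outcome cannot be aligned at are unusable.
  oidx <- match(meta$snp, outcome$snp)
  keep <- !is.na(oidx)
  beta_y <- se_y <- rep(NA_real_, nrow(meta))
  for (i in which(keep)) {
    j <- oidx[i]
    a <- align_alleles(meta$ea[i], meta$oa[i], outcome$ea[j], outcome$oa[j],
                       meta$eaf[i], outcome$eaf[j],
                       palindrome_policy, eaf_window)
    if (startsWith(a$action, "dropped")) {
      keep[i] <- FALSE
    } else {
      beta_y[i] <- if (a$flip) -outcome$beta[j] else outcome$beta[j]
      se_y[i] <- outcome$se[j]
    }
  }
  meta <- meta[keep, , drop = FALSE]
  beta_y <- beta_y[keep]
  se_y <- se_y[keep]

  m <- nrow(meta)
  K <- length(exposures)
  bx <- matrix(0, m, K, dimnames = list(meta$snp, ids))
  present <- matrix(FALSE, m, K)
  for (k in seq_len(K)) {
    ex <- exposures[[k]]
    eidx <- match(meta$snp, ex$snp)
    for (i in which(!is.na(eidx))) {
      j <- eidx[i]
      a <- align_alleles(meta$ea[i], meta$oa[i], ex$ea[j], ex$oa[j],
                         meta$eaf[i], ex$eaf[j], palindrome_policy,
                         eaf_window)
      if (!startsWith(a$action, "dropped")) {
        bx[i, k] <- if (a$flip) -ex$beta[j] else ex$beta[j]
        present[i, k] <- TRUE
      }
    }
  }
  n_imputed <- sum(!present)
  if (missing_mode == "drop_incomplete") {
    complete <- rowSums(present) == K
    meta <- meta[complete, , drop = FALSE]
    bx <- bx[complete, , drop = FALSE]
    beta_y <- beta_y[complete]
    se_y <- se_y[complete]
    n_imputed <- 0L
  }
  if (nrow(meta) == 0L) {
    warning("no usable instruments after alignment; MR-BMA stage skipped")
    return(NULL)
  }
  out <- bma_input(meta$snp, bx, beta_y, se_y)
  attr(out, "n_imputed_zero") <- n_imputed
  attr(out, "included_exposures") <- ids
  out
}

# Standardized working matrices: y (unit error variance) and column-scaled
# design, with the scales needed to back-transform estimates.
bma_working <- function(input) {
  y <- input$beta_y / input$se_y
  X <- input$beta_x / input$se_y
  s <- sqrt(colMeans(X^2))
  s[s == 0 | !is.finite(s)] <- 1
  list(y = y, X = sweep(X, 2, s, "/"), scale = s)
}

# Log marginal likelihood of subset `S` (integer indices; possibly empty)
# under y ~ N(0, I + sigma^2 X_S X_S'), via the Woodbury identity. The
# common constant -m/2 log(2 pi) is dropped. Singular inner systems get
# -Inf.
log_marginal <- function(y, X, S, sigma) {
  yty <- sum(y^2)
  if (length(S) == 0L) return(-0.5 * yty)
  Xs <- X[, S, drop = FALSE]
  A <- diag(length(S)) + sigma^2 * crossprod(Xs)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  u <- crossprod(Xs, y)
  z <- backsolve(ch, forwardsolve(t(ch), u))
  quad <- yty - sigma^2 * sum(u * z)
  logdet <- 2 * sum(log(diag(ch)))
  -0.5 * (logdet + quad)
}

# Weighted least-squares fit of y on X[, S]: estimates, standard errors
# (unit error variance) and normal p-values on the standardized scale.
model_fit <- function(y, X, S) {
  Xs <- X[, S, drop = FALSE]
  XtX <- crossprod(Xs)
  inv <- tryCatch(solve(XtX), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  est <- drop(inv %*% crossprod(Xs, y))
  se <- sqrt(diag(inv))
  list(est = est, se = se, pval = 2 * stats::pnorm(-abs(est / se)),
       fitted = drop(Xs %*% est), hat = rowSums((Xs %*% inv) * Xs))
}

all_subsets <- function(K, max_size) {
  out <- list(integer(0))
  for (size in seq_len(max_size)) {
    out <- c(out, utils::combn(K, size, simplify = FALSE))
  }
  out
}

#' Posterior probabilities over exposure subsets
#'
#' For every exposure subset up to `max_model_size`, computes the closed-form
#' marginal likelihood of the inverse-variance weighted multivariable
#' regression (no intercept) under an independent Gaussian shrinkage prior
#' `N(0, prior_sigma^2)` on the standardized subset effects, combines it with
#' independent Bernoulli(`prior_inclusion_prob`) inclusion priors, and
#' normalizes over the evaluated model space. Exhaustive mode enumerates all
#' subsets; stochastic mode runs a seeded shotgun search and normalizes over
#' the distinct models it visits.
#'
#' @param input a [bma_input()].
#' @param config a [bma_config()].
#' @return A list of class `bma_posteriors`: `models` (each with `subset`,
#'   `exposure_ids`, `pp`, `log_marginal`, `estimates`, `ses`, `pvals` on
#'   the original exposure scale), plus `exposure_ids`, `config` and
#'   `n_singular`.
#' @export
model_posteriors <- function(input, config = bma_config()) {
  K <- ncol(input$beta_x)
  max_size <- config$max_model_size
  if (is.null(max_size)) max_size <- min(K, 12L)
  stopifnot(max_size >= 1L, max_size <= K)
  w <- bma_working(input)
  sigma <- config$prior_sigma
  lp_in <- log(config$prior_inclusion_prob)
  lp_out <- log1p(-config$prior_inclusion_prob)

  subsets <- if (config$search == "exhaustive") {
    all_subsets(K, max_size)
  } else {
    shotgun_subsets(w, K, max_size, config)
  }

  fits <- lapply(subsets, function(S) {
    if (length(S) == 0L) NULL else model_fit(w$y, w$X, S)
  })
  lml <- vapply(seq_along(subsets), function(i) {
    S <- subsets[[i]]
    # a singular design has no identifiable subset effects; excluded
    if (length(S) > 0L && is.null(fits[[i]])) return(-Inf)
    log_marginal(w$y, w$X, S, sigma)
  }, numeric(1))
  lprior <- vapply(subsets, function(S) {
    length(S) * lp_in + (K - length(S)) * lp_out
  }, numeric(1))
  lpost <- lml + lprior
  finite <- is.finite(lpost)
  pp <- rep(0, length(lpost))
  pp[finite] <- exp(lpost[finite] - max(lpost[finite]))
  pp <- pp / sum(pp)

  models <- lapply(seq_along(subsets), function(i) {
    S <- subsets[[i]]
    est <- se <- pv <- stats::setNames(numeric(0), character(0))
    fit <- fits[[i]]
    if (!is.null(fit) && is.finite(lml[i])) {
      est <- stats::setNames(fit$est / w$scale[S], input$exposure_ids[S])
      se <- stats::setNames(fit$se / w$scale[S], input$exposure_ids[S])
      pv <- stats::setNames(fit$pval, input$exposure_ids[S])
    }
    list(subset = S, exposure_ids = input$exposure_ids[S], pp = pp[i],
         log_marginal = lml[i], estimates = est, ses = se, pvals = pv)
  })
  structure(list(models = models, exposure_ids = input$exposure_ids,
                 config = config, n_singular = sum(!finite)),
            class = "bma_posteriors")
}

# Seeded shotgun stochastic search: from a random start, repeatedly score
# the add/delete/swap neighborhood and move with probability proportional to
# the (unnormalized) posterior. Returns the distinct subsets visited.
shotgun_subsets <- function(w, K, max_size, config) {
  sigma <- config$prior_sigma
  lp_in <- log(config$prior_inclusion_prob)
  lp_out <- log1p(-config$prior_inclusion_prob)
  score <- function(S) {
    log_marginal(w$y, w$X, S, sigma) +
      length(S) * lp_in + (K - length(S)) * lp_out
  }
  key <- function(S) paste0("m", paste(S, collapse = ","))
  withr_seed(config$seed, {
    seen <- new.env(parent = emptyenv())
    cur <- sort(sample(K, min(2L, max_size)))
    assign(key(cur), cur, envir = seen)
    for (iter in seq_len(config$n_search_iter)) {
      nb <- list()
      for (j in seq_len(K)) {
        if (j %in% cur) {
          nb <- c(nb, list(setdiff(cur, j)))
        } else if (length(cur) < max_size) {
          nb <- c(nb, list(sort(c(cur, j))))
        }
        for (drop_j in cur) {
          if (!(j %in% cur)) {
            swp <- sort(c(setdiff(cur, drop_j), j))
            if (length(swp) <= max_size) nb <- c(nb, list(swp))
          }
        }
      }
      sc <- vapply(nb, score, numeric(1))
      for (i in seq_along(nb)) assign(key(nb[[i]]), nb[[i]], envir = seen)
      pr <- exp(sc - max(sc[is.finite(sc)]))
      pr[!is.finite(pr)] <- 0
      if (sum(pr) == 0) break
      cur <- nb[[sample.int(length(nb), 1L, prob = pr)]]
    }
    # always include the empty model so the normalization has the null
    assign(key(integer(0)), integer(0), envir = seen)
    unname(as.list(mget(ls(seen), envir = seen)))
  })
}

#' Rank exposures by marginal inclusion probability
#'
#' The marginal inclusion probability (MIP) of a trait is the sum of the
#' posterior probabilities of every model containing it; the model-averaged
#' causal estimate (MACE) is the posterior-probability-weighted average of
#' its model-specific direct effects, with models excluding the trait
#' contributing zero. Each trait's best model is the highest-posterior model
#' containing it; its posterior probability, trait estimate and p-value fill
#' the best-model columns, and traits are ranked both by MIP and by that
#' best-model posterior.
#'
#' @param posteriors output of [model_posteriors()].
#' @return A data frame of class `trait_ranking`, one row per exposure:
#'   `exposure_id`, `mip`, `mace`, `best_model_pp`, `best_model_estimate`,
#'   `best_model_pval`, `rank_by_mip`, `rank_by_pp`.
#' @export
rank_traits <- function(posteriors) {
  ids <- posteriors$exposure_ids
  K <- length(ids)
  mip <- mace <- bpp <- best_est <- best_p <- rep(0, K)
  best_est[] <- best_p[] <- NA_real_
  for (mod in posteriors$models) {
    if (mod$pp == 0 || length(mod$estimates) == 0L) next
    for (k in mod$subset) {
      mip[k] <- mip[k] + mod$pp
      mace[k] <- mace[k] + mod$pp * mod$estimates[[ids[k]]]
      if (mod$pp > bpp[k]) {
        bpp[k] <- mod$pp
        best_est[k] <- mod$estimates[[ids[k]]]
        best_p[k] <- mod$pvals[[ids[k]]]
      }
    }
  }
  out <- data.frame(exposure_id = ids, mip = mip, mace = mace,
                    best_model_pp = bpp, best_model_estimate = best_est,
                    best_model_pval = best_p, stringsAsFactors = FALSE)
  out$rank_by_mip <- rank(-out$mip, ties.method = "first")
  out$rank_by_pp <- rank(-out$best_model_pp, ties.method = "first")
  out <- out[order(out$rank_by_mip), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("trait_ranking", "data.frame")
  out
}

#' Best-model table
#'
#' Individual models whose posterior probability reaches `pp_threshold`,
#' with their member estimates and p-values.
#'
#' @param posteriors output of [model_posteriors()].
#' @param pp_threshold reporting cutoff (default from the config used).
#' @return Data frame: `model` (comma-separated exposure ids), `pp`,
#'   `exposure_id`, `estimate`, `pval` (one row per member exposure).
#' @export
best_models <- function(posteriors, pp_threshold = NULL) {
  if (is.null(pp_threshold)) pp_threshold <- posteriors$config$pp_threshold
  rows <- list()
  for (mod in posteriors$models) {
    if (mod$pp < pp_threshold || length(mod$subset) == 0L ||
        length(mod$estimates) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      model = paste(mod$exposure_ids, collapse = ","), pp = mod$pp,
      exposure_id = mod$exposure_ids,
      estimate = unname(mod$estimates), pval = unname(mod$pvals),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(model = character(0), pp = numeric(0),
                      exposure_id = character(0), estimate = numeric(0),
                      pval = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(-out$pp), , drop = FALSE]
}

#' Influence diagnostics and outlier removal
#'
#' For every best model (posterior probability at or above the config's
#' `pp_threshold`), refits the weighted regression and computes each
#' instrument's Cochran Q contribution (squared standardized residual) and
#' Cook's distance. An instrument exceeding `q_threshold` or the Cook's
#' cutoff in any best model is flagged; the cleaned input excludes flagged
#' instruments so the posterior computation can be repeated without them.
#'
#' @param input a [bma_input()].
#' @param posteriors output of [model_posteriors()] on that input.
#' @param config a [bma_config()].
#' @return List: `diagnostics` (data frame `snp`, `model`, `q`, `cooks_d`,
#'   `flagged`), `flagged_snps`, and `cleaned` (a `bma_input` without the
#'   flagged instruments; identical to `input` when nothing is flagged).
#' @export
influence_diagnostics <- function(input, posteriors, config = bma_config()) {
  w <- bma_working(input)
  m <- length(w$y)
  best <- Filter(function(mod) {
    mod$pp >= config$pp_threshold && length(mod$subset) > 0L
  }, posteriors$models)
  if (length(best) == 0L) {
    # fall back to the single highest-posterior non-empty model
    nonempty <- Filter(function(mod) length(mod$subset) > 0L,
                       posteriors$models)
    if (length(nonempty) > 0L) {
      best <- nonempty[which.max(vapply(nonempty, `[[`, 0, "pp"))]
    }
  }
  if (length(best) == 0L) stop("no non-empty model to diagnose", call. = FALSE)

  rows <- list()
  for (mod in best) {
    S <- mod$subset
    fit <- model_fit(w$y, w$X, S)
    if (is.null(fit)) next
    p <- length(S)
    r <- w$y - fit$fitted
    q <- r^2
    sigma2 <- sum(q) / max(1, m - p)
    # an (up to rounding) exact fit has no influential points
    exact <- sum(q) <= 1e-10 * max(1, sum(w$y^2))
    cooks <- if (!exact) {
      q * fit$hat / (p * sigma2 * (1 - fit$hat)^2)
    } else rep(0, m)
    cook_cut <- if (identical(config$cooks_threshold, "auto")) {
      stats::qf(0.5, p, max(1, m - p))
    } else config$cooks_threshold
    rows[[length(rows) + 1L]] <- data.frame(
      snp = input$snp_ids, model = paste(mod$exposure_ids, collapse = ","),
      q = q, cooks_d = cooks,
      flagged = (q > config$q_threshold | cooks > cook_cut) %in% TRUE,
      stringsAsFactors = FALSE)
  }
  diagnostics <- do.call(rbind, rows)
  flagged <- unique(diagnostics$snp[diagnostics$flagged])
  if (length(flagged) == length(input$snp_ids)) {
    stop("all instruments flagged as outliers; diagnostics:\n",
         paste(utils::capture.output(print(diagnostics)), collapse = "\n"),
         call. = FALSE)
  }
  keep <- !(input$snp_ids %in% flagged)
  cleaned <- bma_input(input$snp_ids[keep],
                       input$beta_x[keep, , drop = FALSE],
                       input$beta_y[keep], input$se_y[keep])
  list(diagnostics = diagnostics, flagged_snps = flagged, cleaned = cleaned)
}

#' Permutation p-values for the trait ranking
#'
#' Empirical p-value per exposure for its marginal inclusion probability:
#' the outcome (effect, standard error) pairs are permuted across
#' instruments, the full posterior computation is repeated, and the p-value
#' is the fraction of permutations reaching the observed MIP, with the
#' `1/(n_permutations + 1)` resolution floor.
#'
#' @param input a [bma_input()].
#' @param config a [bma_config()]; `n_permutations` and `seed` are used.
#' @param observed_mip optional precomputed MIP vector (recomputed when
#'   `NULL`).
#' @return Data frame: `exposure_id`, `mip`, `perm_pval`.
#' @export
permutation_pvalues <- function(input, config = bma_config(),
                                observed_mip = NULL) {
  if (is.null(observed_mip)) {
    obs <- rank_traits(model_posteriors(input, config))
    observed_mip <- stats::setNames(obs$mip, obs$exposure_id)
    observed_mip <- observed_mip[input$exposure_ids]
  }
  B <- config$n_permutations
  hits <- rep(0L, length(input$exposure_ids))
  withr_seed(config$seed + 1L, {
    for (b in seq_len(B)) {
      perm <- sample.int(length(input$beta_y))
      pin <- bma_input(input$snp_ids, input$beta_x,
                       input$beta_y[perm], input$se_y[perm])
      rt <- rank_traits(model_posteriors(pin, config))
      mip_b <- stats::setNames(rt$mip, rt$exposure_id)[input$exposure_ids]
      hits <- hits + as.integer(mip_b >= observed_mip)
    }
  })
  data.frame(exposure_id = input$exposure_ids,
             mip = unname(observed_mip),
             perm_pval = (hits + 1) / (B + 1), stringsAsFactors = FALSE)
}

#' Run the full MR-BMA stage
#'
#' [model_posteriors()] and [rank_traits()] on the input, one
#' [influence_diagnostics()] pass removing flagged instruments, and a
#' recomputation on the cleaned input, mirroring the
#' screen-diagnose-recompute workflow.
#'
#' @param input a [bma_input()].
#' @param config a [bma_config()].
#' @param permute also compute permutation p-values (default `FALSE`; they
#'   dominate the run time).
#' @return List of class `mr_bma_fit`: `pre` and `post` (each with
#'   `posteriors`, `ranking`, `best_models`, and optionally `perm_pvalues`),
#'   `diagnostics`, `flagged_snps`, `input`, `cleaned_input`.
#' @export
run_mr_bma <- function(input, config = bma_config(), permute = FALSE) {
  post0 <- model_posteriors(input, config)
  pre <- list(posteriors = post0, ranking = rank_traits(post0),
              best_models = best_models(post0))
  diag <- influence_diagnostics(input, post0, config)
  if (length(diag$flagged_snps) > 0L) {
    post1 <- model_posteriors(diag$cleaned, config)
    post_stage <- list(posteriors = post1, ranking = rank_traits(post1),
                       best_models = best_models(post1))
  } else {
    post_stage <- pre
  }
  if (permute) {
    pre$perm_pvalues <- permutation_pvalues(input, config,
                                            stats::setNames(pre$ranking$mip,
                                                            pre$ranking$exposure_id)[input$exposure_ids])
    post_stage$perm_pvalues <- permutation_pvalues(
      diag$cleaned, config,
      stats::setNames(post_stage$ranking$mip,
                      post_stage$ranking$exposure_id)[diag$cleaned$exposure_ids])
  }
  structure(list(pre = pre, post = post_stage, diagnostics = diag$diagnostics,
                 flagged_snps = diag$flagged_snps, input = input,
                 cleaned_input = diag$cleaned),
            class = "mr_bma_fit")
}
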