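test_that("the two-model space normalizes and favours a supported exposure", {
  input <- make_bma_fixture(m = 50, K = 1, theta = 0.4, seed = 2)
  post <- model_posteriors(input, bma_config(seed = 1))
  expect_equal(length(post$models), 2L)
  pp <- vapply(post$models, `[[`, 0, "pp")
  expect_equal(sum(pp), 1, tolerance = 1e-12)
  sizes <- vapply(post$models, function(mod) length(mod$subset), 0L)
  expect_gt(pp[sizes == 1], pp[sizes == 0])
})

test_that("posteriors match an independent full-covariance enumeration oracle", {
  for (seed in 1:4) {
    K <- sample(2:4, 1)
    input <- make_bma_fixture(m = 30, K = K,
                              theta = c(0.3, rep(0, K - 1)), seed = seed)
    cfg <- bma_config(seed = seed)
    post <- model_posteriors(input, cfg)
    oracle <- oracle_posteriors(input, cfg)
    key <- function(S) paste0("m", paste(S, collapse = ","))
    imp <- vapply(post$models, function(mod) mod$pp, 0)
    names(imp) <- vapply(post$models, function(mod) key(mod$subset), "")
    orc <- setNames(oracle$pp, vapply(oracle$subsets, key, ""))
    expect_equal(imp[names(orc)], orc, tolerance = 1e-10)
    rt <- rank_traits(post)
    rt <- rt[match(input$exposure_ids, rt$exposure_id), ]
    expect_equal(rt$mip, oracle$mip, tolerance = 1e-10)
    expect_equal(rt$mace, oracle$mace, tolerance = 1e-10)
  }
})

test_that("MIP and MACE follow their defining sums", {
  fake <- structure(list(
    models = list(
      list(subset = 1L, exposure_ids = "a", pp = 0.5,
           estimates = c(a = 0.4), ses = c(a = 0.1), pvals = c(a = 0.01),
           log_marginal = 0),
      list(subset = c(1L, 2L), exposure_ids = c("a", "b"), pp = 0.25,
           estimates = c(a = 0.2, b = 0.1), ses = c(a = 0.1, b = 0.1),
           pvals = c(a = 0.05, b = 0.3), log_marginal = 0),
      list(subset = integer(0), exposure_ids = character(0), pp = 0.25,
           estimates = setNames(numeric(0), character(0)),
           ses = numeric(0), pvals = numeric(0), log_marginal = 0)),
    exposure_ids = c("a", "b"), config = bma_config(seed = 1),
    n_singular = 0L), class = "bma_posteriors")
  rt <- rank_traits(fake)
  a <- rt[rt$exposure_id == "a", ]
  b <- rt[rt$exposure_id == "b", ]
  expect_equal(a$mip, 0.75)
  expect_equal(a$mace, 0.5 * 0.4 + 0.25 * 0.2)
  expect_equal(a$rank_by_mip, 1L)
  expect_equal(b$mip, 0.25)
  expect_equal(b$mace, 0.25 * 0.1)
  # single-model case: MIP = pp, MACE = pp * estimate
  fake$models <- fake$models[c(1, 3)]
  fake$models[[2]]$pp <- 0.2
  fake$models[[1]]$pp <- 0.8
  fake$exposure_ids <- "a"
  rt1 <- rank_traits(fake)
  expect_equal(rt1$mip, 0.8)
  expect_equal(rt1$mace, 0.8 * 0.4)
})

test_that("a vanishing inclusion prior concentrates mass on the null model", {
  input <- make_bma_fixture(m = 40, K = 3, theta = c(0, 0, 0), seed = 3)
  post <- model_posteriors(input, bma_config(prior_inclusion_prob = 1e-9,
                                             seed = 1))
  null_pp <- vapply(post$models, function(mod) {
    if (length(mod$subset) == 0L) mod$pp else 0
  }, 0)
  expect_gt(sum(null_pp), 0.999)
  expect_true(all(rank_traits(post)$mip < 1e-3))
})

test_that("a singular subset is excluded with zero posterior mass", {
  input <- make_bma_fixture(m = 30, K = 2, theta = c(0.3, 0), seed = 4)
  input$beta_x[, 2] <- input$beta_x[, 1]  # exact collinearity
  post <- model_posteriors(input, bma_config(seed = 1))
  pair <- Filter(function(mod) length(mod$subset) == 2L, post$models)[[1]]
  expect_identical(pair$log_marginal, -Inf)
  expect_equal(pair$pp, 0)
  expect_equal(sum(vapply(post$models, `[[`, 0, "pp")), 1, tolerance = 1e-12)
  expect_gt(post$n_singular, 0)
})

test_that("an injected outlier instrument attains the maximal Q contribution and is flagged", {
  set.seed(6)
  for (seed in 1:10) {
    input <- make_bma_fixture(m = 40, K = 3, seed = seed)
    fit0 <- model_posteriors(input, bma_config(seed = 1))
    # inflate one instrument's outcome effect to 10x its model prediction
    target <- 7L
    pred <- sum(input$beta_x[target, ] * c(0.3, 0, 0))
    input$beta_y[target] <- sign(pred + 1e-9) *
      max(abs(pred) * 10, 12 * input$se_y[target])
    post <- model_posteriors(input, bma_config(seed = 1))
    diag <- influence_diagnostics(input, post, bma_config(seed = 1))
    worst <- diag$diagnostics$snp[which.max(diag$diagnostics$q)]
    expect_equal(worst, input$snp_ids[target])
    expect_true(input$snp_ids[target] %in% diag$flagged_snps)
    # removing the flagged instrument never increases the best model's Q
    best <- diag$diagnostics$model[which.max(diag$diagnostics$q)]
    q_before <- sum(diag$diagnostics$q[diag$diagnostics$model == best])
    post2 <- model_posteriors(diag$cleaned, bma_config(seed = 1))
    diag2 <- influence_diagnostics(diag$cleaned, post2, bma_config(seed = 1))
    if (best %in% diag2$diagnostics$model) {
      q_after <- sum(diag2$diagnostics$q[diag2$diagnostics$model == best])
      expect_lte(q_after, q_before)
    }
  }
})

test_that("noise-free inputs pass the diagnostics untouched", {
  set.seed(8)
  X <- matrix(rnorm(60, 0, 0.1), 20, 3)
  y <- drop(X %*% c(0.3, 0, 0))  # exact fit, zero residuals
  input <- bma_input(sprintf("rs%02d", 1:20), X, y, rep(0.03, 20))
  post <- model_posteriors(input, bma_config(seed = 1))
  diag <- influence_diagnostics(input, post, bma_config(seed = 1))
  expect_length(diag$flagged_snps, 0)
  expect_equal(diag$cleaned$snp_ids, input$snp_ids)
  expect_equal(diag$cleaned$beta_y, input$beta_y)
})

test_that("stochastic search reproduces the exhaustive top-3 MIP ranking", {
  input <- make_bma_fixture(m = 60, K = 8, theta = c(0.3, rep(0, 7)),
                            seed = 9)
  exh <- rank_traits(model_posteriors(input, bma_config(seed = 1)))
  sto <- rank_traits(model_posteriors(
    input, bma_config(search = "stochastic", n_search_iter = 200, seed = 1)))
  expect_equal(sto$exposure_id[1:3], exh$exposure_id[1:3])
})

test_that("permutation p-values floor at 1/(B+1) for strong signal and stay consistent when B doubles", {
  input <- make_bma_fixture(m = 50, K = 2, theta = c(0.5, 0), seed = 10,
                            se_y = 0.02)
  p100 <- permutation_pvalues(input, bma_config(n_permutations = 100,
                                                seed = 2))
  expect_equal(p100$perm_pval[p100$exposure_id == "met_1"], 1 / 101)
  p200 <- permutation_pvalues(input, bma_config(n_permutations = 200,
                                                seed = 2))
  expect_lt(max(abs(p100$perm_pval - p200$perm_pval)), 0.15)
})

test_that("permutation p-values are near-uniform under a pure-noise outcome", {
  set.seed(11)
  pvals <- c()
  for (rep in 1:25) {
    input <- make_bma_fixture(m = 30, K = 3, theta = c(0, 0, 0),
                              seed = 100 + rep)
    pv <- permutation_pvalues(input, bma_config(n_permutations = 60,
                                                seed = rep))
    pvals <- c(pvals, pv$perm_pval)
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("build_bma_input pools, re-clumps and aligns instruments", {
  # three exposures sharing all instruments
  sc <- simulate_scenario(scenario_config(n_snps = 40, n_exposures = 3,
                                          sharing = 1,
                                          n_causal_per_exposure = 12,
                                          true_effects = c(0.3, 0, 0),
                                          seed = 12))
  input <- build_bma_input(NULL, sc$exposures, sc$outcome, ld = sc$ld)
  union_inst <- unique(unlist(lapply(sc$exposures, function(e) {
    select_instruments(e, sc$ld)$instruments$snp
  })))
  expect_lte(length(input$snp_ids), length(union_inst))
  expect_equal(ncol(input$beta_x), 3L)
  # disjoint instruments: m equals the sum of per-exposure counts (minus
  # any palindromic-ambiguity losses at outcome alignment)
  sc2 <- simulate_scenario(scenario_config(n_snps = 40, n_exposures = 2,
                                           sharing = 0,
                                           n_causal_per_exposure = 8,
                                           true_effects = c(0.3, 0),
                                           seed = 13))
  counts <- vapply(sc2$exposures, function(e) {
    nrow(select_instruments(e, sc2$ld)$instruments)
  }, 0L)
  input2 <- build_bma_input(NULL, sc2$exposures, sc2$outcome, ld = sc2$ld)
  expect_lte(length(input2$snp_ids), sum(counts))
  expect_gte(length(input2$snp_ids), sum(counts) - 4L)
  expect_gte(attr(input2, "n_imputed_zero"), 0)
})

test_that("a cross-exposure LD pair keeps exactly one member", {
  sc <- simulate_scenario(scenario_config(
    n_snps = 30, n_exposures = 2, sharing = 0, n_causal_per_exposure = 6,
    true_effects = c(0.3, 0), ld_blocks = list(c(2, 0.9)), seed = 14))
  input <- build_bma_input(NULL, sc$exposures, sc$outcome, ld = sc$ld)
  block <- c("rs000001", "rs000002")
  expect_lte(sum(block %in% input$snp_ids), 1L)
})

test_that("fewer than two qualifying exposures skips the stage with a warning", {
  sc <- simulate_scenario(scenario_config(n_snps = 30, n_exposures = 2,
                                          n_causal_per_exposure = 6,
                                          true_effects = c(0.3, 0),
                                          seed = 15))
  uni <- data.frame(trait_id = names(sc$exposures), method = "ivw",
                    pval = c(0.001, 0.9))
  expect_warning(
    out <- build_bma_input(uni, sc$exposures, sc$outcome, ld = sc$ld),
    "fewer than two")
  expect_null(out)
})
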