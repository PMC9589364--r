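# Seeded generator of GWAS summary statistics with the structure the
# analysis assumes: K correlated quantitative exposures whose correlation
# comes from shared causal variants, a binary outcome with heavy
# case/control imbalance, optional LD blocks and optional pleiotropy.
# Effects are simulated directly on the summary-statistic scale; no
# individual-level genotypes are involved.

#' Simulation scenario configuration
#'
#' The defaults mirror the shape of a large NMR metabolite panel screened
#' against a biobank pancreatitis outcome: 10 correlated exposures measured
#' in 115,078 individuals, ~130 distinct instruments after clumping, and an
#' outcome with 3,022 cases and 195,144 controls.
#'
#' @param n_snps total SNPs simulated (causal and null).
#' @param n_exposures number of exposure traits K.
#' @param sharing fraction of each exposure's causal variants drawn from a
#'   pool shared by all exposures (drives cross-exposure correlation).
#' @param n_causal_per_exposure causal variants per exposure.
#' @param true_effects length-K vector of causal effects of the exposures on
#'   the outcome (log-odds per SD of exposure); recycled if length 1.
#' @param pleiotropy_mode `"none"`, `"balanced"` (mean-zero direct effects)
#'   or `"directional"` (a common-sign offset).
#' @param pleiotropy_sd magnitude of the pleiotropic effect: the standard
#'   deviation of the mean-zero effects under `"balanced"`, the constant
#'   offset under `"directional"`.
#' @param pleiotropy_frac fraction of causal variants receiving a
#'   pleiotropic effect (default 0.3).
#' @param n_exposure_samples exposure GWAS sample size.
#' @param n_cases,n_controls outcome GWAS case/control counts.
#' @param maf_range interval in (0, 0.5\] the minor allele frequency is drawn
#'   from, uniformly.
#' @param loading_range interval the causal loading magnitudes (SD of
#'   exposure per allele) are drawn from, uniformly with random sign per
#'   variant.
#' @param ld_blocks optional list of `c(size, r2)` pairs: consecutive blocks
#'   of SNPs (starting at the first SNP) receive the given pairwise squared
#'   correlation and are placed within 100 kb of each other.
#' @param seed integer seed; the whole scenario is a deterministic function
#'   of the configuration.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_snps = 250, n_exposures = 10, sharing = 0.5,
                            n_causal_per_exposure = 26,
                            true_effects = c(0.3, rep(0, n_exposures - 1)),
                            pleiotropy_mode = c("none", "balanced",
                                                "directional"),
                            pleiotropy_sd = 0.1, pleiotropy_frac = 0.3,
                            n_exposure_samples = 115078,
                            n_cases = 3022, n_controls = 195144,
                            maf_range = c(0.05, 0.5),
                            loading_range = c(0.05, 0.25),
                            ld_blocks = NULL, seed = 1) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (length(true_effects) == 1L) {
    true_effects <- rep(true_effects, n_exposures)
  }
  stopifnot(sharing >= 0, sharing <= 1, n_cases + n_controls > 0,
            length(true_effects) == n_exposures,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  n_shared <- round(sharing * n_causal_per_exposure)
  n_private <- n_causal_per_exposure - n_shared
  n_causal_total <- n_shared + n_private * n_exposures
  if (n_causal_total > n_snps) {
    stop("n_snps too small for the requested causal structure (needs >= ",
         n_causal_total, ")", call. = FALSE)
  }
  if (!is.null(ld_blocks)) {
    sizes <- vapply(ld_blocks, `[`, 0, 1)
    if (sum(sizes) > n_snps) {
      stop("LD block sizes exceed n_snps", call. = FALSE)
    }
    if (any(vapply(ld_blocks, `[`, 0, 2) < 0) ||
        any(vapply(ld_blocks, `[`, 0, 2) > 1)) {
      stop("within-block r2 must lie in [0,1]", call. = FALSE)
    }
  }
  structure(list(
    n_snps = n_snps, n_exposures = n_exposures, sharing = sharing,
    n_causal_per_exposure = n_causal_per_exposure,
    n_shared = n_shared, n_private = n_private,
    true_effects = true_effects, pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_frac = pleiotropy_frac,
    n_exposure_samples = n_exposure_samples, n_cases = n_cases,
    n_controls = n_controls, maf_range = maf_range,
    loading_range = loading_range, ld_blocks = ld_blocks,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

snp_ids_for <- function(config) sprintf("rs%06d", seq_len(config$n_snps))

# Deterministic variant frame: ids, placement, alleles, frequency. LD-block
# members sit 10 kb apart on one chromosome; independent loci are spaced
# 25,000 kb apart (well beyond any clumping window) cycling over 22
# chromosomes.
simulate_variants <- function(config) {
  n <- config$n_snps
  block_id <- rep(NA_integer_, n)
  if (!is.null(config$ld_blocks)) {
    at <- 1L
    for (b in seq_along(config$ld_blocks)) {
      size <- config$ld_blocks[[b]][1]
      block_id[at:(at + size - 1L)] <- b
      at <- at + size
    }
  }
  chr <- character(n)
  pos <- numeric(n)
  next_pos <- rep(1e6, 22)
  cur_chr <- 0L
  i <- 1L
  while (i <= n) {
    cur_chr <- cur_chr %% 22L + 1L
    members <- if (!is.na(block_id[i])) which(block_id == block_id[i]) else i
    chr[members] <- as.character(cur_chr)
    pos[members] <- next_pos[cur_chr] + (seq_along(members) - 1L) * 1e4
    next_pos[cur_chr] <- max(pos[members]) + 25e6
    i <- max(members) + 1L
  }
  pairs <- utils::combn(VALID_ALLELES, 2)
  pick <- sample.int(ncol(pairs), n, replace = TRUE)
  swap <- sample(c(TRUE, FALSE), n, replace = TRUE)
  ea <- ifelse(swap, pairs[2, pick], pairs[1, pick])
  oa <- ifelse(swap, pairs[1, pick], pairs[2, pick])
  data.frame(snp = snp_ids_for(config), chr = chr, pos = pos, ea = ea,
             oa = oa, maf = stats::runif(n, config$maf_range[1],
                                         config$maf_range[2]),
             block = block_id, stringsAsFactors = FALSE)
}

# True per-allele exposure effects (SD units): an n_snps x K matrix. The
# first n_shared SNPs are causal for every exposure (correlated loadings:
# one base magnitude per SNP, exposure-specific multipliers); each exposure
# then gets its own private causal variants; remaining SNPs are null.
simulate_loadings <- function(config, variants) {
  n <- config$n_snps
  K <- config$n_exposures
  loadings <- matrix(0, n, K,
                     dimnames = list(variants$snp,
                                     sprintf("met_%02d", seq_len(K))))
  base <- stats::runif(n, config$loading_range[1], config$loading_range[2]) *
    sample(c(-1, 1), n, replace = TRUE)
  shared <- seq_len(config$n_shared)
  at <- config$n_shared
  for (k in seq_len(K)) {
    if (config$n_shared > 0L) {
      loadings[shared, k] <- base[shared] * stats::rnorm(config$n_shared, 1, 0.2)
    }
    if (config$n_private > 0L) {
      private <- at + seq_len(config$n_private)
      loadings[private, k] <- base[private]
      at <- at + config$n_private
    }
  }
  loadings
}

se_exposure <- function(maf, n) 1 / sqrt(2 * maf * (1 - maf) * n)

se_outcome <- function(maf, n_cases, n_controls) {
  sqrt((1 / n_cases + 1 / n_controls) / (2 * maf * (1 - maf)))
}

# Underflow-safe two-sided normal p-value.
wald_pval <- function(z) pmax(2 * stats::pnorm(-abs(z)), 1e-300)

#' Simulate exposure GWAS summary statistics
#'
#' Draws sparse true per-SNP loadings with the configured cross-exposure
#' sharing, adds sampling noise with the standard error implied by the
#' allele frequency and sample size (`1/sqrt(2 maf (1-maf) n)`), and emits
#' one association set per exposure. Deterministic given the seed.
#'
#' @param config a [scenario_config()].
#' @return List: `exposures` (named list of [assoc_set()]), `loadings`
#'   (true effect matrix), `variants` (variant frame with placement, alleles
#'   and allele frequency), `n_significant` (genome-wide-significant SNP
#'   count per exposure).
#' @export
simulate_exposure_gwas <- function(config) {
  withr_seed(config$seed, {
    variants <- simulate_variants(config)
    loadings <- simulate_loadings(config, variants)
    se <- se_exposure(variants$maf, config$n_exposure_samples)
    exposures <- list()
    for (k in seq_len(config$n_exposures)) {
      beta <- loadings[, k] + stats::rnorm(config$n_snps, 0, se)
      id <- colnames(loadings)[k]
      exposures[[id]] <- assoc_set(
        data.frame(snp = variants$snp, chr = variants$chr,
                   pos = variants$pos, ea = variants$ea, oa = variants$oa,
                   eaf = variants$maf, beta = beta, se = se,
                   pval = wald_pval(beta / se),
                   n = config$n_exposure_samples,
                   stringsAsFactors = FALSE),
        trait_id = id, trait_label = sprintf("synthetic metabolite %d", k),
        category = "synthetic_metabolites")
    }
    n_sig <- vapply(exposures, function(e) sum(e$pval < 5e-8), 0L)
    list(exposures = exposures, loadings = loadings, variants = variants,
         n_significant = n_sig)
  })
}

#' Simulate outcome GWAS summary statistics
#'
#' Per-SNP outcome log-odds are the loading-weighted sum of the true causal
#' effects plus any pleiotropic effect and sampling noise; the standard
#' error uses the case/control log-odds approximation
#' `sqrt((1/n_cases + 1/n_controls) / (2 maf (1-maf)))`.
#'
#' @param config a [scenario_config()].
#' @param loadings,variants from [simulate_exposure_gwas()].
#' @return List: `outcome` (an [assoc_set()] with category `"outcome"`),
#'   `pleiotropy` (the per-SNP direct effects).
#' @export
simulate_outcome_gwas <- function(config, loadings, variants) {
  withr_seed(config$seed + 1L, {
    gamma <- drop(loadings %*% config$true_effects)
    pleio <- rep(0, config$n_snps)
    causal <- rowSums(loadings != 0) > 0
    if (config$pleiotropy_mode != "none" && any(causal)) {
      pool <- which(causal)
      n_pleio <- round(config$pleiotropy_frac * length(pool))
      chosen <- sample(pool, n_pleio)
      # Directional pleiotropy is anchored to the exposure-increasing
      # allele: the offset carries the sign of the variant's dominant
      # loading, so it does not cancel under instrument re-orientation.
      lead_sign <- apply(loadings[chosen, , drop = FALSE], 1, function(r) {
        s <- sign(r[which.max(abs(r))])
        if (s == 0) 1 else s
      })
      pleio[chosen] <- switch(config$pleiotropy_mode,
        balanced = stats::rnorm(n_pleio, 0, config$pleiotropy_sd),
        directional = config$pleiotropy_sd * lead_sign)
    }
    se <- se_outcome(variants$maf, config$n_cases, config$n_controls)
    beta <- gamma + pleio + stats::rnorm(config$n_snps, 0, se)
    outcome <- assoc_set(
      data.frame(snp = variants$snp, chr = variants$chr, pos = variants$pos,
                 ea = variants$ea, oa = variants$oa, eaf = variants$maf,
                 beta = beta, se = se, pval = wald_pval(beta / se),
                 n = config$n_cases + config$n_controls,
                 stringsAsFactors = FALSE),
      trait_id = "outcome", trait_label = "synthetic binary outcome",
      category = "outcome")
    list(outcome = outcome, pleiotropy = pleio)
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' @param config a [scenario_config()]; its `ld_blocks` assign consecutive
#'   SNPs the given within-block squared correlation, zeros elsewhere.
#' @return An [ld_matrix()] over all simulated SNP ids.
#' @export
simulate_ld_matrix <- function(config) {
  ids <- snp_ids_for(config)
  m <- diag(1, config$n_snps)
  dimnames(m) <- list(ids, ids)
  if (!is.null(config$ld_blocks)) {
    at <- 1L
    for (b in config$ld_blocks) {
      idx <- at:(at + b[1] - 1L)
      m[idx, idx] <- b[2]
      diag(m)[idx] <- 1
      at <- at + b[1]
    }
    diag(m) <- 1
  }
  ld_matrix(m)
}

#' Simulate a full scenario
#'
#' @param config a [scenario_config()].
#' @return List of class `mr_scenario`: `config`, `exposures`, `outcome`,
#'   `ld`, `truth` (loadings, true effects, pleiotropy assignments,
#'   per-exposure significant counts).
#' @export
simulate_scenario <- function(config = scenario_config()) {
  ex <- simulate_exposure_gwas(config)
  out <- simulate_outcome_gwas(config, ex$loadings, ex$variants)
  structure(list(
    config = config, exposures = ex$exposures, outcome = out$outcome,
    ld = simulate_ld_matrix(config),
    truth = list(loadings = ex$loadings,
                 true_effects = stats::setNames(config$true_effects,
                                                colnames(ex$loadings)),
                 pleiotropy = stats::setNames(out$pleiotropy,
                                              ex$variants$snp),
                 n_significant = ex$n_significant)
  ), class = "mr_scenario")
}

#' Write a simulated scenario to disk
#'
#' Emits one native-dialect summary-statistics TSV per exposure plus the
#' outcome, the LD matrix, a truth JSON (loadings, true effects, pleiotropy
#' assignments) for recovery scoring, and exposure/outcome manifests usable
#' by the pipeline.
#'
#' @param scenario output of [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(trait_id = character(0), file = character(0),
                         label = character(0), category = character(0))
  for (id in names(scenario$exposures)) {
    f <- file.path(dir, paste0(id, ".tsv"))
    write_sumstats(scenario$exposures[[id]], f)
    manifest <- rbind(manifest, data.frame(
      trait_id = id, file = basename(f),
      label = attr(scenario$exposures[[id]], "trait_label"),
      category = attr(scenario$exposures[[id]], "category")))
  }
  write_sumstats(scenario$outcome, file.path(dir, "outcome.tsv"))
  utils::write.table(manifest, file.path(dir, "exposures.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(trait_id = "outcome", file = "outcome.tsv",
               label = attr(scenario$outcome, "trait_label"),
               category = "outcome"),
    file.path(dir, "outcomes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_ld_matrix(scenario$ld, file.path(dir, "ld_matrix.tsv"))
  jsonlite::write_json(
    list(true_effects = as.list(scenario$truth$true_effects),
         pleiotropy = as.list(scenario$truth$pleiotropy[
           scenario$truth$pleiotropy != 0]),
         loadings = as.data.frame(scenario$truth$loadings),
         n_significant = as.list(scenario$truth$n_significant)),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
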