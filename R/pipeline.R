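# End-to-end orchestration: univariable screen of every exposure x outcome
# pair, category grouping, then MR-BMA on named categories.

#' Load a study from a YAML configuration
#'
#' The configuration names an exposure manifest, an outcome manifest
#' (tab-separated: `trait_id`, `file`, `label`, `category`), an optional LD
#' matrix file, threshold overrides and a seed. Every referenced file is
#' resolved (relative to the config file's directory) before any
#' computation starts.
#'
#' @param path path to a YAML file with fields `exposure_manifest`,
#'   `outcome_manifest`, optional `ld_matrix`, `seed`, and optional
#'   `instruments` / `estimators` / `bma` parameter blocks.
#' @return A list of class `study`: `exposures`, `outcomes` (named lists of
#'   [assoc_set()]), `ld`, `params`.
#' @export
load_study <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(f) {
    p <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(p)) stop("file not found: ", f, call. = FALSE)
    p
  }
  read_manifest <- function(f) {
    man <- utils::read.table(resolve(f), header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    sets <- list()
    for (i in seq_len(nrow(man))) {
      sets[[man$trait_id[i]]] <- read_sumstats(
        resolve(man$file[i]), trait_id = man$trait_id[i],
        trait_label = man$label[i], category = man$category[i])
    }
    sets
  }
  exposures <- read_manifest(cfg$exposure_manifest)
  outcomes <- read_manifest(cfg$outcome_manifest)
  ld <- if (!is.null(cfg$ld_matrix)) read_ld_matrix(resolve(cfg$ld_matrix))
  params <- study_params(instruments = cfg$instruments,
                         estimators = cfg$estimators, bma = cfg$bma,
                         seed = if (is.null(cfg$seed)) 1L else cfg$seed)
  structure(list(exposures = exposures, outcomes = outcomes, ld = ld,
                 params = params), class = "study")
}

#' Assemble study parameters with defaults
#'
#' @param instruments,estimators,bma named lists overriding the defaults
#'   (instrument selection thresholds, estimator settings, MR-BMA
#'   configuration).
#' @param seed study-level seed.
#' @return Nested parameter list.
#' @export
study_params <- function(instruments = NULL, estimators = NULL, bma = NULL,
                         seed = 1L) {
  inst <- utils::modifyList(
    list(p_threshold = 5e-8, r2_threshold = 0.001, window_kb = 10000,
         f_threshold = 10),
    if (is.null(instruments)) list() else instruments)
  est <- utils::modifyList(
    list(effects_model = "multiplicative_random", n_boot = 1000,
         palindrome_policy = "infer_by_eaf", eaf_window = 0.08),
    if (is.null(estimators)) list() else estimators)
  bma_over <- if (is.null(bma)) list() else bma
  bma_over$seed <- if (is.null(bma_over$seed)) seed else bma_over$seed
  list(instruments = inst, estimators = est,
       bma = do.call(bma_config, bma_over), seed = as.integer(seed))
}

#' Univariable MR screen over all exposure-outcome pairs
#'
#' For every pair: select instruments ([select_instruments()]), harmonize
#' ([harmonize()]), and run IVW, MR-Egger, weighted median and the
#' heterogeneity statistics. Pairs that cannot be analyzed (no instruments,
#' no overlap) are skipped with a reason, never fatally. No multiple-testing
#' correction is applied to the significance marker -- many metabolite
#' traits share instruments and are far from independent, and correcting
#' would screen out valid exposures before the model-averaging stage -- but
#' a Benjamini-Hochberg FDR column is emitted alongside for users who want
#' it.
#'
#' @param exposures,outcomes named lists of [assoc_set()] objects.
#' @param ld an [ld_matrix()] or `NULL`.
#' @param params from [study_params()].
#' @return Data frame of class `screen_result`, one row per
#'   (trait, outcome, method): identity and category columns plus the tidy
#'   estimate columns of [mr_all_methods()], `significant` (two-sided 0.05)
#'   and `fdr`. Attribute `skips` lists skipped pairs with reasons;
#'   attribute `instruments` keeps the per-pair harmonized instruments.
#' @export
run_univariable_screen <- function(exposures, outcomes, ld = NULL,
                                   params = study_params()) {
  rows <- list()
  skips <- list()
  kept_instruments <- list()
  for (ex_id in names(exposures)) {
    ex <- exposures[[ex_id]]
    inst <- do.call(select_instruments, c(list(ex, ld), params$instruments))
    if (nrow(inst$instruments) == 0L) {
      for (out_id in names(outcomes)) {
        skips[[length(skips) + 1L]] <- data.frame(
          trait_id = ex_id, outcome_id = out_id,
          reason = "no_instruments", stringsAsFactors = FALSE)
      }
      next
    }
    inst_set <- assoc_set(inst$instruments, trait_id = ex_id,
                          trait_label = attr(ex, "trait_label"),
                          category = attr(ex, "category"),
                          validate = FALSE)
    for (out_id in names(outcomes)) {
      h <- tryCatch(
        harmonize(inst_set, outcomes[[out_id]],
                  palindrome_policy = params$estimators$palindrome_policy,
                  eaf_window = params$estimators$eaf_window),
        error = function(e) NULL)
      hk <- if (is.null(h)) NULL else harmonized_kept(h)
      if (is.null(hk) || nrow(hk) == 0L) {
        skips[[length(skips) + 1L]] <- data.frame(
          trait_id = ex_id, outcome_id = out_id,
          reason = "no_harmonized_overlap", stringsAsFactors = FALSE)
        next
      }
      est <- mr_all_methods(hk, n_boot = params$estimators$n_boot,
                            seed = params$seed,
                            effects_model = params$estimators$effects_model)
      est <- cbind(data.frame(trait_id = ex_id,
                              trait_label = attr(ex, "trait_label"),
                              category = attr(ex, "category"),
                              outcome_id = out_id,
                              stringsAsFactors = FALSE),
                   est)
      rows[[length(rows) + 1L]] <- est
      kept_instruments[[paste(ex_id, out_id, sep = "|")]] <- hk
    }
  }
  if (length(rows) == 0L) stop("no exposure-outcome pair could be analyzed",
                               call. = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$significant <- res$pval < 0.05
  res$fdr <- stats::p.adjust(res$pval, method = "BH")
  attr(res, "skips") <- if (length(skips) > 0L) {
    do.call(rbind, skips)
  } else {
    data.frame(trait_id = character(0), outcome_id = character(0),
               reason = character(0))
  }
  attr(res, "instruments") <- kept_instruments
  class(res) <- c("screen_result", "data.frame")
  res
}

#' MR-BMA stage for one category and outcome
#'
#' Restricts the screen to the named category, requires at least two traits
#' with IVW p < `include_p` against the outcome, assembles the combined
#' re-clumped input ([build_bma_input()]) and runs the full
#' posterior-diagnose-recompute workflow ([run_mr_bma()]), emitting both the
#' pre- and post-outlier-removal ranking tables.
#'
#' @param exposures named list of [assoc_set()]; `outcome` an [assoc_set()].
#' @param screen a `screen_result` from [run_univariable_screen()].
#' @param category category name to analyze.
#' @param outcome_id outcome column of the screen to condition on.
#' @param ld an [ld_matrix()] or `NULL`.
#' @param params from [study_params()].
#' @param include_p IVW p-value filter for trait inclusion (default 0.05).
#' @param permute compute permutation p-values (default `FALSE`).
#' @return An `mr_bma_fit` (see [run_mr_bma()]) with an `input` attribute,
#'   or `NULL` (with a warning) when the stage precondition fails.
#' @export
run_bma_stage <- function(exposures, outcome, screen, category, outcome_id,
                          ld = NULL, params = study_params(),
                          include_p = 0.05, permute = FALSE) {
  sub <- screen[screen$category == category &
                  screen$outcome_id == outcome_id, , drop = FALSE]
  cat_exposures <- exposures[names(exposures) %in% unique(sub$trait_id)]
  input <- build_bma_input(
    sub, cat_exposures, outcome, ld = ld, include_p = include_p,
    p_threshold = params$instruments$p_threshold,
    r2_threshold = params$instruments$r2_threshold,
    window_kb = params$instruments$window_kb,
    f_threshold = params$instruments$f_threshold,
    palindrome_policy = params$estimators$palindrome_policy,
    eaf_window = params$estimators$eaf_window)
  if (is.null(input)) return(NULL)
  run_mr_bma(input, params$bma, permute = permute)
}

#' Export a trait-by-outcome estimate matrix for heatmaps
#'
#' @param screen a `screen_result`.
#' @param method one of `"ivw"`, `"egger"`, `"weighted_median"`.
#' @param category optional category filter.
#' @return List with `estimate` (trait x outcome matrix of causal
#'   estimates; pairs that were skipped or not attempted are `NA`) and
#'   `significant` (logical mask at two-sided 0.05).
#' @export
export_heatmap_matrix <- function(screen, method = "ivw", category = NULL) {
  sub <- screen[screen$method == method, , drop = FALSE]
  if (!is.null(category)) sub <- sub[sub$category == category, , drop = FALSE]
  traits <- unique(sub$trait_id)
  outs <- unique(screen$outcome_id)
  est <- matrix(NA_real_, length(traits), length(outs),
                dimnames = list(traits, outs))
  sig <- matrix(NA, length(traits), length(outs),
                dimnames = list(traits, outs))
  idx <- cbind(match(sub$trait_id, traits), match(sub$outcome_id, outs))
  est[idx] <- sub$beta
  sig[idx] <- sub$significant
  list(estimate = est, significant = sig)
}

#' Write screen results, rankings and diagnostics as TSV files
#'
#' @param screen a `screen_result`.
#' @param bma_fits named list of `mr_bma_fit` objects (may be empty).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(screen, bma_fits = list(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(as.data.frame(screen), file.path(dir, "screen.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attr(screen, "skips"), file.path(dir, "skips.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (method in unique(screen$method)) {
    for (category in unique(screen$category)) {
      hm <- export_heatmap_matrix(screen, method, category)
      out <- data.frame(trait_id = rownames(hm$estimate), hm$estimate,
                        check.names = FALSE)
      utils::write.table(out,
                         file.path(dir, sprintf("heatmap_%s_%s.tsv", method,
                                                gsub("[^A-Za-z0-9]", "_",
                                                     category))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (nm in names(bma_fits)) {
    fit <- bma_fits[[nm]]
    if (is.null(fit)) next
    stem <- gsub("[^A-Za-z0-9]", "_", nm)
    utils::write.table(fit$pre$ranking,
                       file.path(dir, sprintf("bma_%s_ranking_pre.tsv", stem)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$post$ranking,
                       file.path(dir, sprintf("bma_%s_ranking_post.tsv", stem)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$diagnostics,
                       file.path(dir, sprintf("bma_%s_diagnostics.tsv", stem)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(fit$post$best_models,
                       file.path(dir, sprintf("bma_%s_models.tsv", stem)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Run the whole two-stage study
#'
#' Univariable screen of every exposure against every outcome, then MR-BMA
#' on the requested (category, outcome) combinations, with all results
#' written under `out_dir`.
#'
#' @param study a `study` from [load_study()] (or a list with the same
#'   shape).
#' @param bma_targets data frame with columns `category` and `outcome_id`
#'   naming the model-averaging runs; `NULL` skips the BMA stage.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param permute compute permutation p-values in the BMA stage.
#' @return List: `screen`, `bma` (named list of fits), `out_dir`.
#' @export
run_study <- function(study, bma_targets = NULL, out_dir = NULL,
                      permute = FALSE) {
  screen <- run_univariable_screen(study$exposures, study$outcomes,
                                   ld = study$ld, params = study$params)
  bma_fits <- list()
  if (!is.null(bma_targets)) {
    for (i in seq_len(nrow(bma_targets))) {
      category <- bma_targets$category[i]
      outcome_id <- bma_targets$outcome_id[i]
      nm <- paste(category, outcome_id, sep = "|")
      bma_fits[[nm]] <- tryCatch(
        run_bma_stage(study$exposures, study$outcomes[[outcome_id]], screen,
                      category, outcome_id, ld = study$ld,
                      params = study$params, permute = permute),
        error = function(e) {
          warning("MR-BMA stage '", nm, "' failed: ", conditionMessage(e))
          NULL
        })
    }
  }
  if (!is.null(out_dir)) write_results(screen, bma_fits, out_dir)
  list(screen = screen, bma = bma_fits, out_dir = out_dir)
}
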