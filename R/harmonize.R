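COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) COMPLEMENT[ea] == oa

#' Harmonize exposure and outcome summary statistics to a shared effect allele
#'
#' Aligns each overlapping SNP so the outcome effect refers to the exposure's
#' effect allele. Directly matching alleles pass through; swapped alleles
#' negate the outcome beta and reflect its allele frequency; strand-complement
#' alleles are complemented and re-matched. Palindromic SNPs (A/T or C/G),
#' whose strand cannot be resolved from the allele letters, are oriented by
#' allele-frequency agreement when both frequencies are well away from 0.5
#' (under `infer_by_eaf`), and dropped otherwise. Exposure effects are never
#' altered; only the outcome beta's sign and the outcome frequency can change.
#'
#' @param exposure,outcome [assoc_set()] objects sharing some SNP ids.
#' @param palindrome_policy `"infer_by_eaf"` (default) or `"drop_all"`.
#' @param eaf_window palindromic SNPs are unresolvable when either allele
#'   frequency lies within `0.5 +/- eaf_window` (default 0.08).
#' @return A data frame of harmonized instruments with columns `snp`,
#'   `beta_x`, `se_x`, `pval_x`, `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `chr`,
#'   `pos`, `action`. Rows with a `dropped_*` action carry `NA` effects and
#'   are excluded by the estimators; the attribute `action_counts` tallies
#'   every action.
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_policy = c("infer_by_eaf", "drop_all"),
                      eaf_window = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  shared <- intersect(exposure$snp, outcome$snp)
  if (length(shared) == 0L) {
    stop("no overlapping SNPs between exposure and outcome", call. = FALSE)
  }
  ex <- as.data.frame(exposure)[match(shared, exposure$snp), ]
  out <- as.data.frame(outcome)[match(shared, outcome$snp), ]

  n <- length(shared)
  action <- character(n)
  beta_y <- out$beta
  eaf_y <- out$eaf

  for (i in seq_len(n)) {
    res <- align_alleles(ex$ea[i], ex$oa[i], out$ea[i], out$oa[i],
                         ex$eaf[i], out$eaf[i],
                         palindrome_policy, eaf_window)
    action[i] <- res$action
    if (res$flip) {
      beta_y[i] <- -beta_y[i]
      eaf_y[i] <- 1 - eaf_y[i]
    }
  }

  kept <- !startsWith(action, "dropped")
  res <- data.frame(
    snp = shared,
    beta_x = ex$beta, se_x = ex$se, pval_x = ex$pval,
    beta_y = ifelse(kept, beta_y, NA_real_),
    se_y = ifelse(kept, out$se, NA_real_),
    eaf_x = ex$eaf, eaf_y = ifelse(kept, eaf_y, NA_real_),
    chr = ex$chr, pos = ex$pos,
    action = action,
    stringsAsFactors = FALSE
  )
  attr(res, "action_counts") <- table(factor(
    action, levels = c("kept", "allele_swapped", "strand_flipped",
                       "dropped_palindromic", "dropped_incompatible")))
  class(res) <- c("harmonized", "data.frame")
  res
}

# Decide orientation for one SNP. Returns the action label and whether the
# outcome beta must be sign-flipped (with eaf reflected).
align_alleles <- function(ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y,
                          palindrome_policy, eaf_window) {
  ok <- function(a) !is.na(a) && a %in% VALID_ALLELES
  if (!ok(ea_x) || !ok(oa_x) || !ok(ea_y) || !ok(oa_y)) {
    return(list(action = "dropped_incompatible", flip = FALSE))
  }
  if (is_palindromic(ea_x, oa_x)) {
    if (palindrome_policy == "drop_all") {
      return(list(action = "dropped_palindromic", flip = FALSE))
    }
    # Letters alone cannot fix the strand: a direct match could be a true
    # match or an opposite-strand swap. Use frequency agreement.
    apparent_flip <- if (ea_y == ea_x && oa_y == oa_x) {
      FALSE
    } else if (ea_y == oa_x && oa_y == ea_x) {
      TRUE
    } else {
      return(list(action = "dropped_incompatible", flip = FALSE))
    }
    if (is.na(eaf_x) || is.na(eaf_y)) {
      return(list(action = "dropped_palindromic", flip = FALSE))
    }
    eaf_aligned <- if (apparent_flip) 1 - eaf_y else eaf_y
    ambiguous <- abs(eaf_x - 0.5) <= eaf_window ||
      abs(eaf_aligned - 0.5) <= eaf_window
    if (ambiguous) {
      return(list(action = "dropped_palindromic", flip = FALSE))
    }
    flip <- if ((eaf_x < 0.5) == (eaf_aligned < 0.5)) {
      apparent_flip
    } else {
      # Frequencies disagree: the files sit on opposite strands, so the
      # apparent orientation is inverted.
      !apparent_flip
    }
    return(list(action = if (flip) "allele_swapped" else "kept", flip = flip))
  }
  if (ea_y == ea_x && oa_y == oa_x) {
    return(list(action = "kept", flip = FALSE))
  }
  if (ea_y == oa_x && oa_y == ea_x) {
    return(list(action = "allele_swapped", flip = TRUE))
  }
  ea_c <- COMPLEMENT[[ea_y]]
  oa_c <- COMPLEMENT[[oa_y]]
  if (ea_c == ea_x && oa_c == oa_x) {
    return(list(action = "strand_flipped", flip = FALSE))
  }
  if (ea_c == oa_x && oa_c == ea_x) {
    return(list(action = "strand_flipped", flip = TRUE))
  }
  list(action = "dropped_incompatible", flip = FALSE)
}

#' Keep only successfully harmonized instruments
#'
#' @param h output of [harmonize()].
#' @return The rows whose action is not `dropped_*`.
#' @export
harmonized_kept <- function(h) {
  h[!startsWith(h$action, "dropped"), , drop = FALSE]
}
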