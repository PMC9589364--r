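# Native column order for summary-statistic tables on disk.
NATIVE_COLS <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
MANDATORY_COLS <- c("snp", "ea", "oa", "beta", "se", "pval")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct an association set
#'
#' An association set is a data frame of per-SNP summary statistics for a
#' single trait (one GWAS), carrying the trait's identity as attributes.
#' Columns follow the native dialect: `snp`, `chr`, `pos`, `ea` (effect
#' allele), `oa` (other allele), `eaf`, `beta`, `se`, `pval`, `n`.
#'
#' @param records data frame with at least the mandatory columns
#'   (`snp`, `ea`, `oa`, `beta`, `se`, `pval`).
#' @param trait_id short machine identifier for the trait.
#' @param trait_label human-readable trait name.
#' @param category trait category label (e.g. "triglycerides") or "outcome".
#' @param validate drop records violating the record invariants and record
#'   drop counts (default `TRUE`).
#' @return A data frame of class `assoc_set` with attributes `trait_id`,
#'   `trait_label`, `category`, `n_dropped` and `drop_log`.
#' @export
assoc_set <- function(records, trait_id, trait_label = trait_id,
                      category = "unclassified", validate = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(MANDATORY_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(NATIVE_COLS, names(records))) records[[col]] <- NA
  records <- as.data.frame(records)[NATIVE_COLS]
  records$snp <- as.character(records$snp)
  records$chr <- as.character(records$chr)
  records$ea <- toupper(as.character(records$ea))
  records$oa <- toupper(as.character(records$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  drop_log <- character(0)
  if (validate) {
    checked <- validate_records(records)
    records <- checked$records
    drop_log <- checked$drop_log
  }
  if (anyDuplicated(records$snp)) {
    dup <- duplicated(records$snp)
    drop_log <- c(drop_log, stats::setNames(rep("duplicate_snp_id", sum(dup)),
                                            records$snp[dup]))
    records <- records[!dup, , drop = FALSE]
  }
  if (nrow(records) == 0L) {
    stop("no valid summary-statistic rows for trait '", trait_id, "'",
         call. = FALSE)
  }
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_label = trait_label,
            category = category,
            n_dropped = length(drop_log), drop_log = drop_log,
            class = c("assoc_set", "data.frame"))
}

# Row-level invariant checks; returns kept records and a named drop log.
validate_records <- function(records) {
  reason <- rep(NA_character_, nrow(records))
  bad_core <- is.na(records$snp) | records$snp == "" |
    is.na(records$beta) | is.na(records$se) | is.na(records$pval)
  reason[bad_core] <- "missing_mandatory_value"
  bad_allele <- is.na(reason) &
    (!(records$ea %in% VALID_ALLELES) | !(records$oa %in% VALID_ALLELES))
  reason[bad_allele] <- "non_snv_allele"
  same_allele <- is.na(reason) & records$ea == records$oa
  reason[same_allele] <- "identical_alleles"
  bad_se <- is.na(reason) & records$se <= 0
  reason[bad_se] <- "nonpositive_se"
  bad_p <- is.na(reason) & (records$pval <= 0 | records$pval > 1)
  reason[bad_p] <- "pval_out_of_range"
  bad_eaf <- is.na(reason) & !is.na(records$eaf) &
    (records$eaf < 0 | records$eaf > 1)
  reason[bad_eaf] <- "eaf_out_of_range"
  # p-value must agree with the Wald z within 10% on the -log10 scale; only
  # assessed away from p ~ 1 (log scale uninformative) and away from the
  # double-precision underflow region where stored p-values are clamped.
  lp_stated <- -log10(records$pval)
  lp_wald <- -stats::pnorm(abs(records$beta / records$se), lower.tail = FALSE,
                           log.p = TRUE) / log(10) - log10(2)
  checkable <- is.na(reason) & !is.na(lp_wald) &
    pmin(lp_stated, lp_wald) > 1 & pmax(lp_stated, lp_wald) < 290
  inconsistent <- checkable &
    abs(lp_stated - lp_wald) > 0.1 * pmax(lp_stated, lp_wald)
  reason[inconsistent] <- "pval_wald_mismatch"

  keep <- is.na(reason)
  list(records = records[keep, , drop = FALSE],
       drop_log = stats::setNames(reason[!keep], records$snp[!keep]))
}

#' @export
print.assoc_set <- function(x, ...) {
  cat(sprintf("<assoc_set> %s (%s, category: %s): %d SNPs, %d dropped at read\n",
              attr(x, "trait_id"), attr(x, "trait_label"),
              attr(x, "category"), nrow(x), attr(x, "n_dropped")))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Read a GWAS summary-statistics table
#'
#' Reads a delimited text table of per-SNP association statistics, maps its
#' columns onto the native dialect, validates each row against the record
#' invariants (alleles in A/C/G/T and distinct, `se > 0`, `pval` in (0,1],
#' `eaf` in \[0,1\] when present, p-value consistent with the Wald z) and
#' drops violating rows with a per-row reason.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect named character vector mapping native column names to the
#'   file's column names, e.g. `c(snp = "variant_id", ea = "effect_allele")`.
#'   Unmapped native names are looked up verbatim. `NULL` means the file is
#'   already in the native dialect.
#' @param trait_id,trait_label,category trait identity (see [assoc_set()]).
#' @param sep field separator (default tab).
#' @return An [assoc_set()].
#' @export
read_sumstats <- function(path, dialect = NULL, trait_id = basename(path),
                          trait_label = trait_id, category = "unclassified",
                          sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "")
  if (nrow(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  mapping <- stats::setNames(NATIVE_COLS, NATIVE_COLS)
  if (!is.null(dialect)) {
    dialect <- unlist(dialect)
    unknown <- setdiff(names(dialect), NATIVE_COLS)
    if (length(unknown) > 0L) {
      stop("dialect maps unknown native column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    mapping[names(dialect)] <- dialect
  }
  missing_map <- setdiff(mapping[MANDATORY_COLS], names(raw))
  if (length(missing_map) > 0L) {
    stop("file ", path, " lacks mandatory column(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (native in NATIVE_COLS) {
    src <- mapping[[native]]
    records[[native]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  assoc_set(records, trait_id = trait_id, trait_label = trait_label,
            category = category)
}

#' Write an association set in the native dialect
#'
#' Writes a tab-separated table with the fixed native header
#' (`snp chr pos ea oa eaf beta se pval n`); reading it back with
#' [read_sumstats()] round-trips the records.
#'
#' @param x an [assoc_set()] (or compatible data frame).
#' @param path output file path.
#' @export
write_sumstats <- function(x, path) {
  out <- as.data.frame(x)[NATIVE_COLS]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}
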