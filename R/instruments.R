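#' Instrument-strength F-statistic
#'
#' The squared Wald z of the SNP-exposure association, `(beta/se)^2`.
#' Instruments with F below 10 are conventionally considered weak.
#'
#' @param beta per-allele effect estimate(s).
#' @param se standard error(s), strictly positive.
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Construct an LD matrix
#'
#' @param r2 symmetric matrix of pairwise squared correlations in \[0,1\]
#'   with unit diagonal; dimnames give the SNP ids.
#' @return The validated matrix with class `ld_matrix`.
#' @export
ld_matrix <- function(r2) {
  stopifnot(is.matrix(r2), nrow(r2) == ncol(r2))
  if (is.null(rownames(r2)) || is.null(colnames(r2))) {
    stop("LD matrix needs SNP ids as dimnames", call. = FALSE)
  }
  if (!identical(rownames(r2), colnames(r2))) {
    stop("LD matrix row and column ids differ", call. = FALSE)
  }
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0,1]", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-12)) {
    stop("LD matrix diagonal must be exactly 1", call. = FALSE)
  }
  if (any(abs(r2 - t(r2)) > 1e-12)) {
    stop("LD matrix must be symmetric", call. = FALSE)
  }
  structure(r2, class = c("ld_matrix", "matrix"))
}

#' Read an LD matrix file
#'
#' Accepts either a square matrix with a SNP-id header row and first column,
#' or a 3-column long format (`snp_a`, `snp_b`, `r2`); unlisted pairs in the
#' long format are taken as r2 = 0.
#'
#' @param path path to a tab-separated file.
#' @return An [ld_matrix()].
#' @export
read_ld_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) == 3L && all(c("snp_a", "snp_b", "r2") %in% names(tab))) {
    ids <- sort(unique(c(tab$snp_a, tab$snp_b)))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    ia <- match(tab$snp_a, ids)
    ib <- match(tab$snp_b, ids)
    m[cbind(ia, ib)] <- tab$r2
    m[cbind(ib, ia)] <- tab$r2
    diag(m) <- 1
    return(ld_matrix(m))
  }
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(tab)[-1])
  ld_matrix(m)
}

#' Write an LD matrix in square format
#'
#' @param ld an [ld_matrix()].
#' @param path output path.
#' @export
write_ld_matrix <- function(ld, path) {
  out <- data.frame(snp = rownames(ld), as.data.frame(unclass(ld)),
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# r2 lookup that treats SNPs absent from the panel as independent.
ld_r2_lookup <- function(ld, a, b) {
  if (is.null(ld)) return(0)
  ia <- match(a, rownames(ld))
  ib <- match(b, rownames(ld))
  if (is.na(ia) || is.na(ib)) return(0)
  ld[ia, ib]
}

#' Greedy LD clumping by p-value
#'
#' Retains the most significant remaining SNP, removes every unretained SNP
#' on the same chromosome within `window_kb` whose squared correlation with
#' it is at least `r2_threshold`, and repeats until no SNP is left. Ties on
#' p-value are broken by lexicographic SNP id, so the result does not depend
#' on input row order. SNPs missing from the LD panel are treated as
#' independent and listed in the log.
#'
#' @param records data frame with columns `snp`, `chr`, `pos`, `pval`.
#' @param ld an [ld_matrix()] or `NULL` (all SNPs independent).
#' @param r2_threshold clumping threshold on squared correlation
#'   (default 0.001).
#' @param window_kb half-width of the distance window in kilobases
#'   (default 10000).
#' @return List with `kept` (character vector of retained SNP ids),
#'   `selection_log` (data frame: `snp`, `reason`; clumped SNPs are tagged
#'   `clumped-by:<index snp>`) and `missing_from_ld`.
#' @export
ld_clump <- function(records, ld = NULL, r2_threshold = 0.001,
                     window_kb = 10000) {
  stopifnot(r2_threshold > 0, r2_threshold < 1)
  records <- as.data.frame(records)
  ord <- order(records$pval, records$snp)
  records <- records[ord, , drop = FALSE]

  missing_ld <- if (is.null(ld)) {
    records$snp
  } else {
    setdiff(records$snp, rownames(ld))
  }

  n <- nrow(records)
  status <- rep(NA_character_, n)  # NA = undecided, "" = kept, else index snp
  pos <- records$pos
  chr <- records$chr
  for (i in seq_len(n)) {
    if (!is.na(status[i])) next
    status[i] <- ""
    if (i == n) break
    for (j in seq.int(i + 1L, n)) {
      if (!is.na(status[j])) next
      same_chr <- !is.na(chr[i]) && !is.na(chr[j]) && chr[i] == chr[j]
      within <- same_chr && !is.na(pos[i]) && !is.na(pos[j]) &&
        abs(pos[i] - pos[j]) <= window_kb * 1000
      if (within &&
          ld_r2_lookup(ld, records$snp[i], records$snp[j]) >= r2_threshold) {
        status[j] <- records$snp[i]
      }
    }
  }
  kept <- records$snp[status == ""]
  clumped <- which(status != "")
  log <- data.frame(snp = records$snp[clumped],
                    reason = if (length(clumped) > 0L) {
                      paste0("clumped-by:", status[clumped])
                    } else character(0),
                    stringsAsFactors = FALSE)
  list(kept = kept, selection_log = log, missing_from_ld = missing_ld)
}

#' Select instrumental variables for one trait
#'
#' Applies, in order: the genome-wide significance filter
#' (`pval < p_threshold`), greedy LD clumping ([ld_clump()]), and the
#' instrument-strength filter (`F >= f_threshold` with
#' F = `(beta/se)^2`).
#'
#' @param assoc an [assoc_set()].
#' @param ld an [ld_matrix()] or `NULL`.
#' @param p_threshold significance threshold (default `5e-8`).
#' @param r2_threshold,window_kb clumping parameters (defaults 0.001 and
#'   10000 kb).
#' @param f_threshold minimum F-statistic (default 10).
#' @return List of class `instrument_set`: `trait_id`, `instruments` (the
#'   retained records), `selection_log` (per-SNP exclusion reasons:
#'   `p-fail`, `clumped-by:<snp>`, `weak-F`), `stage_counts` and
#'   `missing_from_ld`.
#' @export
select_instruments <- function(assoc, ld = NULL, p_threshold = 5e-8,
                               r2_threshold = 0.001, window_kb = 10000,
                               f_threshold = 10) {
  rec <- as.data.frame(assoc)
  sig <- rec$pval < p_threshold
  log <- data.frame(snp = rec$snp[!sig], reason = "p-fail",
                    stringsAsFactors = FALSE)
  rec <- rec[sig, , drop = FALSE]

  missing_ld <- character(0)
  if (nrow(rec) > 0L) {
    cl <- ld_clump(rec, ld, r2_threshold = r2_threshold,
                   window_kb = window_kb)
    log <- rbind(log, cl$selection_log)
    missing_ld <- cl$missing_from_ld
    rec <- rec[rec$snp %in% cl$kept, , drop = FALSE]
  }

  strong <- f_statistic(rec$beta, rec$se) >= f_threshold
  if (any(!strong)) {
    log <- rbind(log, data.frame(snp = rec$snp[!strong], reason = "weak-F",
                                 stringsAsFactors = FALSE))
  }
  rec <- rec[strong, , drop = FALSE]
  rec <- rec[order(rec$snp), , drop = FALSE]
  rownames(rec) <- NULL

  structure(list(
    trait_id = attr(assoc, "trait_id"),
    instruments = rec,
    selection_log = log,
    stage_counts = c(input = sum(!is.na(sig)) + 0L, significant = sum(sig),
                     post_clump = sum(sig) - sum(grepl("^clumped", log$reason)),
                     retained = nrow(rec)),
    missing_from_ld = missing_ld
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d instruments (%s)\n", x$trait_id,
              nrow(x$instruments),
              paste(names(x$stage_counts), x$stage_counts,
                    sep = "=", collapse = ", ")))
  invisible(x)
}
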