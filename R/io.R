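#' Read a two-context GWAS summary-statistics table
#'
#' Tab-separated file with '#'-prefixed comment lines and header columns
#' `variant_id`, `beta_A`, `se_A`, `n_A`, `beta_B`, `se_B`, `n_B`; allele
#' frequency columns `af_A`, `af_B` are optional (required only for
#' combination-weight approximation in [decision_screen()]). Rows with
#' non-positive standard errors or out-of-range allele frequencies are
#' dropped with a warning; duplicated variant ids are an error.
#'
#' @param path File path.
#' @return Validated data frame.
#' @export
read_sumstats <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  req <- c("variant_id", "beta_A", "se_A", "n_A", "beta_B", "se_B", "n_B")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$variant_id))
    stop("duplicate variant_id values in ", path)
  ok <- is.finite(tab$se_A) & tab$se_A > 0 & is.finite(tab$se_B) & tab$se_B > 0
  for (af in intersect(c("af_A", "af_B"), names(tab)))
    ok <- ok & (is.na(tab[[af]]) | (tab[[af]] > 0 & tab[[af]] < 1))
  if (!all(ok)) {
    warning(sprintf("dropping %d invalid row(s) (non-positive se or out-of-range af)",
                    sum(!ok)))
    tab <- tab[ok, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Write a table as TSV with a provenance comment header
#'
#' Output starts with '#'-prefixed comment lines recording the package
#' version and any supplied parameters (including the seed), so every run is
#' self-describing; [read_sumstats()] and plain `read.delim(comment.char =
#' "#")` skip them.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @param params Named list of parameters to record.
#' @return `path`, invisibly.
#' @export
write_tsv_provenance <- function(tab, path, params = list()) {
  ver <- as.character(utils::packageVersion("gxetradeoff"))
  hdr <- c(sprintf("# gxetradeoff %s", ver),
           vapply(names(params), function(k)
             sprintf("# %s = %s", k, paste(format(params[[k]]), collapse = ",")),
             character(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Synthetic paired standard-error table
#'
#' Generates paired (control, high-sugar) per-variant standard errors from a
#' bivariate log-normal. This is a synthetic stand-in for an external
#' experiment's standard-error table: it reproduces the paired, right-skewed
#' character of per-variant GWAS standard errors, not any particular
#' study's values. The default location (median se 0.15 on the effect scale
#' of [flysim_config()]) is chosen so that roughly 1% of variants in the
#' amplification simulation reach per-diet significance at q < 0.01,
#' matching the power scale of the motivating longevity experiment.
#'
#' @param p Number of variants.
#' @param log_mean Mean of log standard errors.
#' @param log_sd Standard deviation of log standard errors (0 for constant
#'   ses).
#' @param pair_corr Correlation of the two log standard errors.
#' @param seed Optional seed.
#' @return Data frame with positive columns `se_c`, `se_h`.
#' @export
synthetic_se_fixture <- function(p, log_mean = log(0.15), log_sd = 0.4,
                                 pair_corr = 0.8, seed = NULL) {
  stopifnot(p >= 1, log_sd >= 0, pair_corr >= -1, pair_corr <= 1)
  maybe_seed(seed)
  cov <- log_sd^2 * matrix(c(1, pair_corr, pair_corr, 1), 2, 2)
  z <- rbvn(p, mean = c(log_mean, log_mean), cov = cov)
  data.frame(se_c = exp(z[, 1]), se_h = exp(z[, 2]))
}
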