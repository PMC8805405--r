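#' Rank candidates by wRMSD (similarity ranking)
#'
#' Ascending by score: rank 1 is the smallest wRMSD (the candidate whose
#' CDR ensemble best reproduces the murine reference). Ties share the
#' smaller rank and the next rank is skipped.
#'
#' @param scores data.frame with columns `candidate_id` and `wrmsd`.
#' @return the same data.frame sorted ascending with an added
#'   `similarity_ranking` column.
#' @export
rankByWrmsd <- function(scores) {
  if (!nrow(scores)) stop("no scores to rank", call. = FALSE)
  if (!all(c("candidate_id", "wrmsd") %in% names(scores)))
    stop("scores needs columns 'candidate_id' and 'wrmsd'", call. = FALSE)
  scores$similarity_ranking <- rank(scores$wrmsd, ties.method = "min")
  out <- scores[order(scores$wrmsd, scores$candidate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

checkPanel <- function(panel) {
  need <- c("candidate_id", "wrmsd", "value")
  if (!all(need %in% names(panel)))
    stop("affinity panel needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(panel$censored)) panel$censored <- FALSE
  panel$censored <- as.logical(panel$censored)
  if (is.null(panel$units)) panel$units <- ""
  if (is.null(panel$measure)) panel$measure <- ""
  if (any(panel$value <= 0))
    stop("affinity values must be positive", call. = FALSE)
  if (length(unique(panel$units)) > 1L)
    stop("mixed units in one panel (",
         paste(unique(panel$units), collapse = ", "),
         "); convert explicitly before fitting", call. = FALSE)
  if (length(unique(panel$measure)) > 1L)
    stop("mixed measures in one panel (",
         paste(unique(panel$measure), collapse = ", "), ")", call. = FALSE)
  panel
}

#' Log-linear regression of affinity on wRMSD
#'
#' Ordinary least squares of `log10(affinity)` on the wRMSD score.
#' Censored records (values reported as a bound, e.g. "> 1000") are
#' excluded by default; `includeCensored = TRUE` substitutes the bound.
#' R-squared is the squared Pearson correlation and is invariant to the
#' logarithm base; slope and intercept are reported in base 10.
#'
#' @param panel data.frame with columns `candidate_id`, `wrmsd`, `value`
#'   and optionally `measure`, `units`, `censored`.
#' @param includeCensored substitute censored bounds instead of dropping
#'   them.
#' @return a [CorrelationFit-class].
#' @examples
#' p <- readAffinityPanel(system.file("extdata", "anti_gpc3_ec50.tsv",
#'                                    package = "humanizeAb"))
#' fitLogAffinity(p)
#' @export
fitLogAffinity <- function(panel, includeCensored = FALSE) {
  panel <- checkPanel(panel)
  if (!includeCensored) panel <- panel[!panel$censored, , drop = FALSE]
  if (nrow(panel) < 2L)
    stop("need at least 2 uncensored matched records", call. = FALSE)
  if (stats::var(panel$wrmsd) == 0)
    stop("zero variance in wrmsd; regression undefined", call. = FALSE)
  fit <- stats::lm(log10(value) ~ wrmsd, data = panel)
  r2 <- stats::cor(panel$wrmsd, log10(panel$value))^2
  new("CorrelationFit", slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      rSquared = unname(r2), nPoints = nrow(panel), logBase = 10)
}

#' Predict affinity from a fitted log-linear relation
#'
#' @param fit a [CorrelationFit-class].
#' @param wrmsd numeric score(s).
#' @return predicted affinity in the panel's units:
#'   `10^(slope * wrmsd + intercept)`.
#' @export
predictAffinity <- function(fit, wrmsd) {
  10^(fit@slope * wrmsd + fit@intercept)
}

#' Read / write an affinity panel TSV
#'
#' Columns: `candidate_id`, `wrmsd`, `measure` (`EC50`/`KD`), `value`,
#' `units`, `censored` (logical; a value reported as "> x" is stored as x
#' with `censored = TRUE`).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readAffinityPanel <- function(path) {
  tb <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  checkPanel(tb)
}

#' @rdname readAffinityPanel
#' @param panel data.frame as above.
#' @param header optional `# `-prefixed comment lines.
#' @export
writeAffinityPanel <- function(panel, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(sprintf("# %s", header), con)
  utils::write.table(panel, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
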