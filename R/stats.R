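# Cohort-level statistics: signal-quality filtering, LogMAR conversion and
# correlation inference. Group comparisons with inter-eye clustering live in
# gee.R.

#' Filter a cohort by signal quality
#'
#' Removes eye-layer rows whose signal-quality index falls below the
#' threshold (the usual acceptance rule keeps scans with SQ >= 6). The
#' removal is logged in the `"removed"` attribute.
#'
#' @param cohort a `cohort_table` data frame with an `sq` column.
#' @param threshold minimum acceptable SQ (default 6).
#' @return The filtered cohort; attribute `"removed"` holds counts of
#'   dropped rows and subjects fully excluded.
#' @export
quality_filter <- function(cohort, threshold = 6L) {
  stopifnot(is.data.frame(cohort), "sq" %in% names(cohort))
  bad <- cohort$sq < threshold
  out <- cohort[!bad, , drop = FALSE]
  lost_subjects <- setdiff(unique(cohort$subject_id), unique(out$subject_id))
  attr(out, "removed") <- list(rows = sum(bad),
                               subjects = lost_subjects,
                               threshold = threshold)
  if (nrow(out) == 0) warning("quality filter removed every row")
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Convert a visual-acuity record to LogMAR
#'
#' Accepts Snellen fractions (`"20/40"` or `list(type = "snellen", num, den)`),
#' finger counting (`"CF"` / `list(type = "counting_fingers")`), or a numeric
#' LogMAR value (passed through). Snellen `a/b` maps to `log10(b/a)`; finger
#' counting maps to a configured constant.
#'
#' @param va a number, a string, or a list record as above.
#' @param counting_fingers_logmar LogMAR assigned to finger counting
#'   (default 1.85, in line with low-vision conversion charts).
#' @return LogMAR as a single number.
#' @examples
#' to_logmar("20/20")   # 0
#' to_logmar("20/200")  # 1
#' @export
to_logmar <- function(va, counting_fingers_logmar = 1.85) {
  if (is.numeric(va) && length(va) == 1) return(as.numeric(va))
  if (is.character(va) && length(va) == 1) {
    if (toupper(trimws(va)) %in% c("CF", "COUNTING_FINGERS"))
      return(counting_fingers_logmar)
    if (grepl("^\\s*\\d+\\s*/\\s*\\d+\\s*$", va)) {
      parts <- as.numeric(strsplit(va, "/")[[1]])
      va <- list(type = "snellen", num = parts[1], den = parts[2])
    } else stop("unrecognized visual-acuity record: ", va)
  }
  if (is.list(va)) {
    type <- va$type
    if (identical(type, "counting_fingers")) return(counting_fingers_logmar)
    if (identical(type, "snellen")) {
      if (va$num <= 0 || va$den <= 0) stop("Snellen terms must be positive")
      return(log10(va$den / va$num))
    }
    if (identical(type, "logmar")) return(as.numeric(va$value))
  }
  stop("unrecognized visual-acuity record")
}

#' Correlation inference from summary statistics
#'
#' Given a correlation coefficient and a sample size, computes the t
#' statistic `t = r sqrt(n - 2) / sqrt(1 - r^2)` and the two-sided p-value
#' from the t distribution with `n - 2` degrees of freedom. This is the
#' standard test behind printed `(Rho, p)` pairs, and (as the usual
#' large-sample approximation) applies to Spearman coefficients as well.
#'
#' @param r correlation in \[-1, 1\].
#' @param n number of pairs (>= 3).
#' @param method label stored in the result (`"pearson"` or `"spearman"`).
#' @return A list of class `correlation_result`: `method`, `r`, `n`,
#'   `t_statistic`, `p_value`, `degenerate` (TRUE when `|r| = 1`).
#' @examples
#' p_from_r(-0.475, 34)$p_value  # ~0.005
#' @export
p_from_r <- function(r, n, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  n <- as.integer(n)
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| must be <= 1")
  degenerate <- abs(r) == 1
  if (degenerate) {
    t_stat <- Inf * sign(r)
    p <- 0
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  structure(list(method = method, r = r, n = n, t_statistic = t_stat,
                 p_value = p, degenerate = degenerate),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s r = %.3f, n = %d, p = %.4g%s\n",
              x$method, x$r, x$n, x$p_value,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

#' Correlate two cohort columns
#'
#' Computes the correlation between two columns of a cohort table at the
#' requested unit of analysis, then derives the p-value via [p_from_r()].
#' At the subject unit both eyes are averaged first (the convention when the
#' clinical covariate, e.g. EDSS, exists once per subject).
#'
#' @param cohort a `cohort_table` data frame.
#' @param x,y column names.
#' @param method `"pearson"` or `"spearman"`.
#' @param unit `"subject"` (average the eyes) or `"eye"`.
#' @param subset optional logical vector (evaluated against `cohort`) or
#'   expression-free filter applied before analysis.
#' @param layer optional capillary layer to restrict to.
#' @return A `correlation_result`.
#' @export
correlate <- function(cohort, x, y, method = c("pearson", "spearman"),
                      unit = c("subject", "eye"), subset = NULL,
                      layer = NULL) {
  method <- match.arg(method)
  unit <- match.arg(unit)
  stopifnot(is.data.frame(cohort), x %in% names(cohort), y %in% names(cohort))
  tab <- as.data.frame(cohort)
  if (!is.null(subset)) {
    stopifnot(is.logical(subset), length(subset) == nrow(tab))
    tab <- tab[subset, , drop = FALSE]
  }
  if (!is.null(layer)) tab <- tab[tab$layer == layer, , drop = FALSE]
  tab <- tab[stats::complete.cases(tab[, c(x, y)]), , drop = FALSE]
  if (unit == "subject" && "subject_id" %in% names(tab)) {
    xs <- tapply(tab[[x]], tab$subject_id, mean)
    ys <- tapply(tab[[y]], tab$subject_id, mean)
    xv <- as.numeric(xs); yv <- as.numeric(ys)
  } else {
    xv <- tab[[x]]; yv <- tab[[y]]
  }
  if (length(xv) < 3) stop("fewer than 3 complete pairs")
  r <- stats::cor(xv, yv, method = method)
  if (is.na(r)) stop("correlation undefined (zero variance)")
  out <- p_from_r(r, length(xv), method)
  if (identical(x, y)) out$degenerate <- TRUE
  out
}
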