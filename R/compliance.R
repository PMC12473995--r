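#' Single-factor grade of one indicator value
#'
#' Looks a concentration up in the scheme's grade intervals, `(lower,
#' upper]` with the grade-I regulatory bound inclusive. Values beyond
#' the grade-V outer bound (above it for cost indicators, below it for
#' DO) are still graded V and flagged `exceeds_v`.
#'
#' @param x Concentration(s), mg/L, non-negative. Vectorized.
#' @param indicator One of [wq_indicators()].
#' @param scheme Scheme id or `grade_scheme`.
#' @return Data frame with columns `grade` (integer 1-5),
#'   `grade_label`, `exceeds_v`.
#' @export
#' @examples
#' single_factor_grade(c(0.058, 0.2), "TP", "customized")
single_factor_grade <- function(x, indicator, scheme = "customized") {
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  stopifnot(indicator %in% wq_indicators())
  if (any(is.na(x) | x < 0)) stop("negative or missing concentration for ",
                                  indicator)
  b <- scheme$bounds[scheme$bounds$indicator == indicator, ]
  b <- b[order(b$grade), ]
  if (indicator_polarity()[[indicator]] == "cost") {
    # grade = first k with x <= upper_k; above the last bound -> V+
    grade <- 1L + findInterval(x, b$upper, left.open = TRUE)
    exceeds <- grade > 5L
  } else {
    # DO intervals are (lower, upper] on decreasing bounds, except the
    # grade-I regulatory bound which is inclusive (x >= lower_1)
    grade <- ifelse(
      x >= b$lower[1], 1L,
      6L - findInterval(x, rev(b$lower), left.open = TRUE)
    )
    exceeds <- grade > 5L
  }
  grade <- pmin(grade, 5L)
  data.frame(grade = grade, grade_label = .grade_labels[grade],
             exceeds_v = exceeds, stringsAsFactors = FALSE)
}

#' Worst-factor grade of a sample
#'
#' The classical single-factor evaluation of a whole sample: the worst
#' per-indicator grade decides the class.
#'
#' @param sample Named concentrations (vector or one-row data frame)
#'   covering all five indicators.
#' @param scheme Scheme id or `grade_scheme`.
#' @return List with `grade`, `grade_label`, `exceeds_v`, `by_indicator`
#'   (named integer vector) and `worst_indicator`.
#' @export
#' @examples
#' worst_factor_grade(c(DO = 9.0, TN = 4.54, NH3N = 0.25, TP = 0.09,
#'                      CODMn = 4.51))
worst_factor_grade <- function(sample, scheme = "customized") {
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  if (is.data.frame(sample)) sample <- unlist(sample[1, , drop = TRUE])
  missing <- setdiff(wq_indicators(), names(sample))
  if (length(missing) > 0) {
    stop("missing indicator(s): ", paste(missing, collapse = ", "))
  }
  per <- vapply(wq_indicators(), function(ind) {
    g <- single_factor_grade(as.numeric(sample[[ind]]), ind, scheme)
    c(g$grade, g$exceeds_v)
  }, numeric(2))
  grades <- stats::setNames(as.integer(per[1, ]), wq_indicators())
  grade <- max(grades)
  list(
    grade = grade,
    grade_label = .grade_labels[grade],
    exceeds_v = any(per[2, ] > 0),
    by_indicator = grades,
    worst_indicator = names(grades)[which.max(grades)]
  )
}

#' Stratified compliance and exceedance rates
#'
#' For each stratum (default: reach x section) and indicator, counts
#' the sites whose single-factor grade meets a stated class and reports
#' the compliance rate, the exceedance rate (its complement), and the
#' raw counts behind both. The default class level is III, the usual
#' regulatory reference; pass `class_level = 1` or `2` for the stricter
#' rates.
#'
#' @param samples Data frame of site records or a `water_matrix`.
#' @param scheme Scheme id or `grade_scheme`.
#' @param class_level Grade number defining compliance (default 3).
#' @param by Metadata columns to stratify on; `character(0)` for a
#'   single overall stratum.
#' @param indicators Indicators to report (default all five).
#' @return Data frame of class `compliance_report` with columns
#'   `stratum`, `indicator`, `n`, `n_compliant`, `compliance_rate`,
#'   `exceedance_rate`, `mean`.
#' @export
compliance_stats <- function(samples, scheme = "customized", class_level = 3,
                             by = c("reach", "section"),
                             indicators = wq_indicators()) {
  wm <- if (inherits(samples, "water_matrix")) samples else validate_samples(samples)
  if (is.character(scheme)) scheme <- load_scheme(scheme)
  stopifnot(class_level %in% 1:5)
  strata <- if (length(by) == 0) {
    rep("all", nrow(wm$x))
  } else {
    do.call(paste, c(wm$sites[by], sep = "/"))
  }
  out <- do.call(rbind, lapply(unique(strata), function(s) {
    idx <- which(strata == s)
    if (length(idx) == 0) stop("empty stratum: ", s)
    do.call(rbind, lapply(indicators, function(ind) {
      g <- single_factor_grade(wm$x[idx, ind], ind, scheme)
      n_ok <- sum(g$grade <= class_level)
      data.frame(
        stratum = s, indicator = ind, n = length(idx), n_compliant = n_ok,
        compliance_rate = n_ok / length(idx),
        exceedance_rate = 1 - n_ok / length(idx),
        mean = mean(wm$x[idx, ind]),
        stringsAsFactors = FALSE
      )
    }))
  }))
  rownames(out) <- NULL
  class(out) <- c("compliance_report", class(out))
  out
}

#' Descriptive statistics of the measurement table
#'
#' Per-indicator min, max, mean, sample standard deviation, median and
#' coefficient of variation (CV = sd/mean; flagged undefined when the
#' mean is zero).
#'
#' @param samples Data frame of site records or a `water_matrix`.
#' @return Data frame with one row per indicator.
#' @export
descriptive_stats <- function(samples) {
  wm <- if (inherits(samples, "water_matrix")) samples else validate_samples(samples)
  if (nrow(wm$x) < 2) stop("need at least 2 samples")
  out <- do.call(rbind, lapply(wq_indicators(), function(ind) {
    v <- wm$x[, ind]
    m <- mean(v)
    s <- stats::sd(v)
    data.frame(
      indicator = ind, n = length(v), min = min(v), max = max(v),
      mean = m, sd = s, median = stats::median(v),
      cv = if (m == 0) NA_real_ else s / m,
      cv_undefined = m == 0,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Grade distribution of evaluation results
#'
#' Tabulates grade calls into counts per class I-V and percentages.
#' Percentages are always recomputed from the integer counts
#' (`100 * count / total`), never stored independently; the print
#' method renders them at one decimal.
#'
#' @param grades Integer grades 1-5 (or roman labels), an `fce_result`,
#'   or its `results` data frame.
#' @param by Optional stratum labels, one per grade (e.g. the reach).
#' @return Data frame of class `grade_distribution` with `stratum`,
#'   `grade_label`, `count`, `total`, `percent`.
#' @export
#' @examples
#' grade_distribution(rep(1:5, c(9, 15, 8, 16, 17)))
grade_distribution <- function(grades, by = NULL) {
  if (inherits(grades, "fce_result")) grades <- grades$results
  if (is.data.frame(grades)) {
    if (is.null(by) && "reach" %in% names(grades)) by <- grades$reach
    grades <- grades$grade
  }
  if (is.character(grades)) grades <- match(grades, .grade_labels)
  if (length(grades) == 0) stop("no grades supplied")
  if (any(is.na(grades)) || !all(grades %in% 1:5)) {
    stop("grades must be integers 1-5 or labels I-V")
  }
  if (is.null(by)) by <- rep("all", length(grades))
  out <- do.call(rbind, lapply(unique(by), function(s) {
    g <- grades[by == s]
    counts <- tabulate(g, nbins = 5)
    data.frame(
      stratum = s, grade_label = .grade_labels, count = counts,
      total = length(g), percent = 100 * counts / length(g),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("grade_distribution", class(out))
  out
}

#' @export
print.grade_distribution <- function(x, ...) {
  df <- as.data.frame(x)
  df$percent <- sprintf("%.1f%%", df$percent)
  print(df, row.names = FALSE)
  invisible(x)
}
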