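#' Build the five-grade membership function family for one indicator
#'
#' Each quality grade gets a fuzzy membership function over
#' concentration. The apex (membership 1) of each grade sits at the
#' midpoint of that grade's interval in the scheme; the two end grades
#' use semi-trapezoids that saturate beyond their apex (grade I toward
#' clean water, grade V toward polluted water), and grades II-IV use
#' triangles whose feet lie at the neighbouring apexes. For the
#' unbounded intervals the apex is placed at the regulatory bound
#' itself (DO grade I apex = its grade-I lower bound; a cost
#' indicator's grade-I apex is the midpoint of \[0, t1\]). This
#' construction makes the five functions a partition of unity between
#' the outer apexes.
#'
#' @param scheme A `grade_scheme` from [load_scheme()].
#' @param indicator One of [wq_indicators()]; if missing, functions for
#'   all five indicators are returned as a named list.
#' @return A `membership_functions` object (fields `indicator`,
#'   `polarity`, `apexes` — grade-ordered apex concentrations), or a
#'   named list of them.
#' @export
#' @examples
#' fns <- build_membership_functions(load_scheme("customized"), "TN")
#' fns$apexes
build_membership_functions <- function(scheme, indicator = NULL) {
  validate_scheme(scheme)
  if (is.null(indicator)) {
    fns <- lapply(wq_indicators(), function(ind)
      build_membership_functions(scheme, ind))
    names(fns) <- wq_indicators()
    return(fns)
  }
  stopifnot(indicator %in% wq_indicators())
  b <- scheme$bounds[scheme$bounds$indicator == indicator, ]
  b <- b[order(b$grade), ]
  pol <- indicator_polarity()[[indicator]]
  apexes <- ifelse(is.finite(b$upper), (b$lower + b$upper) / 2, b$lower)
  structure(
    list(indicator = indicator, polarity = pol, apexes = apexes),
    class = "membership_functions"
  )
}

#' @export
print.membership_functions <- function(x, ...) {
  cat("Membership functions for", x$indicator, sprintf("(%s)", x$polarity),
      "\n  apexes (grade I..V):", paste(signif(x$apexes, 6), collapse = ", "),
      "mg/L\n")
  invisible(x)
}

#' Grade membership degrees of one concentration
#'
#' Evaluates the five grade membership functions at a concentration.
#' The result sums to 1 and has at most two nonzero entries: full mass
#' on grade I (or V) beyond the outer apexes, otherwise a linear split
#' between the two grades whose apexes bracket the value.
#'
#' @param x Concentration in mg/L, non-negative scalar.
#' @param fns A `membership_functions` object.
#' @return Numeric vector of length 5 (grades I..V) summing to 1.
#' @export
#' @examples
#' fns <- build_membership_functions(load_scheme("customized"), "TN")
#' membership_vector(0.55, fns)
membership_vector <- function(x, fns) {
  stopifnot(inherits(fns, "membership_functions"), length(x) == 1, !is.na(x))
  if (x < 0) stop("negative concentration for ", fns$indicator)
  # benefit indicators mirror to the cost case via negation
  s <- if (fns$polarity == "benefit") -1 else 1
  a <- s * fns$apexes
  xx <- s * x
  r <- numeric(5)
  if (xx <= a[1]) {
    r[1] <- 1
  } else if (xx >= a[5]) {
    r[5] <- 1
  } else {
    k <- findInterval(xx, a, rightmost.closed = TRUE)
    w <- (xx - a[k]) / (a[k + 1] - a[k])
    r[k] <- 1 - w
    r[k + 1] <- w
  }
  r
}

#' Membership matrix of one sample
#'
#' Stacks the per-indicator membership vectors of a sample into the
#' m x 5 fuzzy relation matrix R (rows: indicators in canonical order;
#' columns: grades I..V). Every row sums to 1.
#'
#' @param sample Named numeric vector or one-row data frame with all
#'   five indicator concentrations, or a row of a `water_matrix`.
#' @param fns Named list of `membership_functions` for all indicators,
#'   from [build_membership_functions()].
#' @return 5 x 5 numeric matrix of class `membership_matrix`.
#' @export
membership_matrix <- function(sample, fns) {
  if (is.data.frame(sample)) sample <- unlist(sample[1, wq_indicators()])
  inds <- wq_indicators()
  missing <- setdiff(inds, names(sample))
  if (length(missing) > 0) {
    stop("missing indicator(s): ", paste(missing, collapse = ", "))
  }
  R <- t(vapply(inds, function(ind)
    membership_vector(as.numeric(sample[[ind]]), fns[[ind]]), numeric(5)))
  dimnames(R) <- list(inds, .grade_labels)
  class(R) <- c("membership_matrix", class(R))
  R
}

#' Long-format export of membership matrices
#'
#' @param R A `membership_matrix`, or a named list of them (per site).
#' @param path Optional CSV path; when given the table is also written.
#' @return Data frame with columns `site_id`, `indicator`, `grade`,
#'   `degree`.
#' @export
membership_long <- function(R, path = NULL) {
  if (inherits(R, "membership_matrix")) R <- list(sample = R)
  out <- do.call(rbind, lapply(names(R), function(id) {
    m <- R[[id]]
    data.frame(
      site_id = id,
      indicator = rep(rownames(m), times = ncol(m)),
      grade = rep(colnames(m), each = nrow(m)),
      degree = as.vector(m),
      stringsAsFactors = FALSE
    )
  }))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
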