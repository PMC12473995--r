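#' Water-quality indicators
#'
#' The five indicators evaluated by the package, in their fixed column
#' order: dissolved oxygen (DO), total nitrogen (TN), ammonia nitrogen
#' (NH3N), total phosphorus (TP) and the permanganate index (CODMn).
#' All are measured in mg/L. DO is a benefit indicator (higher is
#' better); the other four are cost indicators (lower is better).
#'
#' @return Character vector of the five indicator names, in canonical
#'   order.
#' @export
#' @examples
#' wq_indicators()
wq_indicators <- function() {
  c("DO", "TN", "NH3N", "TP", "CODMn")
}

#' @rdname wq_indicators
#' @return `indicator_polarity()` returns a named character vector,
#'   `"benefit"` or `"cost"` per indicator.
#' @export
indicator_polarity <- function() {
  c(DO = "benefit", TN = "cost", NH3N = "cost", TP = "cost", CODMn = "cost")
}

# Grade thresholds for the two built-in schemes. For cost indicators the
# five values are the upper bounds of grades I..V; for DO they are the
# lower bounds of grades I..V (decreasing). The "gb3838" scheme is the
# national surface-water standard; "customized" tightens CODMn and the
# lower DO classes for a drinking-water source.
.builtin_thresholds <- list(
  gb3838 = list(
    DO    = c(7.5, 6.5, 6.0, 3.0, 2.0),
    TN    = c(0.2, 0.5, 1.0, 1.5, 2.0),
    NH3N  = c(0.15, 0.5, 1.0, 1.5, 2.0),
    TP    = c(0.01, 0.025, 0.05, 0.1, 0.2),
    CODMn = c(2.0, 4.0, 6.0, 10.0, 15.0)
  ),
  customized = list(
    DO    = c(7.5, 6.5, 6.0, 5.5, 4.5),
    TN    = c(0.2, 0.5, 1.0, 1.5, 2.0),
    NH3N  = c(0.15, 0.5, 1.0, 1.5, 2.0),
    TP    = c(0.01, 0.025, 0.05, 0.1, 0.2),
    CODMn = c(1.0, 2.0, 3.0, 4.0, 5.0)
  )
)

.grade_labels <- c("I", "II", "III", "IV", "V")

# Expand a threshold list into the interval table used everywhere else.
# Cost indicator: grade 1 = [0, t1], grade k = (t_{k-1}, t_k].
# DO (benefit): grade 1 = [t1, Inf), grade k = (t_{k+1}... ) i.e. half-open
# from below: grade k = (t_k, t_{k-1}] for k >= 2.
.thresholds_to_bounds <- function(thresholds) {
  pol <- indicator_polarity()
  rows <- lapply(wq_indicators(), function(ind) {
    t <- thresholds[[ind]]
    if (pol[[ind]] == "cost") {
      lower <- c(0, t[-5])
      upper <- t
    } else {
      lower <- c(t[1], t[-1])
      upper <- c(Inf, t[-5])
    }
    data.frame(
      indicator = ind, grade = 1:5, lower = lower, upper = upper,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Load a grade scheme
#'
#' A grade scheme maps each indicator to five contiguous concentration
#' intervals, one per quality grade I (cleanest) to V (worst). Two
#' schemes are built in: `"gb3838"`, the GB 3838-2002 surface-water
#' standard, and `"customized"`, a variant for drinking-water-source
#' reservoirs that narrows the CODMn classes (grade I at <= 1.0 mg/L)
#' and the lower DO classes (grade V at (4.5, 5.5] mg/L). A file path to
#' a JSON or YAML scheme written by [write_scheme()] is also accepted.
#'
#' Intervals are half-open `(lower, upper]`; the grade-I regulatory
#' bound is inclusive (TN <= 0.2 mg/L is grade I, DO >= 7.5 mg/L is
#' grade I). Concentrations beyond the grade-V outer bound remain
#' classifiable as grade V and are flagged "exceeds V" by the grading
#' functions.
#'
#' @param scheme_id `"gb3838"`, `"customized"`, or a path to a scheme
#'   file (`.json`, `.yaml`/`.yml`).
#' @return An object of class `grade_scheme`: a list with `scheme_id`
#'   and `bounds`, a data frame with columns `indicator`, `grade`,
#'   `lower`, `upper` (5 rows per indicator).
#' @seealso [write_scheme()], [single_factor_grade()],
#'   [build_membership_functions()]
#' @export
#' @examples
#' sch <- load_scheme("customized")
#' subset(sch$bounds, indicator == "TN")
load_scheme <- function(scheme_id = c("customized", "gb3838")) {
  if (length(scheme_id) == 1 && !scheme_id %in% names(.builtin_thresholds) &&
      file.exists(scheme_id)) {
    return(read_scheme(scheme_id))
  }
  scheme_id <- match.arg(scheme_id)
  sch <- structure(
    list(
      scheme_id = scheme_id,
      bounds = .thresholds_to_bounds(.builtin_thresholds[[scheme_id]])
    ),
    class = "grade_scheme"
  )
  validate_scheme(sch)
}

#' @export
print.grade_scheme <- function(x, ...) {
  cat("Grade scheme:", x$scheme_id, "\n")
  wide <- do.call(rbind, lapply(split(x$bounds, x$bounds$indicator), function(b) {
    b <- b[order(b$grade), ]
    iv <- ifelse(
      is.finite(b$upper),
      sprintf("(%g, %g]", b$lower, b$upper),
      sprintf(">= %g", b$lower)
    )
    iv[1] <- if (is.finite(b$upper[1])) sprintf("<= %g", b$upper[1]) else iv[1]
    stats::setNames(as.data.frame(as.list(iv)), .grade_labels)
  }))
  print(wide[wq_indicators(), ])
  invisible(x)
}

#' Validate a grade scheme
#'
#' Checks that a scheme covers exactly the five canonical indicators,
#' that thresholds move monotonically (increasing with grade number for
#' cost indicators, decreasing for DO) and that the five intervals tile
#' the concentration axis with shared endpoints (no gaps, no overlaps).
#'
#' @param scheme A `grade_scheme` object.
#' @return The scheme, invisibly unchanged, or an error naming the
#'   offending indicator.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "grade_scheme"))
  b <- scheme$bounds
  if (!setequal(unique(b$indicator), wq_indicators())) {
    stop("scheme must define exactly the indicators ",
         paste(wq_indicators(), collapse = ", "))
  }
  pol <- indicator_polarity()
  for (ind in wq_indicators()) {
    bi <- b[b$indicator == ind, ]
    bi <- bi[order(bi$grade), ]
    if (nrow(bi) != 5) {
      stop("indicator ", ind, ": expected 5 grade intervals, got ", nrow(bi))
    }
    if (any(bi$lower >= bi$upper)) {
      stop("indicator ", ind, ": empty or inverted interval")
    }
    if (pol[[ind]] == "cost") {
      if (any(diff(bi$upper) <= 0)) {
        stop("indicator ", ind, ": cost thresholds must strictly increase")
      }
      contiguous <- all(bi$lower[-1] == bi$upper[-5])
    } else {
      if (any(diff(bi$lower) >= 0)) {
        stop("indicator ", ind, ": DO thresholds must strictly decrease")
      }
      contiguous <- all(bi$upper[-1] == bi$lower[-5])
    }
    if (!contiguous) {
      stop("indicator ", ind, ": grade intervals must share endpoints")
    }
  }
  invisible(scheme)
}

#' Write / read a grade scheme as JSON or YAML
#'
#' Serialization round-trips bit-exactly: writing a scheme, reading it
#' back and writing it again yields an identical file.
#'
#' @param scheme A `grade_scheme`.
#' @param path Output (or input) file; format chosen by extension,
#'   `.json` or `.yaml`/`.yml`.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()`
#'   returns a validated `grade_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  validate_scheme(scheme)
  b <- scheme$bounds
  pol <- indicator_polarity()
  payload <- list(
    scheme_id = scheme$scheme_id,
    indicators = lapply(wq_indicators(), function(ind) {
      bi <- b[b$indicator == ind, ]
      bi <- bi[order(bi$grade), ]
      list(
        indicator = ind,
        polarity = unname(pol[[ind]]),
        bounds = lapply(seq_len(5), function(k) {
          c(bi$lower[k], if (is.finite(bi$upper[k])) bi$upper[k] else ".inf")
        })
      )
    })
  )
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(payload, path, precision = 15)
  } else {
    stop("unsupported scheme file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    payload <- yaml::read_yaml(path)
  } else {
    stop("unsupported scheme file extension: ", path)
  }
  rows <- lapply(payload$indicators, function(entry) {
    bounds <- lapply(entry$bounds, function(iv) {
      vapply(iv, function(v) {
        if (identical(v, ".inf") || identical(v, Inf)) Inf else as.numeric(v)
      }, numeric(1))
    })
    data.frame(
      indicator = entry$indicator,
      grade = seq_along(bounds),
      lower = vapply(bounds, `[`, numeric(1), 1),
      upper = vapply(bounds, `[`, numeric(1), 2),
      stringsAsFactors = FALSE
    )
  })
  sch <- structure(
    list(scheme_id = payload$scheme_id, bounds = do.call(rbind, rows)),
    class = "grade_scheme"
  )
  validate_scheme(sch)
  sch
}

#' Assemble and validate a measurement table
#'
#' Takes a data frame of per-site records (columns `site_id`, `reach`,
#' `section`, and the five indicator concentrations in mg/L) and returns
#' a validated n x m measurement matrix with its site metadata. Zero
#' concentrations are accepted (below-detection readings are stored as
#' 0); negative values and missing indicator columns are errors that
#' name the offending site and indicator.
#'
#' @param samples Data frame with one row per site. `reach` must be
#'   `"main"` or `"tributary"`; `section` one of `"upstream"`,
#'   `"midstream"`, `"downstream"`, `"none"`. Missing metadata columns
#'   default to `"main"` / `"none"`.
#' @return An object of class `water_matrix`: list with `sites` (the
#'   metadata data frame) and `x`, the n x 5 numeric matrix in canonical
#'   indicator order.
#' @export
#' @examples
#' df <- data.frame(site_id = c("A", "B"), DO = c(8, 7), TN = c(0.3, 1.2),
#'                  NH3N = c(0.1, 0.2), TP = c(0.02, 0.04), CODMn = c(1, 2))
#' validate_samples(df)
validate_samples <- function(samples) {
  samples <- as.data.frame(samples)
  if (nrow(samples) == 0) stop("no samples supplied")
  inds <- wq_indicators()
  missing_cols <- setdiff(inds, names(samples))
  if (length(missing_cols) > 0) {
    stop("missing indicator column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"site_id" %in% names(samples)) {
    samples$site_id <- sprintf("S%d", seq_len(nrow(samples)))
  }
  if (!"reach" %in% names(samples)) samples$reach <- "main"
  if (!"section" %in% names(samples)) samples$section <- "none"
  if (!all(samples$reach %in% c("main", "tributary"))) {
    stop("reach must be 'main' or 'tributary'")
  }
  if (!all(samples$section %in% c("upstream", "midstream", "downstream", "none"))) {
    stop("section must be upstream, midstream, downstream or none")
  }
  x <- as.matrix(samples[, inds])
  storage.mode(x) <- "double"
  rownames(x) <- samples$site_id
  bad <- which(is.na(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("invalid (negative or missing) concentration: site ",
         samples$site_id[bad[1, 1]], ", indicator ", inds[bad[1, 2]])
  }
  structure(
    list(sites = samples[, c("site_id", "reach", "section")], x = x),
    class = "water_matrix"
  )
}

#' @export
print.water_matrix <- function(x, ...) {
  cat("Water-quality measurement matrix:", nrow(x$x), "sites x",
      ncol(x$x), "indicators (mg/L)\n")
  print(utils::head(cbind(x$sites, as.data.frame(x$x)), 6), row.names = FALSE)
  if (nrow(x$x) > 6) cat("... and", nrow(x$x) - 6, "more sites\n")
  invisible(x)
}
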