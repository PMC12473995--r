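#' Min-max standardization with indicator polarity
#'
#' Rescales each indicator column of a measurement matrix to \[0, 1\].
#' Benefit columns (DO) use `(x - min) / (max - min)`; cost columns use
#' `(max - x) / (max - min)`, so that 1 always means "best observed".
#' A constant column is mapped to all ones: it carries no information,
#' which downstream yields maximal entropy and zero weight.
#'
#' @param x A `water_matrix` from [validate_samples()], or a plain
#'   numeric matrix with indicator columns.
#' @param polarity Named character vector (`"benefit"`/`"cost"`) per
#'   column; defaults to the canonical polarities for named columns.
#' @return Numeric matrix of the same shape with entries in \[0, 1\].
#' @export
standardize_minmax <- function(x, polarity = NULL) {
  if (inherits(x, "water_matrix")) x <- x$x
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two samples to standardize")
  if (is.null(polarity)) {
    polarity <- indicator_polarity()[colnames(x)]
    if (anyNA(polarity)) stop("unknown column names; supply `polarity`")
  }
  out <- x
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j])
    hi <- max(x[, j])
    if (hi == lo) {
      out[, j] <- 1
    } else if (polarity[[j]] == "benefit") {
      out[, j] <- (x[, j] - lo) / (hi - lo)
    } else {
      out[, j] <- (hi - x[, j]) / (hi - lo)
    }
  }
  out
}

#' Information entropy of standardized indicator columns
#'
#' For each column, the sample proportions `p_ij = x*_ij / sum_i x*_ij`
#' are formed and the normalized Shannon entropy
#' `E_j = -(1/ln n) * sum_i p_ij ln p_ij` is returned, with the
#' convention `0 * ln 0 = 0`. `E_j` lies in \[0, 1\]; 1 means the column
#' is uniform across samples (no information).
#'
#' @param std Standardized matrix from [standardize_minmax()].
#' @return Numeric vector of entropies, one per column.
#' @export
compute_entropy <- function(std) {
  std <- as.matrix(std)
  n <- nrow(std)
  if (n < 2) stop("entropy is undefined for fewer than 2 samples")
  k <- 1 / log(n)
  apply(std, 2, function(col) {
    tot <- sum(col)
    if (tot == 0) return(1)  # unreachable under the all-ones constant rule
    p <- col / tot
    terms <- ifelse(p > 0, p * log(p), 0)
    ej <- -k * sum(terms)
    min(max(ej, 0), 1)  # clamp fp jitter at the boundaries
  })
}

#' Entropy weights from column entropies
#'
#' Each indicator's weight is its information content normalized across
#' indicators: `w_j = (1 - E_j) / sum_j (1 - E_j)`. Weights are
#' non-negative and sum to one.
#'
#' @param entropy Numeric vector of entropies in \[0, 1\].
#' @return Numeric vector of weights summing to 1.
#' @export
compute_weights <- function(entropy) {
  if (any(entropy < 0 | entropy > 1)) stop("entropies must lie in [0, 1]")
  info <- 1 - entropy
  tot <- sum(info)
  if (tot <= 0) {
    stop("all indicators have maximal entropy (zero information); ",
         "fall back to uniform weights explicitly, e.g. ",
         "rep(1/m, m)")
  }
  info / tot
}

#' Entropy weight vector for a measurement table
#'
#' Runs the full objective-weighting chain — min-max standardization,
#' information entropy, weight normalization — and retains the
#' intermediate quantities for audit.
#'
#' @param x A `water_matrix` or numeric matrix (n sites x m indicators).
#' @inheritParams standardize_minmax
#' @return An object of class `entropy_weights`: list with `weights`
#'   (named, sums to 1), `entropy`, `p` (the proportion matrix), and
#'   `k = 1/ln(n)`.
#' @export
#' @examples
#' m <- cbind(DO = c(8, 7, 9), TN = c(0.3, 1.2, 2.1), NH3N = c(.1, .2, .1),
#'            TP = c(.02, .04, .03), CODMn = c(1, 2, 3))
#' entropy_weights(m)
entropy_weights <- function(x, polarity = NULL) {
  std <- standardize_minmax(x, polarity)
  ent <- compute_entropy(std)
  w <- compute_weights(ent)
  p <- apply(std, 2, function(col) col / sum(col))
  structure(
    list(weights = w, entropy = ent, p = p, k = 1 / log(nrow(std))),
    class = "entropy_weights"
  )
}

#' @export
print.entropy_weights <- function(x, ...) {
  cat("Entropy weights (m =", length(x$weights), "indicators)\n")
  print(round(rbind(entropy = x$entropy, weight = x$weights), 4))
  invisible(x)
}

#' Export a weight vector
#'
#' @param w An `entropy_weights` object or named numeric vector.
#' @param path Output file, `.json` or `.csv`.
#' @return `path`, invisibly.
#' @export
write_weights <- function(w, path) {
  if (inherits(w, "entropy_weights")) w <- w$weights
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(w), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(
      data.frame(indicator = names(w), weight = unname(w)),
      path, row.names = FALSE, quote = FALSE
    )
  } else {
    stop("unsupported weight file extension: ", path)
  }
  invisible(path)
}
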