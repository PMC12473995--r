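.emission_source_types <- c("industrial", "agricultural", "domestic",
                            "centralized")
.emission_pollutants <- c("CODMn", "NH3N", "TN", "TP")

#' Read an annual pollutant-emission inventory
#'
#' Inventories are CSV tables with columns `source_type` (industrial,
#' agricultural, domestic, centralized), `subcategory` (e.g. livestock,
#' aquaculture, planting, urban, rural, facility), `pollutant` (CODMn,
#' NH3N, TN, TP) and `amount_t_per_a` in tonnes per year. A `/` or
#' blank amount means "not assessed" and is kept distinct from zero
#' (stored as `NA`).
#'
#' @param path CSV file path.
#' @return Data frame of class `emission_ledger`.
#' @seealso [wanan_inventory()] for the packaged reservoir inventory.
#' @export
read_emission_inventory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_emission_ledger(df)
}

#' @rdname read_emission_inventory
#' @param records Data frame with the inventory columns; amounts may be
#'   numeric, `NA`, `"/"` or `""`.
#' @export
as_emission_ledger <- function(records) {
  df <- as.data.frame(records)
  needed <- c("source_type", "subcategory", "pollutant", "amount_t_per_a")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop("missing inventory column(s): ", paste(missing, collapse = ", "))
  }
  amt <- df$amount_t_per_a
  if (!is.numeric(amt)) {
    amt <- trimws(as.character(amt))
    amt[amt %in% c("/", "")] <- NA
    amt <- as.numeric(amt)
  }
  df$amount_t_per_a <- amt
  if (any(!df$source_type %in% .emission_source_types)) {
    stop("unknown source_type: ",
         paste(setdiff(df$source_type, .emission_source_types), collapse = ", "))
  }
  if (any(!df$pollutant %in% .emission_pollutants)) {
    stop("unknown pollutant: ",
         paste(setdiff(df$pollutant, .emission_pollutants), collapse = ", "))
  }
  if (any(df$amount_t_per_a < 0, na.rm = TRUE)) stop("negative emission amount")
  df <- df[, needed]
  class(df) <- c("emission_ledger", "data.frame")
  df
}

#' The packaged reservoir emission inventory
#'
#' The annual pollutant discharges around the reservoir by source type
#' and subcategory, as shipped with the package (tonnes/year; `/`
#' entries are not-assessed).
#'
#' @return An `emission_ledger` data frame.
#' @export
#' @examples
#' aggregate_emissions(wanan_inventory())
wanan_inventory <- function() {
  read_emission_inventory(
    system.file("extdata", "wanan_emissions.csv", package = "fcewater",
                mustWork = TRUE)
  )
}

#' Aggregate an emission inventory
#'
#' Sums discharges per pollutant into a grand total, per-source-type
#' subtotals and per-subcategory contribution ratios. Not-assessed
#' entries (`NA`) are excluded from every sum and never counted as
#' zeros.
#'
#' @param records An `emission_ledger` (or coercible data frame).
#' @return Object of class `emission_summary`: list with `totals`
#'   (named per pollutant), `by_source_type` and `by_subcategory` data
#'   frames (amounts and shares of the pollutant total).
#' @export
aggregate_emissions <- function(records) {
  led <- as_emission_ledger(records)
  led <- led[!is.na(led$amount_t_per_a), ]
  if (nrow(led) == 0) {
    return(structure(
      list(
        totals = stats::setNames(numeric(0), character(0)),
        by_source_type = data.frame(pollutant = character(0),
                                    source_type = character(0),
                                    amount_t_per_a = numeric(0),
                                    share = numeric(0)),
        by_subcategory = data.frame(pollutant = character(0),
                                    source_type = character(0),
                                    subcategory = character(0),
                                    amount_t_per_a = numeric(0),
                                    share = numeric(0))
      ),
      class = "emission_summary"
    ))
  }
  totals <- tapply(led$amount_t_per_a, led$pollutant, sum)
  totals <- stats::setNames(as.numeric(totals), names(totals))
  by_src <- stats::aggregate(
    amount_t_per_a ~ pollutant + source_type, data = led, FUN = sum
  )
  by_src$share <- by_src$amount_t_per_a / totals[by_src$pollutant]
  by_sub <- stats::aggregate(
    amount_t_per_a ~ pollutant + source_type + subcategory, data = led,
    FUN = sum
  )
  by_sub$share <- by_sub$amount_t_per_a / totals[by_sub$pollutant]
  structure(
    list(totals = totals, by_source_type = by_src, by_subcategory = by_sub),
    class = "emission_summary"
  )
}

#' @export
print.emission_summary <- function(x, ...) {
  cat("Annual pollutant discharge totals (t/a):\n")
  print(round(x$totals, 2))
  invisible(x)
}

#' Subtotal for one source type and pollutant
#'
#' @param records An `emission_ledger`.
#' @param source_type One of industrial, agricultural, domestic,
#'   centralized.
#' @param pollutant One of CODMn, NH3N, TN, TP.
#' @return Tonnes/year (numeric), or `NA` when every matching entry is
#'   not-assessed.
#' @export
#' @examples
#' subtotal_by_source_type(wanan_inventory(), "agricultural", "CODMn")
subtotal_by_source_type <- function(records, source_type, pollutant) {
  led <- as_emission_ledger(records)
  stopifnot(source_type %in% .emission_source_types,
            pollutant %in% .emission_pollutants)
  amt <- led$amount_t_per_a[led$source_type == source_type &
                              led$pollutant == pollutant]
  if (length(amt) == 0 || all(is.na(amt))) return(NA_real_)
  sum(amt, na.rm = TRUE)
}

#' Subcategory contribution ratios for one pollutant
#'
#' @param summary An `emission_summary` from [aggregate_emissions()]
#'   (or an `emission_ledger`, which is aggregated first).
#' @param pollutant One of CODMn, NH3N, TN, TP.
#' @return Named numeric vector of shares summing to 1.
#' @export
#' @examples
#' contribution_ratios(wanan_inventory(), "CODMn")
contribution_ratios <- function(summary, pollutant) {
  if (!inherits(summary, "emission_summary")) {
    summary <- aggregate_emissions(summary)
  }
  stopifnot(pollutant %in% .emission_pollutants)
  sub <- summary$by_subcategory
  sub <- sub[sub$pollutant == pollutant, ]
  if (nrow(sub) == 0) stop("no assessed emissions for ", pollutant)
  stats::setNames(sub$share, sub$subcategory)
}
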