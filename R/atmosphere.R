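#' Radioactive decay rate of carbon-14
#'
#' The true mean life of \eqn{^{14}}C (half-life 5730 yr) gives
#' \eqn{\lambda = 1/8267} yr\eqn{^{-1}}, the convention of compartmental
#' soil-radiocarbon modelling.
#'
#' @format A single numeric value, yr\eqn{^{-1}}.
#' @export
LAMBDA_14C <- 1 / 8267

#' Construct an atmospheric Delta-14C record
#'
#' An atmosphere record is the tracer forcing of the model: a lookup from
#' calendar year (decimal years allowed) to atmospheric \eqn{\Delta^{14}}C in
#' per mil. Years must be strictly increasing after sorting and at least two
#' points are required.
#'
#' @param year Numeric vector of calendar years.
#' @param delta14c Numeric vector of \eqn{\Delta^{14}}C values (per mil),
#'   each in (-1000, 2000).
#' @return A data frame of class `atmosphere_record` with columns `year`
#'   and `delta14c`, sorted by year.
#' @export
atmosphere_record <- function(year, delta14c) {
  if (length(year) != length(delta14c))
    stop("`year` and `delta14c` must have equal length")
  if (length(year) < 2)
    stop("atmosphere record has fewer than 2 points")
  if (anyNA(year) || anyNA(delta14c))
    stop("atmosphere record contains missing values")
  if (any(delta14c <= -1000 | delta14c >= 2000))
    stop("delta14c values must lie in (-1000, 2000) per mil")
  if (is.unsorted(year, strictly = FALSE)) {
    warning("atmosphere years out of order; sorting")
    o <- order(year)
    year <- year[o]
    delta14c <- delta14c[o]
  }
  if (anyDuplicated(year)) {
    bad <- year[duplicated(year)][1]
    stop("atmosphere years not strictly increasing: duplicated year ", bad)
  }
  structure(data.frame(year = year, delta14c = delta14c),
            class = c("atmosphere_record", "data.frame"))
}

#' Read an atmospheric Delta-14C table from CSV
#'
#' Expects a two-column CSV with header `year,delta14c_permil` (the column
#' name `delta14c` is also accepted). Lines starting with `#` are ignored.
#' Rows are sorted by year with a warning if out of order.
#'
#' @param source Path to a CSV file, or a connection.
#' @return An [atmosphere_record()].
#' @export
read_atmosphere_table <- function(source) {
  df <- tryCatch(
    read.csv(source, comment.char = "#", strip.white = TRUE,
             colClasses = "character"),
    error = function(e) stop("cannot read atmosphere table: ",
                             conditionMessage(e)))
  nm <- tolower(names(df))
  ycol <- match("year", nm)
  dcol <- match("delta14c_permil", nm)
  if (is.na(dcol)) dcol <- match("delta14c", nm)
  if (is.na(ycol) || is.na(dcol))
    stop("atmosphere table needs columns `year` and `delta14c_permil`")
  yr <- suppressWarnings(as.numeric(df[[ycol]]))
  dl <- suppressWarnings(as.numeric(df[[dcol]]))
  bad <- which(is.na(yr) | is.na(dl))
  if (length(bad))
    stop("non-numeric value in atmosphere table at data row ", bad[1])
  atmosphere_record(yr, dl)
}

#' Convert Delta-14C (per mil) to a 14C/12C ratio relative to the standard
#'
#' The dimensionless tracer quantity propagated by the model:
#' ratio = 1 + delta/1000.
#'
#' @param delta Per-mil value(s), each > -1000.
#' @return Dimensionless ratio(s).
#' @export
ratio_from_delta <- function(delta) {
  if (any(delta <= -1000))
    stop("delta14c must exceed -1000 per mil")
  1 + delta / 1000
}

#' Convert a 14C/12C ratio to Delta-14C (per mil)
#'
#' Exact inverse of [ratio_from_delta()].
#'
#' @param ratio Dimensionless ratio(s), each > 0.
#' @return Per-mil value(s).
#' @export
delta_from_ratio <- function(ratio) {
  if (any(ratio <= 0))
    stop("14C ratio must be positive")
  (ratio - 1) * 1000
}

#' Atmospheric 14C ratio at a given time
#'
#' Piecewise-linear interpolation of the record, with flat extension before
#' the first year (used by the spin-up) and after the last.
#'
#' @param record An [atmosphere_record()].
#' @param t Calendar year(s), decimal allowed.
#' @return Dimensionless ratio(s).
#' @export
atm_ratio_at <- function(record, t) {
  stopifnot(inherits(record, "atmosphere_record"))
  ratio <- ratio_from_delta(record$delta14c)
  approx(record$year, ratio, xout = t, rule = 2)$y
}
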