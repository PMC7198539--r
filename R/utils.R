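#' Round a percentage half-up at one decimal
#'
#' Claims-study tables conventionally print percentages at one decimal with
#' half-up rounding (so 29.25 prints as 29.3, not 29.2 as under banker's
#' rounding). `pct1()` computes `100 * num / den` and rounds that way.
#'
#' @param num Numerator count(s).
#' @param den Denominator count(s).
#' @return Numeric percentage(s) rounded half-up to one decimal.
#' @examples
#' pct1(537, 1834) # 29.3
#' @export
pct1 <- function(num, den) {
  x <- 100 * num / den
  floor(x * 10 + 0.5) / 10
}

#' @keywords internal
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

# days per month used wherever a month count must become a day count
DAYS_PER_MONTH <- 30.4375

months_to_days <- function(months) as.integer(floor(months * DAYS_PER_MONTH))

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# strip dots from ICD-10 codes so prefix matching is robust to dot usage
icd_normalize <- function(code) gsub(".", "", toupper(trimws(code)), fixed = TRUE)

#' Match ICD-10 codes against a pattern list
#'
#' Prefix matching on dot-stripped codes: the pattern `"S720"` matches
#' `"S72.0"` and `"S72.00"`. Claims extracts vary in whether codes carry
#' dots, so both sides are normalized before comparison.
#'
#' @param codes Character vector of observed diagnosis codes.
#' @param patterns Character vector of code prefixes to match.
#' @return Logical vector, `TRUE` where a code matches any pattern.
#' @export
icd_match <- function(codes, patterns) {
  if (length(patterns) == 0L) return(rep(FALSE, length(codes)))
  codes <- icd_normalize(codes)
  patterns <- icd_normalize(patterns)
  bad <- !grepl("^[A-Z][0-9]", patterns)
  if (any(bad)) {
    stop("invalid ICD pattern(s): ", paste(patterns[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- rep(FALSE, length(codes))
  for (p in patterns) out <- out | startsWith(codes, p)
  out
}

# merge possibly-overlapping integer half-open intervals [start, end)
merge_intervals <- function(start, end) {
  keep <- !is.na(start) & !is.na(end) & end > start
  start <- start[keep]; end <- end[keep]
  if (length(start) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- integer(0); out_e <- integer(0)
  if (length(start) > 1L) {
    for (i in 2:length(start)) {
      if (start[i] <= me) {
        me <- max(me, end[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- start[i]; me <- end[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  data.frame(start = out_s, end = out_e)
}

# total days of [start, end) intervals overlapping window [lo, hi)
overlap_days <- function(start, end, lo, hi) {
  if (length(start) == 0L) return(0L)
  s <- pmax(start, lo)
  e <- pmin(end, hi)
  sum(pmax(e - s, 0L))
}
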