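# Micro-morphological measurement summaries in the five-number notation
# used in species descriptions: "(min-)low-mean-high(-max)", where low/high
# are mean -/+ one sample SD (the convention of the standard description
# format; 5th/95th percentiles are available as an alternative since the
# convention is not universal), all rounded to a fixed step.

#' Summarise a measurement vector
#'
#' @param values numeric measurements (n >= 2, positive), e.g. spore lengths
#'   in micrometres.
#' @param rounding rounding step for all reported numbers (default 0.1).
#' @param spread `"sd"` (low/high = mean -/+ 1 sample SD, the default) or
#'   `"quantile"` (5th/95th percentiles).
#' @param unit unit label carried along (default `"um"`).
#' @return object of class `MeasurementSummary`: list with `n`, `min`,
#'   `low`, `mean`, `high`, `max`, `sd`, `unit`, `rounding`. After
#'   rounding, low/high are clamped into \[min, max\] so that
#'   min <= low <= mean <= high <= max always holds.
#' @examples
#' summarizeMeasurements(c(7.0, 8.0, 9.0))   # (7.0-)7.0-8.0-9.0(-9.0)
#' @export
summarizeMeasurements <- function(values, rounding = 0.1,
                                  spread = c("sd", "quantile"),
                                  unit = "um") {
  spread <- match.arg(spread)
  if (length(values) < 2L) stop("need at least 2 measurements")
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("measurements must be positive and finite")
  }
  mu <- mean(values)
  s <- stats::sd(values)
  if (spread == "sd") {
    lo <- mu - s; hi <- mu + s
  } else {
    q <- stats::quantile(values, c(0.05, 0.95), names = FALSE)
    lo <- q[1L]; hi <- q[2L]
  }
  r <- function(x) round(x / rounding) * rounding
  mn <- r(min(values)); mx <- r(max(values)); mu_r <- r(mu)
  lo <- min(max(r(lo), mn), mu_r)
  hi <- max(min(r(hi), mx), mu_r)
  structure(list(n = length(values), min = mn, low = lo, mean = mu_r,
                 high = hi, max = mx, sd = s, unit = unit,
                 rounding = rounding),
            class = "MeasurementSummary")
}

#' Summarise the length/width quotient Q
#'
#' Element-wise ratios of paired length and width measurements (e.g.
#' basidiospores), summarised like [summarizeMeasurements()] but rounded to
#' 0.01 and dimensionless.
#'
#' @param lengths,widths paired numeric vectors (equal length, widths > 0).
#' @param rounding rounding step (default 0.01).
#' @param spread see [summarizeMeasurements()].
#' @return a `MeasurementSummary` of Q = length/width.
#' @examples
#' qSummary(c(8, 9), c(6, 6))  # mean Q = 1.42
#' @export
qSummary <- function(lengths, widths, rounding = 0.01,
                     spread = c("sd", "quantile")) {
  if (length(lengths) != length(widths)) {
    stop("lengths and widths must be paired (equal length)")
  }
  if (any(widths <= 0)) stop("widths must be positive")
  summarizeMeasurements(lengths / widths, rounding = rounding,
                        spread = match.arg(spread), unit = "")
}

.fmtStep <- function(x, rounding) {
  digits <- max(0L, -floor(log10(rounding) + 1e-9))
  sprintf(paste0("%.", digits, "f"), x)
}

#' Format a measurement summary as description text
#'
#' Renders the five-number notation `"(min-)low-mean-high(-max)"`. The
#' parenthetical extremes are always printed by default; with
#' `dropRedundant = TRUE` they are omitted when they equal the adjacent
#' bound.
#'
#' @param s a `MeasurementSummary`.
#' @param dropRedundant omit `(min-)` when min == low and `(-max)` when
#'   max == high.
#' @return a character string that parses back (see [parseSummary()]) to the
#'   same rounded numbers.
#' @examples
#' formatSummary(summarizeMeasurements(c(7, 8, 9)))
#' @export
formatSummary <- function(s, dropRedundant = FALSE) {
  stopifnot(inherits(s, "MeasurementSummary"))
  f <- function(x) .fmtStep(x, s$rounding)
  core <- paste0(f(s$low), "-", f(s$mean), "-", f(s$high))
  pre <- if (dropRedundant && s$min == s$low) "" else paste0("(", f(s$min), "-)")
  post <- if (dropRedundant && s$max == s$high) "" else paste0("(-", f(s$max), ")")
  paste0(pre, core, post)
}

#' @export
print.MeasurementSummary <- function(x, ...) {
  cat(formatSummary(x), if (nzchar(x$unit)) x$unit else "",
      sprintf("(n = %d)\n", x$n))
  invisible(x)
}

#' Parse description-notation text back into a summary
#'
#' Accepts the ASCII form produced by [formatSummary()] as well as the
#' typographic variants seen in print (en-dashes, spaces after the opening
#' parenthesis). Parenthetical extremes may be absent, in which case they
#' default to the adjacent bound.
#'
#' @param text a string such as `"(7.1-)7.5-8.0-8.5(-9.4)"`.
#' @param rounding rounding step recorded in the result (default inferred
#'   from the printed decimals).
#' @param unit unit label for the result.
#' @return a `MeasurementSummary` (with `n` and `sd` set to `NA`).
#' @export
parseSummary <- function(text, rounding = NULL, unit = "um") {
  t <- gsub("–|−", "-", text)  # en-dash / minus -> hyphen
  t <- gsub("\\s+", "", t)
  num <- "([0-9]+\\.?[0-9]*)"
  pat <- paste0("^(?:\\(", num, "-\\))?", num, "-", num, "-", num,
                "(?:\\(-", num, "\\))?$")
  mm <- regmatches(t, regexec(pat, t, perl = TRUE))[[1L]]
  if (length(mm) == 0L) stop("cannot parse summary: ", text)
  vals <- suppressWarnings(as.numeric(mm[-1L]))
  lo <- vals[2L]; mu <- vals[3L]; hi <- vals[4L]
  mn <- if (is.na(vals[1L])) lo else vals[1L]
  mx <- if (is.na(vals[5L])) hi else vals[5L]
  if (is.null(rounding)) {
    dec <- nchar(sub("^[^.]*\\.?", "", mm[4L]))
    rounding <- 10^(-dec)
  }
  structure(list(n = NA_integer_, min = mn, low = lo, mean = mu, high = hi,
                 max = mx, sd = NA_real_, unit = unit, rounding = rounding),
            class = "MeasurementSummary")
}
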