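#' Construct an employment series
#'
#' An `employment_series` holds yearly employed counts (thousands of persons)
#' by sector. Missing (year, sector) cells are treated as zero employment
#' with a warning, since household-survey detail for some sectors is sparse
#' in early decades.
#'
#' @param records data.frame with columns `year`, `sector`,
#'   `employed_thousands`. Sectors must be canonical identifiers
#'   (see [sector_ids()]).
#' @param warn_missing warn when (year, sector) cells are absent and filled
#'   with zero.
#' @return An object of class `employment_series`: the completed records
#'   (every year crossed with every sector appearing in the data) plus the
#'   inclusive year range.
#' @seealso [load_employment_series()], [sector_prevalence()]
#' @export
employment_series <- function(records, warn_missing = TRUE) {
  stopifnot(is.data.frame(records))
  needed <- c("year", "sector", "employed_thousands")
  miss <- setdiff(needed, names(records))
  if (length(miss)) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$year <- as.integer(records$year)
  records$employed_thousands <- as.numeric(records$employed_thousands)
  match_sector(records$sector)

  bad <- !is.finite(records$employed_thousands) | records$employed_thousands < 0
  if (any(bad)) {
    i <- which(bad)[1L]
    stop(sprintf(
      "validation error: negative or non-finite count for (%d, %s)",
      records$year[i], records$sector[i]), call. = FALSE)
  }
  if (anyDuplicated(records[c("year", "sector")])) {
    stop("validation error: duplicate (year, sector) records", call. = FALSE)
  }

  years <- sort(unique(records$year))
  sectors <- intersect(sector_ids(), unique(records$sector))
  full <- expand.grid(year = years, sector = sectors,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  full <- merge(full, records, by = c("year", "sector"), all.x = TRUE)
  n_missing <- sum(is.na(full$employed_thousands))
  if (n_missing > 0) {
    if (warn_missing) {
      warning(sprintf(
        "%d missing (year, sector) cell(s) treated as zero employment",
        n_missing), call. = FALSE)
    }
    full$employed_thousands[is.na(full$employed_thousands)] <- 0
  }

  totals <- tapply(full$employed_thousands, full$year, sum)
  zero_years <- names(totals)[totals <= 0]
  if (length(zero_years)) {
    stop("validation error: no employment in year ",
         paste(zero_years, collapse = ", "), call. = FALSE)
  }

  full <- full[order(full$year, match(full$sector, sector_ids())), ]
  rownames(full) <- NULL
  structure(list(records = full,
                 year_range = range(years)),
            class = "employment_series")
}

#' @export
print.employment_series <- function(x, ...) {
  cat(sprintf("Employment series: %d-%d, %d sectors, %d records\n",
              x$year_range[1], x$year_range[2],
              length(unique(x$records$sector)), nrow(x$records)))
  invisible(x)
}

#' Load an employment series from delimited text
#'
#' Reads a CSV (default) or TSV file with columns `year`, `sector` and
#' `employed_thousands` (the count column may also be named `employed`).
#' Sector labels are matched case-insensitively through the packaged alias
#' table; unmappable labels are reported with their line numbers.
#'
#' @param path file path.
#' @param delim field delimiter; `NULL` (default) sniffs comma vs tab from
#'   the header line.
#' @return An [employment_series()] object.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("year,sector,employed_thousands",
#'              "1960,Manufacturing,15000"), f)
#' load_employment_series(f)
#' @export
load_employment_series <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8")
  names(raw) <- tolower(names(raw))
  if ("employed" %in% names(raw) && !"employed_thousands" %in% names(raw)) {
    names(raw)[names(raw) == "employed"] <- "employed_thousands"
  }
  needed <- c("year", "sector", "employed_thousands")
  miss <- setdiff(needed, names(raw))
  if (length(miss)) {
    stop("format error: missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  canon <- resolve_sector(raw$sector)
  if (anyNA(canon)) {
    lines <- which(is.na(canon)) + 1L  # +1 for the header line
    stop("validation error: unmappable sector label(s) ",
         paste(sprintf("'%s' (line %d)", raw$sector[is.na(canon)], lines),
               collapse = ", "), call. = FALSE)
  }
  raw$sector <- canon
  employment_series(raw[needed])
}

#' Write an employment series as CSV
#'
#' Inverse of [load_employment_series()]: writes the canonical dialect
#' `year,sector,employed_thousands`, suitable for bit-for-bit round-trips.
#'
#' @param series an [employment_series()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_employment_series <- function(series, path) {
  stopifnot(inherits(series, "employment_series"))
  out <- series$records
  # 17 significant digits so counts survive a write/read round-trip exactly
  out$employed_thousands <- sprintf("%.17g", out$employed_thousands)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sector prevalence in a year
#'
#' Employment share of each sector: the employed count divided by total
#' employment across all sectors (private industry pooled with agriculture)
#' for that year. Shares lie on the simplex — non-negative, summing to one.
#'
#' @param series an [employment_series()] object.
#' @param year calendar year within the series range.
#' @return Named numeric vector of fractions, one per sector in the series.
#' @examples
#' s <- employment_series(data.frame(
#'   year = 1960, sector = c("manufacturing", "information"),
#'   employed_thousands = c(300, 100)))
#' sector_prevalence(s, 1960)
#' @export
sector_prevalence <- function(series, year) {
  stopifnot(inherits(series, "employment_series"))
  if (year < series$year_range[1] || year > series$year_range[2]) {
    stop(sprintf("year %d outside series range %d-%d", as.integer(year),
                 series$year_range[1], series$year_range[2]), call. = FALSE)
  }
  rec <- series$records[series$records$year == year, ]
  if (nrow(rec) == 0L) {
    stop(sprintf("year %d has no records", as.integer(year)), call. = FALSE)
  }
  total <- sum(rec$employed_thousands)
  stats::setNames(rec$employed_thousands / total, rec$sector)
}

#' Sector prevalences for every year
#'
#' @param series an [employment_series()] object.
#' @return A tidy data.frame `year,sector,prevalence`.
#' @export
prevalence_table <- function(series) {
  stopifnot(inherits(series, "employment_series"))
  years <- seq(series$year_range[1], series$year_range[2])
  years <- intersect(years, unique(series$records$year))
  out <- do.call(rbind, lapply(years, function(y) {
    p <- sector_prevalence(series, y)
    data.frame(year = y, sector = names(p), prevalence = unname(p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Ordinary least-squares trend test
#'
#' Regresses a yearly statistic on calendar year and reports the slope with
#' a two-sided t-test p-value. Degenerate perfect fits are handled
#' explicitly: zero residual variance with zero slope gives p = 1 (no
#' evidence of trend), zero residual variance with nonzero slope gives p = 0
#' (an exact linear trend).
#'
#' @param values numeric vector of yearly values; if `years` is missing the
#'   names of `values` are used as years.
#' @param years numeric vector of calendar years, same length as `values`.
#' @return A list of class `trend_test` with `slope` (change per year),
#'   `p_value`, `n_years`, and `method`.
#' @examples
#' trend_test(c(`1960` = 0.48, `1984` = 0.34, `2008` = 0.20))
#' @export
trend_test <- function(values, years = as.numeric(names(values))) {
  if (is.null(years) || anyNA(years)) {
    stop("years must be supplied (or values named by year)", call. = FALSE)
  }
  if (length(unique(years)) < 2L) {
    stop("trend test requires at least 2 distinct years", call. = FALSE)
  }
  stopifnot(length(values) == length(years))
  fit <- stats::lm(values ~ years)
  slope <- unname(stats::coef(fit)[2L])
  res_ss <- sum(stats::residuals(fit)^2)
  # scale-aware zero-residual threshold
  scale2 <- max(sum(values^2), .Machine$double.eps)
  if (res_ss <= 1e-20 * scale2) {
    p <- if (abs(slope) <= sqrt(.Machine$double.eps) * max(abs(values), 1)) 1 else 0
  } else {
    p <- summary(fit)$coefficients["years", "Pr(>|t|)"]
  }
  structure(list(slope = slope, p_value = unname(p),
                 n_years = length(unique(years)),
                 method = "OLS of value on calendar year, two-sided slope t-test"),
            class = "trend_test")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("Trend: slope %.6g per year, p = %.3g (%d years)\n",
              x$slope, x$p_value, x$n_years))
  cat(" method:", x$method, "\n")
  invisible(x)
}
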