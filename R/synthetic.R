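#' Default 1960/2008 sector-prevalence anchors
#'
#' Anchor prevalence vectors for 1960 and 2008 satisfying the printed
#' aggregates: moderate-intensity category mass 0.48 in 1960 and 0.20 in
#' 2008; manufacturing 0.30 and 0.12; professional/business +
#' education/health + leisure/hospitality 0.20 and 0.43. Sectors the
#' aggregates do not pin are fixed, documented constants chosen for
#' qualitative plausibility (construction roughly flat, information and
#' farm declining).
#'
#' @param total_employment_start total employment in the start year,
#'   thousands.
#' @param total_employment_end total employment in the end year, thousands.
#' @return An object of class `anchor_set`: `year_start`, `year_end`,
#'   `prevalence_start`, `prevalence_end` (named simplex vectors),
#'   `total_employment_start`, `total_employment_end`.
#' @examples
#' a <- default_anchor_set()
#' sum(a$prevalence_start)
#' @export
default_anchor_set <- function(total_employment_start = 52000,
                               total_employment_end = 137000) {
  p1960 <- c(farm = 0.08, mining_logging = 0.04, construction = 0.06,
             manufacturing = 0.30,                       # moderate sums to 0.48
             trade_transport_utilities = 0.22, information = 0.035,
             financial = 0.045, professional_business = 0.07,
             education_health = 0.07, leisure_hospitality = 0.06,
             other_services = 0.02)
  p2008 <- c(farm = 0.01, mining_logging = 0.01, construction = 0.06,
             manufacturing = 0.12,                       # moderate sums to 0.20
             trade_transport_utilities = 0.245, information = 0.025,
             financial = 0.065, professional_business = 0.16,
             education_health = 0.17, leisure_hospitality = 0.10,
             other_services = 0.035)
  anchor_set(1960, 2008, p1960, p2008,
             total_employment_start, total_employment_end)
}

#' Construct and validate an anchor set
#'
#' @param year_start,year_end calendar years, `year_start < year_end`.
#' @param prevalence_start,prevalence_end named sector-prevalence vectors on
#'   the simplex.
#' @param total_employment_start,total_employment_end totals in thousands.
#' @return An object of class `anchor_set`.
#' @export
anchor_set <- function(year_start, year_end,
                       prevalence_start, prevalence_end,
                       total_employment_start, total_employment_end) {
  stopifnot(year_start < year_end,
            total_employment_start > 0, total_employment_end > 0)
  for (p in list(prevalence_start, prevalence_end)) {
    match_sector(names(p))
    if (length(p) != length(sector_ids())) {
      stop("anchor prevalence must cover all 11 sectors", call. = FALSE)
    }
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("anchor prevalence must lie on the simplex", call. = FALSE)
    }
  }
  structure(list(year_start = as.integer(year_start),
                 year_end = as.integer(year_end),
                 prevalence_start = prevalence_start[sector_ids()],
                 prevalence_end = prevalence_end[sector_ids()],
                 total_employment_start = total_employment_start,
                 total_employment_end = total_employment_end),
            class = "anchor_set")
}

#' @export
print.anchor_set <- function(x, ...) {
  cat(sprintf("Anchor set %d -> %d (totals %g -> %g thousand)\n",
              x$year_start, x$year_end,
              x$total_employment_start, x$total_employment_end))
  print(round(rbind(start = x$prevalence_start, end = x$prevalence_end), 3))
  invisible(x)
}

#' Generate a synthetic employment series
#'
#' Emulates the statistical structure the trend analysis assumes: sector
#' prevalences drift linearly between the anchor vectors, with optional
#' multiplicative log-normal noise per (year, sector) followed by
#' renormalization to the simplex; counts are prevalences times a linearly
#' interpolated total employment. Deterministic given the seed. This is a
#' structural stand-in for establishment/household survey extracts, not an
#' emulator of their microstructure.
#'
#' @param anchors an [anchor_set()]; default [default_anchor_set()].
#' @param noise_sd relative (log-scale) noise standard deviation, >= 0.
#' @param seed integer seed.
#' @return An [employment_series()] object covering every year from the
#'   start to the end anchor.
#' @examples
#' s <- generate_employment_series(noise_sd = 0, seed = 1)
#' sector_prevalence(s, 1960)[["manufacturing"]]  # 0.30
#' @export
generate_employment_series <- function(anchors = default_anchor_set(),
                                       noise_sd = 0, seed = 1L) {
  stopifnot(inherits(anchors, "anchor_set"), noise_sd >= 0)
  years <- seq(anchors$year_start, anchors$year_end)
  frac <- (years - anchors$year_start) /
    (anchors$year_end - anchors$year_start)
  sectors <- sector_ids()

  # rows = years, cols = sectors
  prev <- outer(1 - frac, anchors$prevalence_start) +
    outer(frac, anchors$prevalence_end)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv()))
    set.seed(as.integer(seed))
    noise <- matrix(stats::rlnorm(length(prev), meanlog = 0, sdlog = noise_sd),
                    nrow = nrow(prev))
    prev <- prev * noise
  }
  prev <- prev / rowSums(prev)

  totals <- (1 - frac) * anchors$total_employment_start +
    frac * anchors$total_employment_end
  counts <- prev * totals

  records <- data.frame(
    year = rep(years, times = length(sectors)),
    sector = rep(sectors, each = length(years)),
    employed_thousands = as.vector(counts),
    stringsAsFactors = FALSE)
  employment_series(records)
}

#' Packaged NHANES mean-weight anchors
#'
#' Mean body weight (kg) for the 40-50 year old age group by survey period
#' and gender. Only the three published cells are populated — men and women
#' in 1960-62 (76.9 and 64.9 kg) and men in 2003-06 (91.8 kg); the remaining
#' cells are absent (NA) and flagged as such in the `source` column.
#'
#' @return A data.frame `period,gender,mean_weight_kg,source` covering the
#'   six survey periods 1960-62 through 2003-06.
#' @examples
#' nhanes_weight_fixture()
#' @export
nhanes_weight_fixture <- function() {
  path <- system.file("extdata", "nhanes_weights.csv", package = "metshift",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c("character", "character", "numeric",
                                 "character"))
}

#' Calendar years covered by each NHANES survey period
#'
#' @return Named list mapping period label to the integer years it spans.
#' @export
nhanes_period_years <- function() {
  list(`1960-62` = 1960:1962,
       `1971-74` = 1971:1974,
       `1976-80` = 1976:1980,
       `1988-94` = 1988:1994,
       `1999-2002` = 1999:2002,
       `2003-06` = 2003:2006)
}
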