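#' Canonical industry sectors
#'
#' The analysis works at the granularity of 11 industry sectors: farm jobs
#' (agriculture), three goods-producing sectors, and seven service-providing
#' sectors. Trade, transportation and utilities are pooled into a single
#' sector because they share one MET assignment.
#'
#' @return Character vector of the 11 canonical sector identifiers, in
#'   conventional display order.
#' @examples
#' sector_ids()
#' @export
sector_ids <- function() {
  c("farm", "mining_logging", "construction", "manufacturing",
    "trade_transport_utilities", "information", "financial",
    "professional_business", "education_health", "leisure_hospitality",
    "other_services")
}

#' Super-category of each sector
#'
#' Maps sectors onto the three top-level employment categories:
#' agriculture (farm), goods-producing (mining/logging, construction,
#' manufacturing) and service-providing (the remaining seven).
#'
#' @param sector character vector of sector identifiers.
#' @return Character vector of super-categories, same length as `sector`.
#' @examples
#' sector_super_category(c("farm", "manufacturing", "information"))
#' @export
sector_super_category <- function(sector = sector_ids()) {
  sector <- match_sector(sector)
  map <- c(farm = "agriculture",
           mining_logging = "goods_producing",
           construction = "goods_producing",
           manufacturing = "goods_producing")
  out <- unname(map[sector])
  out[is.na(out)] <- "service_providing"
  out
}

#' Sector alias table
#'
#' Free-text sector labels found in employment extracts (for example
#' "Mining and logging" or "Trade, transportation, and utilities") are mapped
#' onto canonical identifiers through a packaged alias table. Matching is
#' case-insensitive and ignores surrounding whitespace and punctuation
#' variants listed in the table.
#'
#' @return A data.frame with columns `alias` and `sector`.
#' @export
sector_alias_table <- function() {
  path <- system.file("extdata", "sector_aliases.csv", package = "metshift",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# Normalize a label for alias lookup: lower-case, trim, collapse runs of
# spaces, drop commas/ampersands/parentheses so punctuation variants match.
normalize_label <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[(),&]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Map labels to canonical sector ids; NA where unmappable.
resolve_sector <- function(labels, aliases = sector_alias_table()) {
  key <- normalize_label(aliases$alias)
  idx <- match(normalize_label(labels), key)
  aliases$sector[idx]
}

# Validate that x contains only canonical sector ids; returns x.
match_sector <- function(x) {
  bad <- setdiff(unique(x), sector_ids())
  if (length(bad)) {
    stop("unknown sector identifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  x
}
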