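#' Packaged MET assignments by sector
#'
#' Median, minimum and maximum physical-activity intensity in METs
#' (1 MET = 1 kcal per kg body weight per hour) for each of the 11 sectors,
#' with the intensity category implied by the median. Goods-producing
#' sectors and farm jobs are moderate intensity; service sectors are
#' sedentary or light.
#'
#' @return A data.frame with columns `sector`, `met_median`, `met_min`,
#'   `met_max`, `category`, one row per sector.
#' @examples
#' met_table_default()
#' @export
met_table_default <- function() {
  path <- system.file("extdata", "met_table.csv", package = "metshift",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_met_table(tab)
  tab
}

validate_met_table <- function(tab) {
  needed <- c("sector", "met_median", "met_min", "met_max", "category")
  miss <- setdiff(needed, names(tab))
  if (length(miss)) {
    stop("MET table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  match_sector(tab$sector)
  if (anyDuplicated(tab$sector)) {
    stop("MET table has duplicate sectors", call. = FALSE)
  }
  if (any(tab$met_min > tab$met_median | tab$met_median > tab$met_max)) {
    stop("MET table violates met_min <= met_median <= met_max", call. = FALSE)
  }
  implied <- classify_intensity(tab$met_median)
  if (!identical(implied, tab$category)) {
    stop("MET table category column inconsistent with median classification",
         call. = FALSE)
  }
  invisible(tab)
}

#' Intensity classification scheme
#'
#' Cutpoints for the occupational intensity categories: sedentary below
#' 2 METs, light from 2 up to (not including) 3, moderate from 3 up to
#' (not including) 6. There is no vigorous category; medians at or above
#' the moderate upper bound are rejected.
#'
#' @param sedentary_upper exclusive upper bound of sedentary, METs.
#' @param light_upper exclusive upper bound of light, METs.
#' @param moderate_upper exclusive upper bound of moderate, METs.
#' @return A list of class `intensity_scheme`.
#' @export
intensity_scheme <- function(sedentary_upper = 2, light_upper = 3,
                             moderate_upper = 6) {
  if (!(0 < sedentary_upper && sedentary_upper < light_upper &&
        light_upper < moderate_upper)) {
    stop("cutpoints must satisfy 0 < sedentary < light < moderate",
         call. = FALSE)
  }
  structure(list(sedentary_upper = sedentary_upper,
                 light_upper = light_upper,
                 moderate_upper = moderate_upper),
            class = "intensity_scheme")
}

#' Classify MET values into intensity categories
#'
#' Half-open intervals: `[0, 2)` sedentary, `[2, 3)` light, `[3, 6)`
#' moderate, so 2.9999 is light and 3.0 is moderate. Values at or above the
#' moderate bound have no category in this scheme and raise an error.
#'
#' @param met numeric vector of MET values, each > 0.
#' @param scheme an [intensity_scheme()].
#' @return Character vector of categories.
#' @examples
#' classify_intensity(c(1.5, 2.5, 3.0))
#' @export
classify_intensity <- function(met, scheme = intensity_scheme()) {
  stopifnot(inherits(scheme, "intensity_scheme"))
  if (any(!is.finite(met) | met <= 0)) {
    stop("MET values must be positive and finite", call. = FALSE)
  }
  if (any(met >= scheme$moderate_upper)) {
    stop(sprintf(
      "MET value >= %g has no category (no vigorous category in this scheme)",
      scheme$moderate_upper), call. = FALSE)
  }
  ifelse(met < scheme$sedentary_upper, "sedentary",
         ifelse(met < scheme$light_upper, "light", "moderate"))
}

#' Energy-expenditure assumptions
#'
#' Fixed assumptions used to convert mean METs to daily occupational
#' energy expenditure: an 8-hour workday and gender-specific reference
#' body weights held at the 1960-62 NHANES means (76.9 kg men, 64.9 kg
#' women) for every year. The workweek factor 5/7 converts a per-workday
#' expenditure change to a per-calendar-day average and is applied only
#' when predicting weight trajectories.
#'
#' @param hours_per_workday hours worked per day, in (0, 24].
#' @param reference_weight_kg named numeric, kg per gender.
#' @param workweek_factor fraction of days worked, in (0, 1].
#' @return A list of class `ee_assumptions`.
#' @export
ee_assumptions <- function(hours_per_workday = 8,
                           reference_weight_kg = c(men = 76.9, women = 64.9),
                           workweek_factor = 5 / 7) {
  stopifnot(hours_per_workday > 0, hours_per_workday <= 24,
            all(reference_weight_kg > 0),
            workweek_factor > 0, workweek_factor <= 1)
  if (is.null(names(reference_weight_kg)) ||
      any(!nzchar(names(reference_weight_kg)))) {
    stop("reference_weight_kg must be named by gender", call. = FALSE)
  }
  structure(list(hours_per_workday = hours_per_workday,
                 reference_weight_kg = reference_weight_kg,
                 workweek_factor = workweek_factor),
            class = "ee_assumptions")
}

#' Prevalence-weighted mean METs
#'
#' The employment-weighted mean occupational intensity: each sector's
#' prevalence multiplied by its median METs, summed. Equivalent to summing
#' count x median over sectors and dividing by total employment.
#'
#' @param prevalence named numeric vector of sector prevalences on the
#'   simplex.
#' @param met_table MET assignment table, see [met_table_default()].
#' @return Mean METs (scalar), bounded by the range of table medians.
#' @examples
#' mean_met(c(construction = 0.5, financial = 0.5))
#' @export
mean_met <- function(prevalence, met_table = met_table_default()) {
  if (is.null(names(prevalence))) {
    stop("prevalence must be named by sector", call. = FALSE)
  }
  match_sector(names(prevalence))
  if (any(prevalence < -1e-12) || abs(sum(prevalence) - 1) > 1e-6) {
    stop("prevalence must be non-negative and sum to 1", call. = FALSE)
  }
  idx <- match(names(prevalence), met_table$sector)
  if (anyNA(idx)) {
    stop("configuration error: sector(s) missing from MET table: ",
         paste(names(prevalence)[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  sum(prevalence * met_table$met_median[idx])
}

#' Daily occupational energy expenditure
#'
#' Applies the expenditure formula
#' kcal/workday = hours worked x mean METs x body weight (kg),
#' using the gender's fixed reference weight.
#'
#' @param mean_met mean occupational METs, > 0.
#' @param assumptions an [ee_assumptions()] object.
#' @param gender one of the genders named in the assumptions.
#' @return kcal per workday (scalar).
#' @examples
#' daily_occupational_ee(1, gender = "men")  # 8 * 1 * 76.9 = 615.2
#' @export
daily_occupational_ee <- function(mean_met, assumptions = ee_assumptions(),
                                  gender) {
  stopifnot(inherits(assumptions, "ee_assumptions"))
  if (!is.numeric(mean_met) || any(!is.finite(mean_met) | mean_met <= 0)) {
    stop("mean_met must be positive", call. = FALSE)
  }
  if (length(gender) != 1L ||
      !gender %in% names(assumptions$reference_weight_kg)) {
    stop("unknown gender: ", paste(gender, collapse = ", "), call. = FALSE)
  }
  assumptions$hours_per_workday * mean_met *
    unname(assumptions$reference_weight_kg[gender])
}

#' Yearly activity trend table
#'
#' For each year of an employment series: the prevalence-weighted mean METs,
#' the prevalence of each intensity category (sector prevalences aggregated
#' by the category of each sector's median MET), and the daily occupational
#' energy expenditure per gender.
#'
#' @param series an [employment_series()] object.
#' @param met_table MET assignment table.
#' @param scheme an [intensity_scheme()].
#' @param assumptions an [ee_assumptions()] object.
#' @return A data.frame of class `activity_trend` with columns `year`,
#'   `mean_met`, `prev_sedentary`, `prev_light`, `prev_moderate` and one
#'   `ee_kcal_<gender>` column per gender in the assumptions.
#' @examples
#' s <- generate_employment_series(noise_sd = 0, seed = 1)
#' head(activity_trend(s))
#' @export
activity_trend <- function(series, met_table = met_table_default(),
                           scheme = intensity_scheme(),
                           assumptions = ee_assumptions()) {
  stopifnot(inherits(series, "employment_series"))
  validate_met_table(met_table)
  category <- stats::setNames(classify_intensity(met_table$met_median, scheme),
                              met_table$sector)
  years <- sort(unique(series$records$year))
  genders <- names(assumptions$reference_weight_kg)

  rows <- lapply(years, function(y) {
    p <- sector_prevalence(series, y)
    mm <- mean_met(p, met_table)
    cat_prev <- vapply(c("sedentary", "light", "moderate"), function(cl) {
      sum(p[category[names(p)] == cl])
    }, numeric(1))
    ee <- vapply(genders, function(g) {
      daily_occupational_ee(mm, assumptions, g)
    }, numeric(1))
    c(year = y, mean_met = mm,
      prev_sedentary = unname(cat_prev["sedentary"]),
      prev_light = unname(cat_prev["light"]),
      prev_moderate = unname(cat_prev["moderate"]),
      stats::setNames(ee, paste0("ee_kcal_", genders)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  class(out) <- c("activity_trend", "data.frame")
  out
}

#' Write an activity trend table as CSV
#'
#' @param trend an [activity_trend()] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_activity_trend <- function(trend, path) {
  utils::write.csv(as.data.frame(trend), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Plot intensity-category prevalences and energy expenditure over time
#'
#' Two stacked panels: yearly prevalence of sedentary, light and moderate
#' intensity occupations, and daily occupational energy expenditure per
#' gender.
#'
#' @param x an [activity_trend()] table.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.activity_trend <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  graphics::matplot(x$year,
                    cbind(x$prev_sedentary, x$prev_light, x$prev_moderate),
                    type = "l", lty = 1, col = c(4, 3, 2),
                    xlab = "Year", ylab = "Prevalence",
                    main = "Intensity-category prevalence", ...)
  graphics::legend("topleft", c("sedentary", "light", "moderate"),
                   col = c(4, 3, 2), lty = 1, bty = "n")
  ee_cols <- grep("^ee_kcal_", names(x), value = TRUE)
  graphics::matplot(x$year, as.matrix(x[ee_cols]),
                    type = "l", lty = 1, col = seq_along(ee_cols),
                    xlab = "Year", ylab = "kcal/workday",
                    main = "Daily occupational energy expenditure", ...)
  graphics::legend("topright", sub("^ee_kcal_", "", ee_cols),
                   col = seq_along(ee_cols), lty = 1, bty = "n")
  invisible(x)
}
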