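#' Energy-balance model of body-weight change
#'
#' A single-compartment energy-balance differential equation for population
#' mean body weight W (kg):
#' \deqn{dW/dt = (-\Delta_{EE} - \gamma (W - W_0)) / \rho}
#' where \eqn{\Delta_{EE}} is a sustained change in daily energy expenditure
#' (kcal/day, negative for a reduction), \eqn{\gamma} is the marginal total
#' energy expenditure per kg of body weight (kcal kg^-1 day^-1), \eqn{W_0}
#' the baseline weight and \eqn{\rho} the energy density of tissue change
#' (kcal/kg). Intake is held fixed; as weight rises, weight-dependent
#' expenditure grows until it offsets the imposed reduction, giving the
#' steady state \eqn{W^* = W_0 - \Delta_{EE}/\gamma}.
#'
#' By default \eqn{\gamma} is calibrated so the model reproduces a published
#' kg-per-kcal steady-state sensitivity (`target_ratio`): 0.090 kg per
#' kcal/day for men and 0.092 for women, i.e. \eqn{\gamma} = 1/0.090 and
#' 1/0.092. \eqn{\rho} affects only the approach timescale, never the steady
#' state.
#'
#' @param gender `"men"` or `"women"`; sets the default baseline weight and
#'   sensitivity.
#' @param baseline_weight_kg baseline (1960-62 NHANES mean) weight, kg;
#'   defaults to 76.9 (men) / 64.9 (women).
#' @param gamma marginal expenditure slope, kcal kg^-1 day^-1; overrides
#'   `target_ratio` when given.
#' @param target_ratio steady-state kg gained per kcal/day expenditure
#'   reduction; `gamma` is its reciprocal. Defaults to 0.090 (men) / 0.092
#'   (women).
#' @param rho energy density of tissue change, kcal/kg; default 7700.
#' @return An object of class `energy_balance_model` with components
#'   `gender`, `baseline_weight_kg`, `gamma`, `rho`.
#' @seealso [steady_state_weight()], [simulate_weight()],
#'   [kg_per_kcal_ratio()], [predict_trajectory()]
#' @examples
#' m <- energy_balance_model("men")
#' coef(m)
#' predict(m, delta_ee = -142)  # 89.7 kg
#' @export
energy_balance_model <- function(gender = c("men", "women"),
                                 baseline_weight_kg = NULL,
                                 gamma = NULL,
                                 target_ratio = NULL,
                                 rho = 7700) {
  gender <- match.arg(gender)
  if (is.null(baseline_weight_kg)) {
    baseline_weight_kg <- switch(gender, men = 76.9, women = 64.9)
  }
  if (is.null(gamma)) {
    if (is.null(target_ratio)) {
      target_ratio <- switch(gender, men = 0.090, women = 0.092)
    }
    gamma <- calibrate_gamma(target_ratio)
  }
  stopifnot(baseline_weight_kg > 0, gamma > 0, rho > 0)
  structure(list(gender = gender,
                 baseline_weight_kg = baseline_weight_kg,
                 gamma = gamma,
                 rho = rho),
            class = "energy_balance_model")
}

#' @export
print.energy_balance_model <- function(x, ...) {
  cat("Energy-balance model (single compartment, linear)\n")
  cat(sprintf("  gender: %s;  baseline weight: %.1f kg\n",
              x$gender, x$baseline_weight_kg))
  cat(sprintf("  gamma: %.4f kcal/kg/day  (1/gamma = %.3f kg per kcal/day)\n",
              x$gamma, 1 / x$gamma))
  cat(sprintf("  rho:   %.0f kcal/kg (tissue energy density)\n", x$rho))
  invisible(x)
}

#' @export
coef.energy_balance_model <- function(object, ...) {
  c(baseline_weight_kg = object$baseline_weight_kg,
    gamma = object$gamma,
    rho = object$rho)
}

#' @export
summary.energy_balance_model <- function(object, ...) {
  out <- list(model = object,
              kg_per_kcal = 1 / object$gamma,
              half_life_days = log(2) * object$rho / object$gamma)
  class(out) <- "summary.energy_balance_model"
  out
}

#' @export
print.summary.energy_balance_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  steady-state sensitivity: %.3f kg per kcal/day\n",
              x$kg_per_kcal))
  cat(sprintf("  approach half-life: %.0f days (%.1f years)\n",
              x$half_life_days, x$half_life_days / 365.25))
  invisible(x)
}

#' Closed-form steady-state weight
#'
#' The weight at which weight-dependent expenditure exactly offsets a
#' sustained change in daily expenditure: `W0 - delta_ee / gamma`. A
#' negative `delta_ee` (an expenditure reduction) raises weight.
#'
#' @param model an [energy_balance_model()].
#' @param delta_ee change in daily energy expenditure, kcal/day (negative =
#'   reduction). May be a vector.
#' @return Steady-state weight(s), kg.
#' @examples
#' steady_state_weight(energy_balance_model("men"), -142)  # 89.68 kg
#' @export
steady_state_weight <- function(model, delta_ee) {
  stopifnot(inherits(model, "energy_balance_model"), is.numeric(delta_ee))
  model$baseline_weight_kg - delta_ee / model$gamma
}

#' @rdname steady_state_weight
#' @param object an [energy_balance_model()].
#' @param ... unused.
#' @export
predict.energy_balance_model <- function(object, delta_ee = 0, ...) {
  steady_state_weight(object, delta_ee)
}

#' Simulate the weight trajectory to steady state
#'
#' Numerically integrates the model from the baseline weight under a
#' sustained expenditure change, terminating when the daily rate of weight
#' change falls below `tolerance` or at the horizon. Integration uses
#' lsoda on a daily grid.
#'
#' @param model an [energy_balance_model()].
#' @param delta_ee change in daily energy expenditure, kcal/day.
#' @param horizon_days simulation horizon, days (default 30 years).
#' @param tolerance convergence threshold on |dW/dt|, kg/day.
#' @param step_days output/termination grid spacing, days; the reported
#'   terminal weight is the first grid point whose rate is below tolerance.
#' @param rtol,atol relative and absolute integrator tolerances.
#' @return An object of class `weight_simulation`: `weight_kg` (terminal),
#'   `delta_weight_kg`, `delta_ee_kcal`, `converged`, `days_to_tolerance`,
#'   and the `trajectory` data.frame (`day`, `weight_kg`).
#' @examples
#' sim <- simulate_weight(energy_balance_model("men"), delta_ee = -142)
#' sim$weight_kg
#' @export
simulate_weight <- function(model, delta_ee,
                            horizon_days = 30 * 365.25,
                            tolerance = 1e-6,
                            step_days = 1,
                            rtol = 1e-10, atol = 1e-10) {
  stopifnot(inherits(model, "energy_balance_model"),
            length(delta_ee) == 1L, is.finite(delta_ee),
            horizon_days > 0, tolerance > 0, step_days > 0)
  w0 <- model$baseline_weight_kg

  rate <- function(w) (-delta_ee - model$gamma * (w - w0)) / model$rho

  if (abs(rate(w0)) < tolerance) {
    # already at (numerical) steady state, e.g. delta_ee = 0
    return(structure(list(weight_kg = w0, delta_weight_kg = 0,
                          delta_ee_kcal = delta_ee, converged = TRUE,
                          days_to_tolerance = 0,
                          trajectory = data.frame(day = 0, weight_kg = w0)),
                     class = "weight_simulation"))
  }

  times <- seq(0, ceiling(horizon_days), by = step_days)
  sol <- deSolve::ode(
    y = c(W = w0), times = times,
    func = function(t, y, parms) list(rate(y[1])),
    parms = NULL, method = "lsoda",
    rtol = rtol, atol = atol)
  w <- sol[, "W"]
  rates <- abs(vapply(w, rate, numeric(1)))
  hit <- which(rates < tolerance)
  converged <- length(hit) > 0L
  stop_i <- if (converged) hit[1L] else length(w)
  traj <- data.frame(day = times[seq_len(stop_i)],
                     weight_kg = unname(w[seq_len(stop_i)]))
  structure(list(weight_kg = unname(w[stop_i]),
                 delta_weight_kg = unname(w[stop_i]) - w0,
                 delta_ee_kcal = delta_ee,
                 converged = converged,
                 days_to_tolerance = if (converged) times[stop_i] else NA_real_,
                 trajectory = traj),
            class = "weight_simulation")
}

#' @export
print.weight_simulation <- function(x, ...) {
  cat(sprintf(
    "Weight simulation: delta_ee %+.1f kcal/day -> %.2f kg (%+.2f kg)\n",
    x$delta_ee_kcal, x$weight_kg, x$delta_weight_kg))
  cat(if (x$converged) {
    sprintf("  converged after %d days\n", as.integer(x$days_to_tolerance))
  } else "  did not converge within horizon\n")
  invisible(x)
}

#' @export
plot.weight_simulation <- function(x, ...) {
  graphics::plot(x$trajectory$day / 365.25, x$trajectory$weight_kg,
                 type = "l", xlab = "Years", ylab = "Weight (kg)",
                 main = sprintf("Approach to steady state (%+.0f kcal/day)",
                                x$delta_ee_kcal), ...)
  invisible(x)
}

#' Steady-state weight change per kcal/day of expenditure reduction
#'
#' Reproduces the published calibration procedure: simulate sustained
#' expenditure reductions of 50, 100 and 150 kcal/day each to steady state,
#' form the ratio of steady-state weight change to the size of each
#' reduction, and average the three ratios.
#'
#' @param model an [energy_balance_model()].
#' @param increments expenditure reductions to simulate, kcal/day (positive
#'   magnitudes).
#' @param ... passed to [simulate_weight()].
#' @return Mean kg gained per kcal/day of expenditure reduction, with the
#'   per-increment ratios attached as attribute `"ratios"`.
#' @examples
#' round(kg_per_kcal_ratio(energy_balance_model("men")), 3)    # 0.090
#' round(kg_per_kcal_ratio(energy_balance_model("women")), 3)  # 0.092
#' @export
kg_per_kcal_ratio <- function(model, increments = c(50, 100, 150), ...) {
  stopifnot(inherits(model, "energy_balance_model"), all(increments > 0))
  ratios <- vapply(increments, function(inc) {
    sim <- simulate_weight(model, delta_ee = -inc, ...)
    if (!sim$converged) {
      stop(sprintf("simulation did not converge for the %g kcal/day increment",
                   inc), call. = FALSE)
    }
    sim$delta_weight_kg / inc
  }, numeric(1))
  structure(mean(ratios), ratios = stats::setNames(ratios, increments))
}

#' Calibrate the expenditure slope from a kg-per-kcal sensitivity
#'
#' Inverts the model: the steady-state weight change per kcal/day is
#' `1/gamma`, so the slope matching a published sensitivity is its
#' reciprocal.
#'
#' @param target_ratio kg per kcal/day, > 0.
#' @return `gamma`, kcal kg^-1 day^-1.
#' @examples
#' calibrate_gamma(0.090)  # 11.111...
#' @export
calibrate_gamma <- function(target_ratio) {
  if (!is.numeric(target_ratio) || length(target_ratio) != 1L ||
      !is.finite(target_ratio) || target_ratio <= 0) {
    stop("target_ratio must be a positive number", call. = FALSE)
  }
  1 / target_ratio
}

#' Predict a weight trajectory across survey periods
#'
#' For each period, the change in occupational expenditure per workday
#' relative to the baseline (first) period is converted to a per-calendar-day
#' change — multiplied by the workweek factor (5/7) when `apply_workweek` is
#' `TRUE`, taken as-is otherwise — and mapped to the steady-state weight.
#' Observed mean weights (e.g. NHANES anchors) are attached when provided.
#'
#' @param model an [energy_balance_model()].
#' @param ee_by_period data.frame with columns `period` (label), `mid_year`
#'   (optional) and `ee_kcal_workday` (occupational kcal per workday), first
#'   row the baseline; or a named numeric vector of per-workday EE.
#' @param assumptions an [ee_assumptions()] object (supplies the workweek
#'   factor).
#' @param apply_workweek apply the 5/7 workweek factor to expenditure
#'   changes.
#' @param observed optional named numeric: observed mean weight (kg) by
#'   period label.
#' @return A data.frame of class `weight_trajectory` with columns `period`,
#'   `mid_year`, `delta_ee_workday`, `delta_ee_daily`, `predicted_kg`,
#'   `observed_kg`.
#' @examples
#' m <- energy_balance_model("men")
#' ee <- c(`1960-62` = 1600, `2003-06` = 1458)
#' predict_trajectory(m, ee, apply_workweek = FALSE,
#'                    observed = c(`2003-06` = 91.8))
#' @export
predict_trajectory <- function(model, ee_by_period,
                               assumptions = ee_assumptions(),
                               apply_workweek = TRUE,
                               observed = NULL) {
  stopifnot(inherits(model, "energy_balance_model"),
            inherits(assumptions, "ee_assumptions"))
  if (is.numeric(ee_by_period)) {
    if (length(ee_by_period) == 0L) {
      stop("ee_by_period must contain at least the baseline period",
           call. = FALSE)
    }
    ee_by_period <- data.frame(period = names(ee_by_period),
                               mid_year = NA_real_,
                               ee_kcal_workday = unname(ee_by_period),
                               stringsAsFactors = FALSE)
  }
  if (nrow(ee_by_period) == 0L) {
    stop("ee_by_period must contain at least the baseline period",
         call. = FALSE)
  }
  if (!all(c("period", "ee_kcal_workday") %in% names(ee_by_period))) {
    stop("ee_by_period needs columns period and ee_kcal_workday",
         call. = FALSE)
  }
  if (any(ee_by_period$ee_kcal_workday <= 0)) {
    stop("per-workday EE values must be positive", call. = FALSE)
  }
  if (!"mid_year" %in% names(ee_by_period)) {
    ee_by_period$mid_year <- NA_real_
  }
  factor <- if (apply_workweek) assumptions$workweek_factor else 1
  baseline_ee <- ee_by_period$ee_kcal_workday[1L]
  delta_workday <- ee_by_period$ee_kcal_workday - baseline_ee
  delta_daily <- delta_workday * factor
  out <- data.frame(
    period = ee_by_period$period,
    mid_year = ee_by_period$mid_year,
    delta_ee_workday = delta_workday,
    delta_ee_daily = delta_daily,
    predicted_kg = steady_state_weight(model, delta_daily),
    observed_kg = if (is.null(observed)) NA_real_ else
      unname(observed[match(ee_by_period$period, names(observed))]),
    stringsAsFactors = FALSE)
  attr(out, "gender") <- model$gender
  attr(out, "apply_workweek") <- apply_workweek
  class(out) <- c("weight_trajectory", "data.frame")
  out
}

#' Plot predicted vs observed weights by survey period
#'
#' @param x a [predict_trajectory()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.weight_trajectory <- function(x, ...) {
  xs <- if (all(is.na(x$mid_year))) seq_len(nrow(x)) else x$mid_year
  ylim <- range(c(x$predicted_kg, x$observed_kg), na.rm = TRUE)
  graphics::plot(xs, x$predicted_kg, type = "b", pch = 16, ylim = ylim,
                 xlab = "Period mid-year", ylab = "Mean weight (kg)",
                 main = sprintf("Predicted vs observed weight (%s)",
                                attr(x, "gender") %||% ""), ...)
  if (any(!is.na(x$observed_kg))) {
    graphics::points(xs, x$observed_kg, pch = 1, col = 2)
    graphics::legend("topleft", c("predicted", "observed"),
                     pch = c(16, 1), col = c(1, 2), bty = "n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
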