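# Independent oracles used across test files. These are coded from first
# principles (closed forms, brute-force sums), not by calling the package
# functions they check.

# Closed-form simple linear regression of y on x with two-sided slope t-test.
ols_oracle <- function(x, y) {
  n <- length(x)
  xbar <- sum(x) / n
  ybar <- sum(y) / n
  sxx <- sum((x - xbar)^2)
  sxy <- sum((x - xbar) * (y - ybar))
  beta <- sxy / sxx
  alpha <- ybar - beta * xbar
  rss <- sum((y - alpha - beta * x)^2)
  s2 <- rss / (n - 2)
  tstat <- beta / sqrt(s2 / sxx)
  list(slope = beta, p_value = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Closed-form solution of dW/dt = (-delta - gamma (W - W0)) / rho at time t.
ode_closed_form <- function(w0, gamma, rho, delta_ee, t) {
  wstar <- w0 - delta_ee / gamma
  wstar + (w0 - wstar) * exp(-gamma * t / rho)
}

# Tiny valid employment data.frame builder.
make_records <- function(years, sectors, counts) {
  expand <- expand.grid(year = years, sector = sectors,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand$employed_thousands <- counts
  expand
}
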