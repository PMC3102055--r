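test_that("packaged MET table carries the published sector assignments", {
  tab <- met_table_default()
  expect_equal(nrow(tab), 11)
  expect_setequal(tab$sector, sector_ids())
  row <- function(s) tab[tab$sector == s, ]
  expect_equal(row("construction")[, c("met_median", "met_min", "met_max")],
               data.frame(met_median = 4.0, met_min = 1.5, met_max = 7.5),
               ignore_attr = TRUE)
  expect_equal(row("construction")$category, "moderate")
  expect_equal(row("information")$met_median, 1.5)
  expect_equal(row("information")$category, "sedentary")
  expect_equal(row("farm")[, c("met_median", "met_min", "met_max")],
               data.frame(met_median = 3.0, met_min = 2.5, met_max = 4.5),
               ignore_attr = TRUE)
  expect_equal(row("farm")$category, "moderate")
  expect_true(all(tab$met_min <= tab$met_median & tab$met_median <= tab$met_max))
  expect_identical(classify_intensity(tab$met_median), tab$category)
})

test_that("intensity classification uses half-open intervals", {
  expect_equal(classify_intensity(c(0.5, 1.5, 1.9999)), rep("sedentary", 3))
  expect_equal(classify_intensity(c(2.0, 2.5, 2.9999)), rep("light", 3))
  expect_equal(classify_intensity(c(3.0, 4.0, 5.9999)), rep("moderate", 3))
  expect_error(classify_intensity(0), "positive")
  expect_error(classify_intensity(-1), "positive")
  expect_error(classify_intensity(6), "no category")
  expect_error(classify_intensity(8), "no category")
  expect_error(intensity_scheme(3, 2, 6), "cutpoints")
})

test_that("mean METs is the prevalence-weighted median, checked by oracle", {
  expect_equal(mean_met(c(manufacturing = 1)), 3.0)
  expect_equal(mean_met(c(construction = 0.5, financial = 0.5)), 2.75)

  p <- default_anchor_set()$prevalence_start
  tab <- met_table_default()
  dot <- 0
  for (s in names(p)) dot <- dot + p[[s]] * tab$met_median[tab$sector == s]
  expect_equal(mean_met(p, tab), dot, tolerance = 1e-12)
  expect_gte(mean_met(p, tab), min(tab$met_median))
  expect_lte(mean_met(p, tab), max(tab$met_median))

  expect_error(mean_met(c(farm = 1), tab[tab$sector != "farm", ]),
               "missing from MET table")
  expect_error(mean_met(c(farm = 0.4, manufacturing = 0.4)), "sum to 1")
})

test_that("daily expenditure applies hours x METs x weight", {
  expect_equal(daily_occupational_ee(1, gender = "men"), 615.2)
  expect_equal(daily_occupational_ee(2.57, gender = "women"),
               2.57 * 8 * 64.9, tolerance = 1e-9)
  expect_error(daily_occupational_ee(0, gender = "men"), "positive")
  expect_error(daily_occupational_ee(2, gender = "child"), "unknown gender")
})

test_that("daily expenditure is homogeneous of degree 1 in each factor", {
  set.seed(5)
  for (i in 1:10) {
    k <- runif(1, 0.2, 5)
    met <- runif(1, 1, 5.9)
    a1 <- ee_assumptions(hours_per_workday = 6,
                         reference_weight_kg = c(men = 80))
    a2 <- ee_assumptions(hours_per_workday = 6 * min(k, 4),
                         reference_weight_kg = c(men = 80))
    a3 <- ee_assumptions(hours_per_workday = 6,
                         reference_weight_kg = c(men = 80 * k))
    base <- daily_occupational_ee(met, a1, "men")
    expect_equal(daily_occupational_ee(met * k, a1, "men") / base, k,
                 tolerance = 1e-12)
    expect_equal(daily_occupational_ee(met, a2, "men") / base, min(k, 4),
                 tolerance = 1e-12)
    expect_equal(daily_occupational_ee(met, a3, "men") / base, k,
                 tolerance = 1e-12)
  }
})

test_that("activity trend aggregates sectors into categories consistently", {
  one <- employment_series(data.frame(year = 1990, sector = "manufacturing",
                                      employed_thousands = 100))
  tr <- activity_trend(one)
  expect_equal(tr$prev_moderate, 1)
  expect_equal(tr$prev_sedentary, 0)
  expect_equal(tr$mean_met, 3.0)

  s <- generate_employment_series(noise_sd = 0.05, seed = 9)
  tr <- activity_trend(s)
  tab <- met_table_default()
  cat_of <- stats::setNames(tab$category, tab$sector)
  for (y in c(1965, 1985, 2005)) {
    p <- sector_prevalence(s, y)
    expect_identical(tr$prev_moderate[tr$year == y],
                     sum(p[cat_of[names(p)] == "moderate"]))
    expect_identical(tr$prev_light[tr$year == y],
                     sum(p[cat_of[names(p)] == "light"]))
  }
  expect_equal(tr$prev_sedentary + tr$prev_light + tr$prev_moderate,
               rep(1, nrow(tr)), tolerance = 1e-9)
})

test_that("anchored noiseless series reproduces the printed category anchors", {
  s <- generate_employment_series(noise_sd = 0, seed = 1)
  tr <- activity_trend(s)
  expect_equal(tr$prev_moderate[tr$year == 1960], 0.48, tolerance = 0.005)
  expect_equal(tr$prev_moderate[tr$year == 2008], 0.20, tolerance = 0.005)
  expect_equal(sector_prevalence(s, 1960)[["manufacturing"]], 0.30,
               tolerance = 0.005)
})

test_that("men's and women's expenditure differ only by the weight ratio", {
  s <- generate_employment_series(noise_sd = 0.03, seed = 13)
  tr <- activity_trend(s)
  expect_equal(tr$ee_kcal_men, tr$ee_kcal_women * 76.9 / 64.9,
               tolerance = 1e-9)
})

test_that("shifting mass from moderate to sedentary sectors never raises mean METs", {
  set.seed(31)
  tab <- met_table_default()
  moderate <- tab$sector[tab$category == "moderate"]
  sedentary <- tab$sector[tab$category == "sedentary"]
  for (i in 1:20) {
    p <- stats::setNames(stats::runif(11), sector_ids())
    p <- p / sum(p)
    from <- sample(moderate, 1)
    to <- sample(sedentary, 1)
    shift <- stats::runif(1, 0, p[[from]])
    q <- p
    q[[from]] <- q[[from]] - shift
    q[[to]] <- q[[to]] + shift
    expect_lte(mean_met(q, tab), mean_met(p, tab) + 1e-12)
  }
})
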