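test_that("descriptive summaries report the standard statistics", {
  d <- data.frame(
    grp = rep("A", 1000),
    cat = c(rep("yes", 172), rep("no", 828)),
    val = c(1, 2, 3, 4, 100, rep(3, 995)))
  out <- describe_cohort(d, c("cat", "val"), strata = "grp")
  yes <- out[out$variable == "cat" & out$level == "yes", ]
  expect_equal(yes$count, 172)
  expect_equal(yes$pct, 17.2)
  # order statistics on a skewed variable
  v5 <- describe_cohort(data.frame(g = "A", val = c(1, 2, 3, 4, 100)),
                        "val", strata = "g")
  expect_equal(v5$median, 3)
  expect_equal(v5$min, 1)
  expect_equal(v5$max, 100)
  # constant variable: SD 0, min = median = max
  cst <- describe_cohort(data.frame(g = "A", val = rep(7, 10)), "val",
                         strata = "g")
  expect_equal(cst$sd, 0)
  expect_equal(cst$min, cst$median)
  expect_equal(cst$median, cst$max)
})

test_that("test selection follows the expected-frequency and normality rules", {
  # balanced 2x2 with all expected counts 5: Pearson chi-square, p = 1
  d1 <- data.frame(x = rep(c("a", "b"), each = 10),
                   g = rep(c("g1", "g2"), times = 10))
  r1 <- compare_groups(d1, "x", "g")
  expect_equal(r1$test_used, "chi-square")
  expect_equal(r1$p_value, 1)

  # 2x2 [[1,9],[2,8]]: expected cells 1.5/1.5 below 5 (50% > 20%) -> Fisher
  d2 <- data.frame(
    x = c(rep("a", 1), rep("b", 9), rep("a", 2), rep("b", 8)),
    g = c(rep("g1", 10), rep("g2", 10)))
  ex <- suppressWarnings(stats::chisq.test(table(d2$x, d2$g),
                                           correct = FALSE))$expected
  expect_equal(mean(ex < 5), 0.5)
  r2 <- suppressWarnings(compare_groups(d2, "x", "g"))
  expect_equal(r2$test_used, "Fisher")

  # identical continuous samples in both groups -> p = 1
  d3 <- data.frame(x = rep(c(1, 2, 3, 4, 5), 2),
                   g = rep(c("g1", "g2"), each = 5))
  r3 <- compare_groups(d3, "x", "g")
  expect_true(r3$test_used %in% c("t-test", "Mann-Whitney"))
  expect_equal(r3$p_value, 1)

  # heavy-tailed data fail the normality gate -> Mann-Whitney
  set.seed(31)
  d4 <- data.frame(x = exp(c(rnorm(60, 0, 2), rnorm(60, 0.2, 2))),
                   g = rep(c("g1", "g2"), each = 60))
  expect_equal(compare_groups(d4, "x", "g")$test_used, "Mann-Whitney")

  # three normal groups -> ANOVA; three heavy-tailed -> Kruskal-Wallis
  set.seed(32)
  d5 <- data.frame(x = rnorm(150), g = rep(c("g1", "g2", "g3"), each = 50))
  expect_equal(compare_groups(d5, "x", "g")$test_used, "ANOVA")
  d6 <- data.frame(x = exp(rnorm(150, 0, 2)),
                   g = rep(c("g1", "g2", "g3"), each = 50))
  expect_equal(compare_groups(d6, "x", "g")$test_used, "Kruskal-Wallis")

  # a group with fewer than 2 observations is an error naming the group
  d7 <- data.frame(x = c(1, 2, 3), g = c("g1", "g1", "g2"))
  expect_error(compare_groups(d7, "x", "g"), "g2")
  expect_error(compare_groups(data.frame(x = 1:3, g = "only"), "x", "g"),
               "2 non-empty")
})

test_that("incidence rates use the exact Poisson interval", {
  # zero events: closed-form upper bound per * (-ln 0.025) / PY
  z <- incidence_rate(0, 1000)
  expect_equal(z$rate, 0)
  expect_equal(z$ci_low, 0)
  expect_equal(z$ci_high, 100000 * (-log(0.025)) / 1000, tolerance = 1e-10)

  # 10 events in 100,000 PY: rate 10, CI brackets the rate
  e <- incidence_rate(10, 1e5)
  expect_equal(e$rate, 10)
  expect_lt(e$ci_low, 10)
  expect_gt(e$ci_high, 10)

  # 3 events in 50,000 PY against the tail-inversion oracle
  e3 <- incidence_rate(3, 50000)
  want <- poisson_ci_oracle(3, 50000)
  expect_equal(e3$ci_low, unname(want["lo"]), tolerance = 1e-7)
  expect_equal(e3$ci_high, unname(want["hi"]), tolerance = 1e-7)

  expect_error(incidence_rate(3, 0), "positive")
  expect_error(incidence_rate(-1, 10), "non-negative")
})

test_that("cohort incidence aggregates events and person-years by arm", {
  d <- toy_survival(time = c(1, 2, 3, 4), status = c(1, 0, 1, 1),
                    arm = c("A", "A", "B", "B"))
  inc <- cohort_incidence(d, per = 100)
  expect_equal(inc$events[inc$group == "A"], 1)
  expect_equal(inc$person_years[inc$group == "A"], 3)
  expect_equal(inc$rate[inc$group == "B"], 100 * 2 / 7)
})

test_that("the Cox fit matches a hand-written partial-likelihood grid search", {
  d <- toy_survival(time = c(1, 2, 3, 4), status = c(1, 1, 0, 0),
                    arm = c("treat", "control", "treat", "control"))
  fit <- fit_cox(d, reference_arm = "control")
  beta_hat <- log(fit$hr[fit$term == "treat"])
  beta_oracle <- cox_grid_oracle(c(1, 2, 3, 4), c(1, 1, 0, 0), c(1, 0, 1, 0))
  expect_lt(abs(beta_hat - beta_oracle), 1e-3)
  # closed form for this dataset: exp(beta) = sqrt(2)
  expect_equal(unname(exp(beta_hat)), sqrt(2), tolerance = 1e-6)
})

test_that("Cox output carries the reference arm and recovery of a null effect", {
  cfg <- one_stratum_scenario(n = 10000, hr = 1, lambda = 0.1, seed = 23)
  tabs <- simulated_tables(cfg)
  linked <- link_tables(tabs$registry, tabs$claims, "DII", tabs$truth)
  fit <- fit_cox(linked, reference_arm = "non-RT")
  expect_equal(fit$hr[fit$reference], 1)
  expect_equal(fit$term[fit$reference], "non-RT")
  hr <- fit$hr[fit$is_treatment & !fit$reference]
  expect_gt(hr, 0.9)
  expect_lt(hr, 1.1)
  expect_false(isTRUE(attr(fit, "adjusted")))
})

test_that("Cox errors and flags behave as specified", {
  d <- toy_survival(time = 1:6, status = rep(0, 6),
                    arm = rep(c("A", "B"), 3))
  expect_error(fit_cox(d), "no events")
  expect_error(fit_cox(toy_survival(numeric(0), integer(0), character(0))),
               "empty")
  d2 <- toy_survival(time = c(0, 1, 2, 3), status = c(1, 1, 0, 0),
                     arm = rep(c("A", "B"), 2))
  expect_error(fit_cox(d2), "positive")
  # complete separation is flagged, not silent
  d3 <- toy_survival(time = c(1, 2, 3, 10, 11, 12),
                     status = c(1, 1, 1, 0, 0, 0),
                     arm = rep(c("A", "B"), each = 3))
  fit3 <- fit_cox(d3)
  expect_true(nzchar(fit3$flag[1]))
})

test_that("constant covariates are dropped instead of breaking the fit", {
  cfg <- one_stratum_scenario(n = 2000, hr = 1.5, lambda = 0.1, seed = 29)
  tabs <- simulated_tables(cfg)
  linked <- link_tables(tabs$registry, tabs$claims, "DII", tabs$truth)
  # sex is constant in a cervical stratum
  fit <- fit_cox(linked, covariates = c("age_years", "sex"),
                 reference_arm = "non-RT")
  expect_true("sex" %in% attr(fit, "dropped_covariates"))
  expect_true("age_years" %in% attr(fit, "covariates"))
  expect_true(isTRUE(attr(fit, "adjusted")))
  expect_gte(cox_r_squared(fit), 0)
  expect_lt(cox_r_squared(fit), 1)
})

test_that("subgroup analysis stratifies correctly and skips empty strata", {
  cfg <- one_stratum_scenario(n = 3000, hr = 1.5, lambda = 0.1, seed = 37)
  tabs <- simulated_tables(cfg)
  linked <- link_tables(tabs$registry, tabs$claims, "DII", tabs$truth)
  d <- as.data.frame(linked)
  d$one_level <- "all"
  sg <- subgroup_effects(d, stratifier = "one_level", reference_arm = "non-RT")
  full <- fit_cox(d, reference_arm = "non-RT")
  expect_equal(sg[["all"]]$hr, full$hr)

  # a stratum whose members never fracture is skipped with a message
  d$flag_grp <- ifelse(seq_len(nrow(d)) <= 10, "tiny", "rest")
  d$event_indicator[d$flag_grp == "tiny"] <- "censored"
  expect_message(
    sg2 <- subgroup_effects(d, stratifier = "flag_grp",
                            reference_arm = "non-RT"),
    "tiny")
  expect_identical(attr(sg2, "skipped"), "tiny")
  expect_named(sg2, "rest")
})

test_that("a simulated interaction is recovered stratum by stratum", {
  defs <- stratum_definitions()
  make <- function(hr, seed)
    simulated_tables(one_stratum_scenario(n = 5000, hr = hr, lambda = 0.1,
                                          seed = seed))
  ta <- make(2.0, 41); tb <- make(1.0, 43)
  da <- as.data.frame(link_tables(ta$registry, ta$claims, "DII", ta$truth))
  db <- as.data.frame(link_tables(tb$registry, tb$claims, "DII", tb$truth))
  da$layer <- "A"; db$layer <- "B"
  db$uid <- paste0("B", db$uid); db$rid <- paste0("B", db$rid)
  d <- rbind(da, db)
  sg <- subgroup_effects(d, stratifier = "layer", reference_arm = "non-RT")
  for (lv in c("A", "B")) {
    truth <- if (lv == "A") 2.0 else 1.0
    row <- sg[[lv]][sg[[lv]]$is_treatment & !sg[[lv]]$reference, ]
    expect_gt(row$ci_high, truth * 0.97, label = paste("stratum", lv))
    expect_lt(row$ci_low, truth * 1.03, label = paste("stratum", lv))
  }
})
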