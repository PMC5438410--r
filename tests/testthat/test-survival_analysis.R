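test_that("endpoint rules map statuses to events and exclude DUC", {
  subj <- make_subjects(4, status = c("DFS", "AWD", "DOD", "DUC"))
  os <- prepare_survival(subj, "OS")
  expect_equal(nrow(os), 3)
  expect_equal(os$event, c(0, 0, 1))
  expect_equal(attr(os, "n_excluded"), 1)
  dfs <- prepare_survival(subj, "DFS")
  expect_equal(dfs$event, c(0, 1, 1))

  spec <- simulation_spec(seed = 12)
  cohort <- simulate_cohort(spec)
  os <- prepare_survival(cohort, "OS")
  n_bad <- sum(cohort$status %in% c("DUC", "lost", "alive_unknown") |
                 is.na(cohort$followup_months))
  expect_equal(nrow(os), nrow(cohort) - n_bad)
})

test_that("Kaplan-Meier estimate matches hand products and the empirical
          survival function without censoring", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  expect_equal(nrow(km_curve(c(4, 9), c(0, 0))), 0)  # all censored: S = 1

  expect_equal(km_curve(5, 1)$survival, 0)

  set.seed(71)
  t <- rexp(80)
  km <- km_curve(t, rep(1, 80))
  emp <- vapply(km$time, function(x) mean(t > x), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
  expect_true(all(diff(km$survival) <= 0))
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("Kaplan-Meier and log-rank agree with the survival package", {
  skip_if_not_installed("survival")
  set.seed(72)
  t <- round(rexp(120) * 20); e <- rbinom(120, 1, 0.6)
  g <- sample(c("a", "b", "c"), 120, TRUE)
  km <- km_curve(t, e)
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  expect_equal(km$survival, summary(sf, times = km$time)$surv,
               tolerance = 1e-12)
  lr <- logrank(t, e, g)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(lr$statistic, sd$chisq, tolerance = 1e-10)
  expect_equal(unname(lr$observed), unname(sd$obs), tolerance = 1e-12)
})

test_that("log-rank is zero for identical groups and matches a hand
          O-E computation", {
  t <- c(3, 5, 8, 11); e <- c(1, 0, 1, 1)
  lr <- logrank(c(t, t), c(e, e), rep(c("x", "y"), each = 4))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  # A events at 1,2; B events at 3,4; no censoring
  # t=1: E_A = 2/4; t=2: E_A = 1/3; t=3,4: E_A = 0 -> O-E = 2 - 5/6
  # V = (2/4)(2/4) + (1/3)(2/3) = 0.25 + 2/9
  lr <- logrank(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  oe <- 2 - (2 / 4 + 1 / 3)
  v <- (2 / 4) * (2 / 4) + (1 / 3) * (2 / 3)
  expect_equal(lr$statistic, oe^2 / v, tolerance = 1e-12)
  expect_equal(unname(lr$observed), c(2, 2))
  expect_equal(unname(lr$expected), c(5 / 6, 4 - 5 / 6), tolerance = 1e-12)
  # two-group statistic is the squared standardized O-E (consistency)
  expect_equal(lr$statistic,
               (lr$observed[1] - lr$expected[1])^2 / v,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(logrank(t, c(0, 0, 0, 0), c("A", "A", "B", "B")),
               "no events")
})

test_that("Cox partial likelihood matches hand-enumerated risk-set products
          on a tiny dataset", {
  # 4 subjects, no ties: events at 1, 3; censored at 2, 4
  time <- c(1, 2, 3, 4); event <- c(1, 0, 1, 0); x <- c(1, 0, 1, 0)
  fit <- cox_fit(time, event, cbind(x = x), max_iter = 1)
  # log PL at beta: sum over events of xb - log(sum_{risk} exp(xb))
  hand <- function(b) {
    (b - log(2 * exp(b) + 2)) + (b - log(exp(b) + 1))
  }
  expect_equal(fit$loglik_null, hand(0), tolerance = 1e-12)
  full <- cox_fit(time, event, cbind(x = x))
  expect_equal(full$loglik, hand(full$coefficients$coef), tolerance = 1e-10)
})

test_that("Cox fit agrees with coxph under Efron ties", {
  skip_if_not_installed("survival")
  set.seed(81)
  n <- 150
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  t <- round(rexp(n, exp(-0.6 * x1 + 0.3 * x2) * 0.1) * 2)
  e <- rbinom(n, 1, 0.75)
  fit <- cox_fit(t, e, cbind(x1 = x1, x2 = x2))
  ref <- survival::coxph(survival::Surv(t, e) ~ x1 + x2, ties = "efron")
  expect_true(fit$converged)
  expect_equal(fit$coefficients$coef, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$coef))
})

test_that("Cox fit is calibrated under the null and flags degeneracy", {
  d <- simulate_survival_data(500, hr = 1, prevalence = 0.4,
                              base_hazard = 0.01, censor_max = 300,
                              seed = 82)
  fit <- cox_fit(d$time, d$event, cbind(marker = d$marker))
  expect_gte(fit$coefficients$hr, 0.85)
  expect_lte(fit$coefficients$hr, 1.18)

  expect_error(cox_fit(d$time, d$event, cbind(k = rep(1, 500))),
               "degenerate covariate")
  expect_error(cox_fit(d$time, rep(0, 500), cbind(m = d$marker)),
               "no events")
  # complete separation: marker perfectly splits event times
  sep <- data.frame(time = c(1, 2, 3, 4, 10, 11, 12, 13),
                    event = 1, x = c(1, 1, 1, 1, 0, 0, 0, 0))
  fit <- cox_fit(sep$time, sep$event, cbind(x = sep$x))
  expect_false(fit$converged)
})

test_that("Cox estimates are unbiased on data simulated from the model", {
  coefs <- vapply(1:120, function(r) {
    d <- simulate_survival_data(1000, hr = 0.5, prevalence = 0.3,
                                base_hazard = 0.01, censor_max = 800,
                                seed = 9000 + r)
    cox_fit(d$time, d$event, cbind(m = d$marker))$coefficients$coef
  }, numeric(1))
  bias <- mean(coefs) - log(0.5)
  expect_lt(abs(bias), 0.1 * abs(log(0.5)))
})

test_that("subgroup filters select the intended strata and compose", {
  subj <- make_subjects(5, stage = c("I", "IIa", "IIb", "III", "IV"))
  expect_equal(nrow(subgroup_filter(subj, "stage_II_III")), 3)

  mixed <- make_subjects(6, subtype = rep(c("insulinoma", "non_insulinoma"),
                                          3))
  expect_equal(unique(subgroup_filter(mixed, "insulinoma")$subtype),
               "insulinoma")
  expect_equal(nrow(subgroup_filter(mixed, "combined")), 6)

  # cohort with the published stage distribution: 98+34+31 = 163 in II-III
  counts <- stage_distribution()
  staged <- make_subjects(sum(counts),
                          stage = rep(names(counts), counts))
  expect_equal(nrow(subgroup_filter(staged, "stage_II_III")), 163)

  both <- subgroup_filter(subgroup_filter(mixed, "insulinoma"),
                          "stage_II_III")
  expect_true(all(both$subtype == "insulinoma" &
                    both$stage %in% c("IIa", "IIb", "III")))
})

test_that("concurrent marker status requires both markers observed", {
  subj <- make_subjects(4,
                        uchl1_percent = c(50, 50, 10, NA),
                        inx_percent = c(80, 10, 80, 80))
  ms <- marker_status(subj)
  expect_equal(ms$concurrent, c("present", "absent", "absent", NA))
})

test_that("cross-sectional report reproduces published outcome rows and
          never drops subjects silently", {
  # disease-free survival: 57/3 present vs 106/62 absent
  subj <- make_subjects(
    228,
    uchl1_percent = c(rep(60, 60), rep(5, 168)),
    inx_percent = c(rep(60, 60), rep(5, 168)),
    status = c(rep("DFS", 57), rep("AWD", 3), rep("DFS", 106),
               rep("AWD", 62)))
  rep1 <- clinicopath_report(subj)
  dfs_row <- rep1[rep1$feature == "disease_free_survival", ]
  expect_equal(signif(dfs_row$p_value, 3), 6.10e-7)
  expect_equal(dfs_row$n, 228)
  expect_equal(dfs_row$n_present + dfs_row$n_absent, dfs_row$n)

  # death: 1/59 present vs 37/133 absent
  subj2 <- make_subjects(
    230,
    uchl1_percent = c(rep(60, 60), rep(5, 170)),
    inx_percent = c(rep(60, 60), rep(5, 170)),
    status = c(rep("DOD", 1), rep("DFS", 59), rep("DOD", 37),
               rep("DFS", 133)))
  rep2 <- clinicopath_report(subj2)
  expect_equal(signif(rep2$p_value[rep2$feature == "death"], 3), 7.79e-5)

  # a feature identical across strata gives p = 1
  same <- make_subjects(40,
                        uchl1_percent = rep(c(60, 5), 20),
                        inx_percent = rep(c(60, 5), 20),
                        sex = rep(c("male", "female"), each = 20))
  rep3 <- clinicopath_report(same)
  expect_equal(rep3$p_value[rep3$feature == "sex"], 1)

  # DUC subjects stay in the demographic rows, leave the survival rows
  duc <- make_subjects(30,
                       uchl1_percent = rep(c(60, 5), 15),
                       inx_percent = rep(c(60, 5), 15),
                       status = c(rep("DUC", 10), rep("DFS", 10),
                                  rep("DOD", 10)))
  rep4 <- clinicopath_report(duc)
  expect_equal(rep4$n[rep4$feature == "death"], 20)
  expect_equal(rep4$n[rep4$feature == "age"], 30)
})
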