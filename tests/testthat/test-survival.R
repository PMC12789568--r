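toy_cohort <- function(times_a, times_b, events_a = NULL, events_b = NULL) {
  n <- length(times_a) + length(times_b)
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    efs_days = c(times_a, times_b),
    efs_event = c(events_a %||% rep(1, length(times_a)),
                  events_b %||% rep(1, length(times_b))),
    relapse = rep(0, n)
  )
}
toy_groups <- function(n_a, n_b) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n_a + n_b)),
             group = rep(c("A", "B"), c(n_a, n_b)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("the triple-marker rule stratifies with explicit cuts", {
  co <- data.frame(patient_id = c("P1", "P2", "P3"),
                   CD68 = c(5, 5, 1), CD163 = c(5, 5, 1),
                   CD40LG = c(1, 4, 1))
  st <- stratify(co, cutpoints = c(CD68 = 3, CD163 = 3, CD40LG = 2))
  expect_identical(st$groups$group, c("uncommon_TME", "other", "other"))
  # identical markers + median cuts: strict ">" puts everyone in "other"
  same <- data.frame(patient_id = paste0("P", 1:4), CD68 = 2, CD163 = 2,
                     CD40LG = 2)
  expect_true(all(stratify(same)$groups$group == "other"))
  # missing markers exclude the patient with a warning
  co$CD68[2] <- NA
  expect_warning(st2 <- stratify(co, c(CD68 = 3, CD163 = 3, CD40LG = 2)),
                 "excluded")
  expect_equal(nrow(st2$groups), 2)
})

test_that("generator-planted groups are recovered at default separation", {
  acc <- vapply(1:50, function(seed) {
    coh <- simulate_cohort(60, group_fraction = 0.4, seed = seed)
    st <- stratify(coh)
    mean(st$groups$group == coh$true_group)
  }, 0)
  expect_gte(mean(acc), 0.99)
})

test_that("KM curves match hand-computed product-limit values", {
  co <- toy_cohort(c(1, 2, 3), c(4, 5, 6))
  res <- km_logrank(co, toy_groups(3, 3), "efs")
  a <- res$curves[res$curves$group == "A", ]
  expect_equal(a$time, c(1, 2, 3))
  expect_equal(a$survival, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(a$n_risk, c(3, 2, 1))
  # with no censoring the KM estimate is the empirical survival function
  b <- res$curves[res$curves$group == "B", ]
  expect_equal(b$survival, 1 - (1:3) / 3, tolerance = 1e-12)
})

test_that("the log-rank statistic matches the survival package", {
  skip_if_not_installed("survival")
  set.seed(8)
  for (rep in 1:5) {
    n <- 40
    co <- data.frame(
      patient_id = sprintf("P%02d", 1:n),
      efs_days = round(rexp(n, 1 / 100)) + 1,
      efs_event = rbinom(n, 1, 0.8),
      relapse = 0
    )
    gr <- data.frame(patient_id = co$patient_id,
                     group = sample(c("A", "B"), n, replace = TRUE))
    res <- km_logrank(co, gr, "efs")
    sd <- survival::survdiff(
      survival::Surv(efs_days, efs_event) ~ group,
      data = merge(co, gr, by = "patient_id"))
    expect_equal(res$chisq, sd$chisq, tolerance = 1e-9)
    expect_equal(res$p, 1 - pchisq(sd$chisq, 1), tolerance = 1e-9)
  }
})

test_that("log-rank p is invariant to time rescaling and null on identity", {
  co <- toy_cohort(c(1, 2, 3), c(4, 5, 6))
  r1 <- km_logrank(co, toy_groups(3, 3))
  co2 <- co; co2$efs_days <- co2$efs_days * 2
  r2 <- km_logrank(co2, toy_groups(3, 3))
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  expect_equal(r1$chisq, r2$chisq, tolerance = 1e-12)
  # two identical groups -> statistic 0, p 1
  co3 <- toy_cohort(c(2, 4, 8), c(2, 4, 8))
  r3 <- km_logrank(co3, toy_groups(3, 3))
  expect_equal(r3$chisq, 0, tolerance = 1e-12)
  expect_equal(r3$p, 1)
})

test_that("relapse Fisher test matches enumeration and handles margins", {
  co <- data.frame(patient_id = sprintf("P%02d", 1:20),
                   relapse = c(rep(c(1, 0), c(1, 9)),
                               rep(c(1, 0), c(8, 2))))
  gr <- toy_groups(10, 10)
  res <- relapse_test(co, gr)
  tab <- rbind(c(1, 9), c(8, 2))
  expect_equal(res$p, fisher_enum_oracle(tab), tolerance = 1e-12)
  # transposing group labels leaves p unchanged
  gr2 <- gr; gr2$group <- rev(gr2$group)
  expect_equal(relapse_test(co, gr2)$p, res$p, tolerance = 1e-12)
  # zero margin: warn and p = 1
  co0 <- co; co0$relapse <- 0
  expect_warning(res0 <- relapse_test(co0, gr), "zero margin")
  expect_equal(res0$p, 1)
})

test_that("Cox fits are invariant to duplicating every patient", {
  coh <- simulate_cohort(120, hazard_ratio = 0.5, seed = 10)
  st <- stratify(coh)
  fit1 <- cox_multivariate(coh, st$groups, "age", ties = "breslow")
  coh2 <- rbind(coh, transform(coh, patient_id = paste0(patient_id, "b")))
  gr2 <- rbind(st$groups,
               transform(st$groups, patient_id = paste0(patient_id, "b")))
  fit2 <- cox_multivariate(coh2, gr2, "age", ties = "breslow")
  expect_equal(fit1$hr, fit2$hr, tolerance = 1e-6)
  expect_error(cox_multivariate(coh, st$groups, "nope"), "absent")
  coh$flat <- 1
  expect_error(cox_multivariate(coh, st$groups, "flat"), "constant")
})

test_that("Cox recovers a planted hazard ratio", {
  hrs <- vapply(1:30, function(seed) {
    coh <- simulate_cohort(300, group_fraction = 0.5, hazard_ratio = 0.5,
                           censor_rate = 0.1, seed = seed)
    st <- stratify(coh)
    fit <- cox_multivariate(coh, st$groups)
    fit$hr[grepl("uncommon", fit$term)]
  }, 0)
  expect_lt(abs(median(hrs) - 0.5) / 0.5, 0.15)
})
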