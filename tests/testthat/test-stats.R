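test_that("upper-tail IQR outlier rule matches the hand-worked example", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4 (type 7), threshold = 4 + 1.5*2 = 7
  res <- exclude_outliers(c(1, 2, 3, 4, 100))
  expect_equal(res$threshold, 7)
  expect_equal(res$excluded, c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$kept, c(1, 2, 3, 4))

  # identical values: IQR 0, nothing strictly above the threshold
  same <- exclude_outliers(rep(5, 6))
  expect_false(any(same$excluded))

  # degenerate inputs pass through
  expect_false(any(exclude_outliers(numeric(0))$excluded))
  expect_equal(exclude_outliers(5)$kept, 5)
  expect_equal(exclude_outliers(c(1, 2, 3))$kept, c(1, 2, 3))

  # low outliers are never removed (upper-side-only rule)
  low <- exclude_outliers(c(-100, 2, 3, 4, 5))
  expect_false(any(low$excluded))
})

test_that("repeating the outlier rule is almost always a no-op (one-shot contract)", {
  # On light-tailed data, upper-tail removal rarely exposes new outliers; on
  # heavy-tailed data it can, and the single pass is the contract regardless.
  set.seed(17)
  noop <- 0
  for (i in 1:1000) {
    x <- rnorm(30)
    first <- exclude_outliers(x)
    second <- exclude_outliers(first$kept)
    noop <- noop + !any(second$excluded)
  }
  expect_gt(noop / 1000, 0.9)
})

test_that("group comparison statistics match closed forms", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  res <- group_compare(x, y, "t_test")
  # pooled-variance Student t computed from scratch
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_value,
               2 * pt(abs(t_manual), length(x) + length(y) - 2,
                      lower.tail = FALSE),
               tolerance = 1e-12)

  same <- group_compare(c(1, 2, 3), c(1, 2, 3), "t_test")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  sep <- group_compare(c(1, 2, 3), c(101, 102, 103), "mann_whitney")
  expect_equal(sep$statistic, 0)           # complete separation: U = 0

  expect_error(group_compare(1, c(1, 2), "t_test"), "at least 2")
  expect_error(group_compare(numeric(0), 1, "mann_whitney"), "non-empty")
})

test_that("univariable standardized beta equals the Pearson correlation", {
  set.seed(23)
  df <- data.frame(x = rnorm(40), e = rnorm(40))
  df$y <- 0.6 * df$x + df$e
  res <- regress_standardized(df, "y", "x")
  expect_equal(res$beta_std, cor(df$x, df$y), tolerance = 1e-12)
  expect_true(res$ci95[1] <= res$beta_std && res$beta_std <= res$ci95[2])
  expect_equal(res$n, 40)

  # y == x: beta 1, CI of zero width
  df2 <- data.frame(x = rnorm(20))
  df2$y <- df2$x
  res2 <- suppressWarnings(regress_standardized(df2, "y", "x"))
  expect_equal(res2$beta_std, 1, tolerance = 1e-10)
  expect_lt(diff(res2$ci95), 1e-8)
})

test_that("orthogonal covariates leave the standardized beta unchanged", {
  set.seed(29)
  n <- 64
  x <- rnorm(n)
  z_raw <- rnorm(n)
  z <- residuals(lm(z_raw ~ x))            # constructed orthogonal to x
  y <- 0.5 * x + 0.3 * z + rnorm(n, 0, 0.4)
  df <- data.frame(y = y, x = x, z = z)
  uni <- regress_standardized(df, "y", "x")
  multi <- regress_standardized(df, "y", "x", "z")
  expect_equal(multi$beta_std, uni$beta_std, tolerance = 1e-10)
})

test_that("collinear designs and missing rows are handled explicitly", {
  df <- data.frame(y = rnorm(10), x = rnorm(10))
  df$x2 <- 2 * df$x
  expect_error(regress_standardized(df, "y", "x", "x2"), "collinear|aliased")
  df$z <- rnorm(10); df$z[1] <- NA
  res <- regress_standardized(df, "y", "x", "z")
  expect_equal(res$n, 9)
  expect_equal(res$n_dropped, 1)
  expect_error(regress_standardized(df, "y", "nope"), "missing column")
})

toy_cohort <- function(n_per = 12, seed = 5) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", 1:(2 * n_per)),
    group = rep(c("control", "patient"), each = n_per),
    age = runif(2 * n_per, 55, 85),
    sex = sample(c("male", "female"), 2 * n_per, replace = TRUE),
    vegfa = c(abs(rnorm(n_per, 14, 8)), abs(rnorm(n_per, 25, 12))),
    wmh_rel_volume = c(abs(rnorm(n_per, 3.5e-3, 1e-3)),
                       abs(rnorm(n_per, 16e-3, 4e-3))),
    ki_nawm = abs(rnorm(2 * n_per, 1.0, 0.3)),
    vl_nawm = c(rnorm(n_per, 0.27, 0.05), rnorm(n_per, 0.37, 0.05)),
    ki_wmh = abs(rnorm(2 * n_per, 0.85, 0.3)),
    vl_wmh = c(rnorm(n_per, 0.32, 0.05), rnorm(n_per, 0.46, 0.05)),
    stringsAsFactors = FALSE
  )
}

test_that("group report computes hand-checkable means and sane betas", {
  co <- toy_cohort()
  rep1 <- run_table1(co)
  m <- rep1$means
  hand <- mean(co$vl_nawm[co$group == "patient"])
  expect_equal(m$mean[m$measure == "vl_nawm" & m$group == "patient"], hand)
  hand_sem <- sd(co$vl_nawm[co$group == "patient"]) /
    sqrt(sum(co$group == "patient"))
  expect_equal(m$sem[m$measure == "vl_nawm" & m$group == "patient"], hand_sem)

  a <- rep1$associations
  expect_setequal(unique(a$analysis), c("univariable", "multivariable"))
  expect_gt(a$beta[a$measure == "vl_nawm" & a$analysis == "univariable"], 0)

  # equal distributions across groups: beta 0 with CI containing 0
  co2 <- co
  co2$vl_nawm <- rep(co$vl_nawm[co$group == "control"], 2)
  a2 <- run_table1(co2)$associations
  b <- a2[a2$measure == "vl_nawm" & a2$analysis == "univariable", ]
  expect_equal(b$beta, 0, tolerance = 1e-10)
  expect_true(b$ci_lo < 0 && b$ci_hi > 0)

  expect_error(run_table1(co[co$group == "patient", ]), "both groups")
})

test_that("VEGFA report removes outliers first and is deterministic", {
  co <- toy_cohort()
  co$vegfa[co$group == "patient"][1] <- 500   # an obvious upper outlier
  rep2 <- run_table2(co, "patient")
  expect_equal(rep2$n_outliers, 1)
  expect_true(all(rep2$associations$n == sum(co$group == "patient") - 1))
  rep2b <- run_table2(co, "patient")
  expect_identical(rep2, rep2b)
})

test_that("VEGFA permutation null keeps false positives near the nominal rate", {
  cfg <- simulation_config(n_patients = 47, n_controls = 0, vegfa_ki_slope = 0)
  co <- simulate_cohort_table(cfg)
  set.seed(303)
  p <- replicate(200, {
    co$vegfa <- sample(co$vegfa)
    regress_standardized(co, "ki_nawm", "vegfa")$p_value
  })
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.05)
})

test_that("the configured VEGFA-K_i coupling is detected at n = 200", {
  cfg <- simulation_config(n_patients = 200, n_controls = 0)
  co <- simulate_cohort_table(cfg)
  res <- regress_standardized(co, "ki_nawm", "vegfa", c("age", "sex"))
  expect_gt(res$beta_std, 0)
  expect_lt(res$p_value, 0.05)
})
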