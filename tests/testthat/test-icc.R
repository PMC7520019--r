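test_that("identical reader columns give ICC of exactly 1", {
  set.seed(61)
  x <- rnorm(10, 7.5, 4)
  fit <- icc_a1(cbind(x, x))
  expect_equal(fit$estimate, 1, tolerance = 1e-12)
  expect_lte(fit$ci_lower, fit$estimate)
  expect_gte(fit$ci_upper, fit$estimate)
})

test_that("a small matrix matches the brute-force ANOVA oracle and an external fit", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), ncol = 2)
  fit <- icc_a1(m)
  expect_equal(fit$estimate, icc_bruteforce_oracle(m), tolerance = 1e-12)
  expect_equal(fit$estimate, 8 / 9, tolerance = 1e-12)  # MSE = 0 here

  # frozen from an independent implementation (pingouin ICC2, absolute
  # agreement, single measures) on the same 20 x 3 table
  set.seed(42)
  m2 <- matrix(rnorm(20 * 3, 10, 3), 20, 3)
  fit2 <- icc_a1(m2)
  expect_equal(fit2$estimate, 0.184881473241, tolerance = 1e-10)
  expect_lt(abs(fit2$ci_lower - (-0.07)), 0.005)
  expect_lt(abs(fit2$ci_upper - 0.49), 0.005)
})

test_that("the formula equals the brute-force oracle on random tables", {
  set.seed(62)
  for (i in 1:100) {
    n <- sample(3:12, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 8, 3), n, k) +
      outer(rep(1, n), rnorm(k, 0, 0.5))     # reader shifts
    est <- suppressWarnings(icc_a1(m)$estimate)
    expect_equal(est, icc_bruteforce_oracle(m), tolerance = 1e-10)
  }
})

test_that("mean squares agree with a two-way aov decomposition", {
  set.seed(63)
  m <- matrix(rnorm(12 * 2, 7, 3), 12, 2)
  fit <- suppressWarnings(icc_a1(m))
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(12), 2)),
                   reader = factor(rep(1:2, each = 12)))
  tab <- summary(stats::aov(y ~ subject + reader, data = df))[[1]]
  expect_equal(fit$ms_rows, tab["subject", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$ms_cols, tab["reader", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(fit$ms_error, tab["Residuals", "Mean Sq"], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("a large simulated study recovers the variance-ratio closed form", {
  set.seed(64)
  n <- 2000
  s <- rnorm(n, 7.5, 2)                      # subject effect, SD 2
  m <- cbind(s + rnorm(n), s + rnorm(n))     # error SD 1, no reader shift
  expect_equal(icc_a1(m)$estimate, 0.8, tolerance = 0.03)  # 4 / (4 + 1)
})

test_that("the ICC is exactly invariant to subject permutation", {
  set.seed(65)
  m <- matrix(rnorm(30, 7, 3), 15, 2)
  fit <- suppressWarnings(icc_a1(m))
  perm <- suppressWarnings(icc_a1(m[sample(15), ]))
  expect_identical(fit$estimate, perm$estimate)
  expect_identical(fit$ci_lower, perm$ci_lower)
})

test_that("reader shifts lower absolute agreement but not consistency", {
  set.seed(66)
  for (i in 1:20) {
    s <- rnorm(12, 7, 3)                     # real subject effect
    m <- cbind(s + rnorm(12, 0, 0.5), s + rnorm(12, 0, 0.5))
    m <- sweep(m, 2, colMeans(m))            # equal column means baseline
    shift <- m; shift[, 2] <- shift[, 2] + runif(1, 0.5, 3)
    expect_lte(suppressWarnings(icc_a1(shift)$estimate),
               suppressWarnings(icc_a1(m)$estimate) + 1e-12)
    expect_equal(icc_consistency_oracle(shift), icc_consistency_oracle(m),
                 tolerance = 1e-10)
  }
})

test_that("degenerate ratings are flagged instead of silently scored", {
  expect_error(icc_a1(matrix(3, 5, 2)), "zero total variance")
  # a table dominated by error variance can go negative, with a warning
  anti <- cbind(1:6, 6:1)
  expect_warning(fit <- icc_a1(anti), "negative ICC")
  expect_lt(fit$estimate, 0)
})

test_that("descriptive summaries follow the sample conventions", {
  one <- summarize_slopes(7.4)
  expect_equal(one$mean, 7.4)
  expect_true(is.na(one$sd))
  expect_equal(c(one$min, one$max), c(7.4, 7.4))
  expect_equal(summarize_slopes(c(0, 0, 0))$sd, 0)
  expect_error(summarize_slopes(numeric(0)), "no values")

  set.seed(68)
  x <- rnorm(1000, 7.4, 4.72)
  sm <- summarize_slopes(x)
  expect_lt(abs(sm$mean - 7.4), 0.45)        # 3-sigma sampling band
  expect_lt(abs(sm$sd - 4.72), 0.35)
})

test_that("reader_study produces one ICC per region plus descriptives", {
  set.seed(69)
  n <- 54
  regions <- c("medial_plateau", "medial_rim", "lateral_plateau",
               "lateral_rim", "radiograph")
  long <- do.call(rbind, lapply(regions, function(rg) {
    s <- rnorm(n, 7.5, 4)
    do.call(rbind, lapply(1:2, function(r) {
      data.frame(subject = 1:n, reader = paste0("reader", r), region = rg,
                 slope_deg = s + rnorm(n, 0, 1))
    }))
  }))
  st <- reader_study(long)
  expect_equal(nrow(st$icc), 5L)
  expect_setequal(st$icc$region, regions)
  expect_true(all(st$icc$n == 54 & st$icc$k == 2))
  expect_equal(nrow(st$descriptives), 10L)
  expect_true(all(st$icc$ci_lower <= st$icc$estimate &
                    st$icc$estimate <= st$icc$ci_upper))
  # duplicate-reader input: all ICCs exactly 1
  dup <- long
  dup$slope_deg <- ave(dup$slope_deg, dup$subject, dup$region)
  expect_true(all(abs(reader_study(dup)$icc$estimate - 1) < 1e-12))
})

test_that("single-reader regions are skipped with a warning", {
  set.seed(71)
  s <- rnorm(5, 7, 3)
  long <- data.frame(subject = rep(1:5, 2),
                     reader = rep(c("r1", "r2"), each = 5),
                     region = "medial_plateau",
                     slope_deg = s[rep(1:5, 2)] + rnorm(10, 0, 0.5))
  solo <- data.frame(subject = 1:5, reader = "r1", region = "radiograph",
                     slope_deg = rnorm(5, 6, 2))
  expect_warning(st <- reader_study(rbind(long, solo)), "radiograph")
  expect_equal(st$icc$region, "medial_plateau")
})

test_that("tidiers expose the fit as tibbles", {
  set.seed(70)
  fit <- suppressWarnings(icc_a1(matrix(rnorm(20, 7, 3), 10, 2)))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("estimate", "ci_lower", "ci_upper", "conf_level"))
  gl <- glance(fit)
  expect_true(all(c("ms_rows", "ms_cols", "ms_error") %in% names(gl)))
})
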