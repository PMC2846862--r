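make_calls <- function(b, n, c, population = NULL, no_call = FALSE) {
  df <- data.frame(sample_id = sprintf("s%02d", seq_along(b)),
                   b = b, n = n, c = c,
                   class = paste0(b + c, ":", n),
                   no_call = rep_len(no_call, length(b)))
  if (!is.null(population)) df$population <- population
  df
}

test_that("population summaries report means, classes and gene-pool shares", {
  # 12 of 24 samples in class 3:2 -> 50%
  df <- make_calls(b = c(rep(1, 12), rep(2, 12)),
                   n = 2, c = c(rep(2, 12), rep(2, 12)),
                   population = "Mex")
  s <- summarize_populations(df)[["Mex"]]
  expect_equal(unname(s$class_freq["3:2"]), 0.5)
  # three identical calls
  s3 <- summarize_populations(make_calls(b = c(1, 1, 1), n = 2, c = 3,
                                         population = "X"))[["X"]]
  expect_equal(unname(s3$mean["b"]), 1.0)
  expect_equal(unname(s3$sd["b"]), 0.0)
  expect_equal(sum(s3$class_freq), 1.0)
  # gene-pool shares = normalised mean copy numbers (Mexican-like means)
  mex <- make_calls(b = c(rep(2, 6), rep(1, 4)),
                    n = c(rep(2, 9), 3),
                    c = rep(1, 10), population = "Mex")
  s <- summarize_populations(mex)[["Mex"]]
  expect_equal(unname(s$mean), c(1.6, 2.1, 1.0))
  expect_equal(unname(s$gene_pool_share), c(16, 21, 10) / 47,
               tolerance = 1e-12)
  expect_equal(sum(s$gene_pool_share), 1, tolerance = 1e-9)
})

test_that("no-call samples are excluded and empty populations explicit", {
  df <- make_calls(b = c(1, 1), n = 2, c = c(2, 2),
                   population = c("A", "B"), no_call = c(FALSE, TRUE))
  s <- summarize_populations(df)
  expect_equal(s[["A"]]$n, 1L)
  expect_equal(s[["B"]]$n, 0L)
  expect_equal(s[["B"]]$n_no_call, 1L)
  expect_true(all(is.na(s[["B"]]$mean)))
})

test_that("summary-statistic t test agrees with stats::t.test on raw data", {
  set.seed(202)
  for (rep in 1:5) {
    x <- rnorm(13, 2, 1)
    y <- rnorm(9, 1.4, 1.6)
    for (m in c("student", "welch")) {
      mine <- two_sample_t(c(mean = mean(x), sd = sd(x), n = length(x)),
                           c(mean = mean(y), sd = sd(y), n = length(y)),
                           method = m)
      ref <- t.test(x, y, var.equal = (m == "student"))
      expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(mine$df, unname(ref$parameter), tolerance = 1e-12)
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
      # raw-vector interface takes the same route
      raw <- two_sample_t(x, y, method = m)
      expect_equal(raw$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("published summary statistics reproduce the NCF1C contrast", {
  # AA (2.3 +/- 0.6, n 32) vs Mexican (1.0 +/- 0.4, n 24), pooled Student
  tt <- two_sample_t(c(mean = 2.3, sd = 0.6, n = 32),
                     c(mean = 1.0, sd = 0.4, n = 24))
  expect_equal(tt$df, 54)
  expect_equal(tt$t, 9.1828, tolerance = 1e-4)
  expect_lt(tt$p, 1e-10)
  # oracle: the same summaries realised as raw data through stats::t.test
  ref <- t.test(raw_with_stats(2.3, 0.6, 32), raw_with_stats(1.0, 0.4, 24),
                var.equal = TRUE)
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-9)
  # Caucasian vs AA NCF1B lands in the published 0.03-0.05 band
  tt2 <- two_sample_t(c(mean = 1.8, sd = 0.7, n = 30),
                      c(mean = 1.4, sd = 0.8, n = 32))
  expect_gt(tt2$p, 0.03)
  expect_lt(tt2$p, 0.05)
})

test_that("t-test symmetries and degenerate cases hold", {
  g1 <- c(mean = 2.0, sd = 0.5, n = 10)
  g2 <- c(mean = 1.5, sd = 0.8, n = 14)
  a <- two_sample_t(g1, g2)
  b <- two_sample_t(g2, g1)
  expect_equal(a$p, b$p)
  expect_equal(a$t, -b$t)
  # Student and Welch agree when n and SD match
  g3 <- c(mean = 1.0, sd = 0.5, n = 10)
  g4 <- c(mean = 1.4, sd = 0.5, n = 10)
  s <- two_sample_t(g3, g4, method = "student")
  w <- two_sample_t(g3, g4, method = "welch")
  expect_equal(s$t, w$t)
  expect_equal(s$df, w$df)
  expect_equal(s$p, w$p)
  # identical groups: t = 0, p = 1
  id <- two_sample_t(g1, g1)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)
  # zero variance in both groups
  z_eq <- two_sample_t(c(mean = 1, sd = 0, n = 5), c(mean = 1, sd = 0, n = 5))
  expect_equal(z_eq$p, 1)
  z_ne <- two_sample_t(c(mean = 2, sd = 0, n = 5), c(mean = 1, sd = 0, n = 5))
  expect_equal(z_ne$p, 0)
  expect_true(z_ne$degenerate)
  expect_error(two_sample_t(c(mean = 1, sd = 0.1, n = 1), g1), "n >= 2")
})

test_that("pairwise population comparison covers all pairs and paralogs", {
  set.seed(7)
  df <- make_calls(b = sample(0:3, 30, TRUE), n = 2,
                   c = sample(0:3, 30, TRUE),
                   population = rep(c("AA", "Cau", "Mex"), each = 10))
  tab <- compare_populations(df)
  expect_equal(nrow(tab), 9L) # 3 pairs x 3 paralogs
  bon <- compare_populations(df, correction = "bonferroni")
  expect_equal(bon$p, pmin(1, tab$p * 9))
  # identical populations give p = 1 throughout
  same2 <- rbind(make_calls(b = c(1, 2, 1, 2), n = 2, c = c(0, 1, 1, 0),
                            population = "P1"),
                 make_calls(b = c(1, 2, 1, 2), n = 2, c = c(0, 1, 1, 0),
                            population = "P2"))
  same2$sample_id <- sprintf("s%02d", seq_len(nrow(same2)))
  expect_true(all(compare_populations(same2)$p == 1))
})

test_that("type-I error of the pipeline t test is near nominal", {
  # two populations drawn from the same haplotype pool: the NCF1C contrast
  # should reject at alpha = 0.05 about 5% of the time
  pool <- population_preset("Mexican")
  n_rej <- 0L
  n_rep <- 1000L
  for (k in seq_len(n_rep)) {
    s1 <- simulate_population(pool, 24, seed = 50000 + k)
    s2 <- simulate_population(pool, 24, seed = 90000 + k)
    c1 <- ncf1_call(s1$samples)$calls
    c2 <- ncf1_call(s2$samples)$calls
    p <- two_sample_t(c1$c[!c1$no_call], c2$c[!c2$no_call])$p
    if (p < 0.05) n_rej <- n_rej + 1L
  }
  expect_gt(n_rej / n_rep, 0.025)
  expect_lt(n_rej / n_rep, 0.075)
})
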