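test_that("one_sample_t matches the explicit-sum formula", {
  set.seed(1)
  for (i in 1:5) {
    x <- rnorm(10 + i, mean = 0.2)
    res <- one_sample_t(x, mu0 = 0.1)
    n <- length(x)
    m <- sum(x) / n
    s <- sqrt(sum((x - m)^2) / (n - 1))
    t_manual <- (m - 0.1) / (s / sqrt(n))
    expect_equal(res$t, t_manual, tolerance = 1e-12)
    expect_equal(res$df, n - 1)
    expect_equal(res$p, 2 * pt(abs(t_manual), n - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(res$d, (m - 0.1) / s, tolerance = 1e-12)
    expect_equal(sign(res$t), sign(res$d))
  }
  # symmetric sample: t = d = 0, p = 1
  res0 <- one_sample_t(c(-1, 0, 1), mu0 = 0)
  expect_equal(res0$t, 0)
  expect_equal(res0$d, 0)
  expect_equal(res0$p, 1)
  expect_error(one_sample_t(rep(2, 5), mu0 = 1), "zero variance")
  expect_error(one_sample_t(3), "at least 2")
})

make_cells <- function(n, mu, sd_noise = 0.1, seed = 1) {
  # mu: named c(closed.delay, closed.no_delay, open.delay, open.no_delay)
  set.seed(seed)
  grid <- expand.grid(subject_id = seq_len(n),
                      loop = c("closed", "open"),
                      delay = c("delay", "no_delay"),
                      stringsAsFactors = FALSE)
  grid$value <- mu[paste(grid$loop, grid$delay, sep = ".")] +
    rnorm(nrow(grid), 0, sd_noise)
  grid
}

test_that("the 2x2 within-ANOVA agrees with the aov() decomposition", {
  d <- make_cells(14, c(closed.delay = 0.2, closed.no_delay = 0.35,
                        open.delay = 0.05, open.no_delay = 0.1), seed = 3)
  got <- anova_2x2_within(d)
  ref <- summary(stats::aov(value ~ loop * delay +
                              Error(factor(subject_id) / (loop * delay)),
                            data = d))
  ref_f <- c(ref[["Error: factor(subject_id):loop"]][[1]]$`F value`[1],
             ref[["Error: factor(subject_id):delay"]][[1]]$`F value`[1],
             ref[["Error: factor(subject_id):loop:delay"]][[1]]$`F value`[1])
  ref_p <- c(ref[["Error: factor(subject_id):loop"]][[1]]$`Pr(>F)`[1],
             ref[["Error: factor(subject_id):delay"]][[1]]$`Pr(>F)`[1],
             ref[["Error: factor(subject_id):loop:delay"]][[1]]$`Pr(>F)`[1])
  expect_equal(got$F, ref_f, tolerance = 1e-8)
  expect_equal(got$p, ref_p, tolerance = 1e-8)
  expect_equal(got$df_den, rep(13L, 3))
})

test_that("each ANOVA effect equals the squared paired-contrast t", {
  d <- make_cells(20, c(closed.delay = 0.3, closed.no_delay = 0.1,
                        open.delay = 0, open.no_delay = 0.05), seed = 5)
  got <- anova_2x2_within(d)
  wide <- tidyr::pivot_wider(d, names_from = c(loop, delay),
                             values_from = value)
  inter <- (wide$closed_delay - wide$closed_no_delay -
              wide$open_delay + wide$open_no_delay) / 2
  t_inter <- one_sample_t(inter)
  expect_equal(got$F[got$effect == "interaction"], t_inter$t^2,
               tolerance = 1e-10)
  expect_equal(got$partial_eta_sq,
               got$F / (got$F + got$df_den), tolerance = 1e-12)
})

test_that("degenerate and additive cell patterns behave as constructed", {
  # identical cells per subject: no effect anywhere
  flat <- make_cells(8, c(closed.delay = 0, closed.no_delay = 0,
                          open.delay = 0, open.no_delay = 0), sd_noise = 0)
  flat$value <- rep(rnorm(8), 4) # subject offsets only
  got <- anova_2x2_within(flat)
  expect_equal(got$F, rep(0, 3))
  # pure additive main effects, no noise: interaction exactly null
  # (dyadic values keep the per-subject cancellation exact in floating point)
  add <- make_cells(50, c(closed.delay = 0.5, closed.no_delay = 0.75,
                          open.delay = 0.125, open.no_delay = 0.375),
                    sd_noise = 0)
  add$value <- add$value + rep(sample(-64:64, 50, replace = TRUE) / 1024, 4)
  got2 <- anova_2x2_within(add)
  expect_equal(got2$F[got2$effect == "interaction"], 0)
  expect_lt(max(got2$p[got2$effect != "interaction"]), 0.001)
  # incomplete cells are a completeness error
  expect_error(anova_2x2_within(make_cells(5, c(closed.delay = 0,
                                                closed.no_delay = 0,
                                                open.delay = 0,
                                                open.no_delay = 0))[-1, ]),
               "all four cells")
})

test_that("Bonferroni presentation rounds half-up to three decimals", {
  b4 <- bonferroni_alpha(0.05, 4)
  expect_equal(b4$alpha_adjusted, 0.0125)
  expect_equal(b4$alpha_presented, 0.013)
  b3 <- bonferroni_alpha(0.05, 3)
  expect_equal(b3$alpha_presented, 0.017)
  b1 <- bonferroni_alpha(0.05, 1)
  expect_equal(b1$alpha_adjusted, 0.05)
  # exact recovery of the familywise level
  for (m in 1:8) {
    expect_equal(bonferroni_alpha(0.05, m)$alpha_adjusted * m, 0.05)
  }
  expect_error(bonferroni_alpha(0.05, 0), "integer")
})

test_that("noncentral-t power matches base R's oracle and is monotone", {
  # independent route: power.t.test implements the same computation
  for (n in c(10, 30, 80)) {
    ref <- stats::power.t.test(n = n, delta = 0.62, sd = 1,
                               sig.level = 0.05, type = "one.sample",
                               strict = TRUE)$power
    expect_equal(power_one_sample_t(0.62, n), ref, tolerance = 1e-6)
  }
  expect_gt(power_one_sample_t(10, 5), 1 - 1e-6)
  pows <- sapply(3:100, function(n) power_one_sample_t(0.62, n))
  expect_true(all(diff(pows) > 0))
  expect_error(power_one_sample_t(-1, 10), "positive")
})

test_that("minimal sample size satisfies the minimality contract", {
  n <- sample_size_one_sample_t(0.62, 0.05, 0.90)
  expect_gte(power_one_sample_t(0.62, n), 0.90)
  expect_lt(power_one_sample_t(0.62, n - 1), 0.90)
  # large effects need few subjects; scan the oracle directly
  n_big <- sample_size_one_sample_t(2.5, 0.05, 0.90)
  brute <- which(sapply(2:30, function(k)
    power_one_sample_t(2.5, k) >= 0.90))[1] + 1
  expect_equal(n_big, brute)
  expect_error(sample_size_one_sample_t(0, 0.05, 0.9), "positive")
})

test_that("type-I rate of the 2x2 ANOVA is nominal under the null", {
  # null cells, 300 simulated cohorts: rejection of the loop effect at 5%
  set.seed(17)
  rej <- replicate(300, {
    d <- make_cells(12, c(closed.delay = 0, closed.no_delay = 0,
                          open.delay = 0, open.no_delay = 0),
                    sd_noise = 1, seed = sample.int(1e6, 1))
    anova_2x2_within(d)$p[1] < 0.05
  })
  # 99% binomial band around 0.05 for 300 draws
  expect_gt(mean(rej), 0.05 - 2.576 * sqrt(0.05 * 0.95 / 300))
  expect_lt(mean(rej), 0.05 + 2.576 * sqrt(0.05 * 0.95 / 300))
})
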