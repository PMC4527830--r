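dset <- function(x, g = "g") list(genotype = g, lifespans = x)

test_that("RLS summaries report the standard descriptive statistics", {
  s <- summarize_rls(dset(c(30, 30, 30)))
  expect_equal(s$mean_lifespan, 30)
  expect_equal(s$median_lifespan, 30)
  expect_equal(s$max_lifespan, 30)

  s2 <- summarize_rls(dset(c(10, 20, 30, 40)))
  expect_equal(s2$mean_lifespan, 25)
  expect_equal(s2$median_lifespan, 25)
  expect_equal(s2$max_lifespan, 40)

  cv <- s2$survival_curve
  expect_equal(cv$surviving[cv$generations == 0], 1)
  expect_true(all(diff(cv$surviving) <= 0))
  expect_equal(cv$surviving[cv$generations == max(cv$generations)], 0)
  expect_error(summarize_rls(dset(integer(0))), "empty")
})

test_that("flank8 selects the eight points around the median position", {
  expect_equal(flank8_select(dset(8:1)), 1:8)
  expect_equal(flank8_select(dset(sample(1:40))), 17:24)
  expect_equal(flank8_select(dset(rep(5, 12))), rep(5, 8))
  expect_error(flank8_select(dset(1:7)), "at least 8")

  # property: size-8 multiset subset containing the median position
  set.seed(13)
  for (n in c(8, 9, 15, 40, 41)) {
    x <- sample(1:60, n, replace = TRUE)
    f <- flank8_select(dset(x))
    expect_length(f, 8)
    pool <- sort(x)
    for (v in unique(f))
      expect_lte(sum(f == v), sum(pool == v))
    m_pos <- if (n %% 2 == 0) n / 2 else (n + 1) / 2
    expect_true(pool[m_pos] %in% f)
  }
  # alternative nearest-by-value rule is also a size-8 subset
  expect_length(flank8_select(dset(1:40), method = "nearest"), 8)
})

test_that("Mann-Whitney U matches exhaustive enumeration", {
  r <- mann_whitney_u(1:4, 5:8, mode = "exact")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 70)

  same <- mann_whitney_u(c(3, 1, 4, 1, 5), c(3, 1, 4, 1, 5), mode = "exact")
  expect_equal(same$statistic, 25 / 2)  # n1 * n2 / 2
  expect_equal(same$p_value, 1)

  set.seed(17)
  for (i in 1:8) {
    x <- sample(1:6, 5, replace = TRUE)  # replacement forces ties
    y <- sample(1:6, 4, replace = TRUE)
    got <- mann_whitney_u(x, y, mode = "exact")
    want <- enumerate_mw(x, y)
    expect_equal(got$statistic, want$u)
    expect_equal(got$p_value, want$p)
  }
})

test_that("the normal approximation tracks the exact distribution", {
  set.seed(19)
  for (i in 1:10) {
    x <- rnorm(8)
    y <- rnorm(8, mean = runif(1, 0, 1.5))
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "normal_approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
    # tie-free exact mode agrees with the reference implementation
    expect_equal(pe, stats::wilcox.test(x, y, exact = TRUE)$p.value)
    expect_equal(pa, stats::wilcox.test(x, y, exact = FALSE,
                                        correct = TRUE)$p.value)
  }
  # auto mode picks exact at n <= 10 and the approximation above
  expect_equal(mann_whitney_u(1:4, 5:8)$method, "mann_whitney_exact")
  expect_equal(mann_whitney_u(rnorm(11), rnorm(11))$method,
               "mann_whitney_normal")
  expect_error(mann_whitney_u(numeric(0), 1:3), "nonempty")
})

test_that("cessation day follows the two-empty-days rule", {
  expect_equal(repro_cessation_day(c(5, 8, 6, 0, 0)), 3L)
  expect_equal(repro_cessation_day(c(5, 0, 0, 2, 0, 0)), 4L)
  expect_identical(repro_cessation_day(c(5, 8, 6, 0)), NA_integer_)
  expect_identical(repro_cessation_day(c(0, 0, 0)), NA_integer_)
  expect_equal(repro_cessation_day(c(1, 0, 0)), 1L)
})

test_that("reproduction curves follow cessation days with sterile exclusion", {
  all4 <- repro_set_from(rep(4, 10))
  c1 <- build_repro_curve(all4)
  expect_equal(c1$curve$fraction_reproducing, c(1, 1, 1, 1))

  half <- repro_set_from(c(rep(2, 5), rep(6, 5)))
  c2 <- build_repro_curve(half)
  expect_equal(c2$curve$fraction_reproducing[3:6], rep(0.5, 4))

  with_sterile <- repro_set_from(c(rep(2, 5), rep(6, 5), 1, 1),
                                 sterile = c(rep(FALSE, 10), TRUE, TRUE))
  c3 <- build_repro_curve(with_sterile)
  expect_equal(c3$n_sterile_excluded, 2)
  expect_equal(c3$n_included, 10)
  expect_equal(c3$curve, c2$curve)

  expect_true(all(diff(c3$curve$fraction_reproducing) <= 0))
  expect_error(build_repro_curve(repro_set_from(c(1, 2),
                                                sterile = TRUE)),
               "no worms")
})

test_that("matricide worms are censored (or dropped) without bias direction", {
  mix <- repro_set_from(c(2, 2, 3, 5, 6, 6),
                        outcome = c("ceased", "ceased", "matricide",
                                    "ceased", "ceased", "alive_at_end"))
  cens <- build_repro_curve(mix, matricide = "censor")
  drop <- build_repro_curve(mix, matricide = "drop")
  expect_equal(cens$n_matricide, 1)
  expect_equal(drop$n_included, 5)
  expect_true(all(diff(cens$curve$fraction_reproducing) <= 0))
  # censoring keeps the matricide worm at risk through its death day
  expect_gte(cens$curve$fraction_reproducing[3],
             drop$curve$fraction_reproducing[3])

  # product-limit handling agrees with the reference survival fit:
  # fraction reproducing on day d equals S(d - 1)
  if (requireNamespace("survival", quietly = TRUE)) {
    fit <- survival::survfit(
      survival::Surv(mix$last_progeny_day, mix$outcome == "ceased") ~ 1)
    S <- stats::stepfun(fit$time, c(1, fit$surv))
    expect_equal(cens$curve$fraction_reproducing,
                 S(cens$curve$day - 1), tolerance = 1e-12)
  }
})

test_that("log-rank matches the hand-worked table and survdiff", {
  a <- repro_set_from(c(2, 2, 3), genotype = "a")
  b <- repro_set_from(c(5, 6, 6), genotype = "b")
  r <- logrank_test(a, b)
  # frozen hand computation: O_B = 3, E_B = 1.25, V = 0.5875
  expect_equal(r$statistic, (3 - 1.25)^2 / 0.5875, tolerance = 1e-12)
  expect_equal(r$statistic, 5.212766, tolerance = 1e-6)
  expect_equal(r$p_value, pchisq(5.212766, 1, lower.tail = FALSE),
               tolerance = 1e-6)

  same <- logrank_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # invariance under strictly monotone time transforms
  a2 <- repro_set_from(2 * c(2, 2, 3), genotype = "a")
  b2 <- repro_set_from(2 * c(5, 6, 6), genotype = "b")
  expect_equal(logrank_test(a2, b2)$statistic, r$statistic)

  # independent oracle on a censored mixture
  set.seed(23)
  ga <- repro_set_from(sample(2:8, 12, TRUE),
                       outcome = sample(c("ceased", "matricide"), 12, TRUE,
                                        c(0.7, 0.3)))
  gb <- repro_set_from(sample(4:10, 12, TRUE),
                       outcome = sample(c("ceased", "alive_at_end"), 12,
                                        TRUE, c(0.8, 0.2)))
  got <- logrank_test(ga, gb)
  time <- c(ga$last_progeny_day, gb$last_progeny_day)
  event <- c(ga$outcome, gb$outcome) == "ceased"
  grp <- rep(0:1, each = 12)
  expect_equal(got$statistic, oracle_logrank(time, event, grp))
  if (requireNamespace("survival", quietly = TRUE)) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    expect_equal(got$statistic, sd$chisq, tolerance = 1e-9)
  }

  none <- repro_set_from(c(3, 4), outcome = "alive_at_end")
  expect_error(logrank_test(none, none), "no cessation events")
})

test_that("percent change matches the reporting convention", {
  s10 <- summarize_rls(dset(rep(10, 5)))
  s14 <- summarize_rls(dset(rep(14, 5)))
  expect_equal(percent_change(s10, s14, "median"), 40)
  expect_equal(percent_change(s10, s10, "mean"), 0)
  a <- summarize_rls(dset(rep(17.5, 4)))
  b <- summarize_rls(dset(rep(27.5, 4)))
  expect_equal(percent_change(a, b, "mean"), 100 * 10 / 17.5,
               tolerance = 1e-9)
  expect_error(percent_change(summarize_rls(dset(0)), s10), "positive")
})
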