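test_that("clone envelope reproduces the printed doubling bounds", {
  expect_identical(clone_envelope(30, foa_on = FALSE), 2^30)  # 1073741824
  expect_identical(clone_envelope(30, foa_on = TRUE, loss_fraction = 0.7),
                   2^21)                                      # 2097152
  expect_identical(clone_envelope(1, foa_on = FALSE), 2)
  expect_error(clone_envelope(0, FALSE), "positive")
  expect_error(clone_envelope(30, TRUE, 0), "loss_fraction")
})

test_that("the smallest lineage follows the verbal division rules", {
  lib <- toy_library(L = 1, lo = 1, hi = 1)
  st <- new_pool(lib, foa_on = TRUE, mode = "expected", clock = "reset",
                 init_per_strain = 1)
  st <- step_generation(st)
  # one doomed (unsilenced age-1) mother + one silenced age-0 daughter
  expect_equal(unname(pool_counts(st)[1]), 2)
  expect_equal(st$groups[[1]]$doomed[1], 1)
  expect_equal(st$groups[[1]]$V[1, 1], 1)
  st <- step_generation(st)
  # the doomed mother is removed; the daughter has divided
  expect_equal(unname(pool_counts(st)[1]), 2)
})

test_that("deterministic degenerate limit equals the clone envelope", {
  for (L in c(1, 2, 5, 12, 30)) {
    lib <- toy_library(L, lo = 1, hi = 1)
    for (foa in c(FALSE, TRUE)) {
      st <- new_pool(lib, foa_on = foa, mode = "expected", clock = "reset",
                     init_per_strain = 1)
      for (i in seq_len(L)) st <- step_generation(st)
      expect_equal(unname(pool_counts(st)[1]),
                   clone_envelope(L, foa, loss_fraction = 1),
                   info = sprintf("L=%d foa=%s", L, foa))
    }
  }
  # earliest-loss window: a 30-generation strain halted at 70 percent
  lib <- toy_library(30, lo = 0.7, hi = 0.7)
  st <- new_pool(lib, TRUE, "expected", "reset", init_per_strain = 1)
  for (i in 1:21) st <- step_generation(st)
  expect_equal(unname(pool_counts(st)[1]), 2^21)
})

test_that("expected counts match a brute-force per-cell enumeration", {
  # deterministic parameters beyond the degenerate limit: loss strictly
  # inside the lifespan, several steps past the halt point
  cases <- list(c(L = 4, g = 3), c(L = 5, g = 4), c(L = 6, g = 5))
  for (cs in cases) {
    f <- cs[["g"]] / cs[["L"]]
    lib <- toy_library(cs[["L"]], lo = f, hi = f)
    for (foa in c(TRUE, FALSE)) {
      st <- new_pool(lib, foa_on = foa, mode = "expected", clock = "reset",
                     init_per_strain = 1)
      for (s in seq_len(cs[["L"]] + 4)) {
        st <- step_generation(st)
        expect_equal(unname(pool_counts(st)[1]),
                     agent_pool_counts(cs[["L"]], cs[["g"]], foa, s),
                     info = sprintf("L=%d g=%d foa=%s step=%d",
                                    cs[["L"]], cs[["g"]], foa, s))
      }
    }
  }
})

test_that("reseeding rescales exactly and multinomially on average", {
  lib <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 3)
  st <- new_pool(lib, TRUE, "expected", "reset", init_per_strain = 1000)
  for (i in 1:6) st <- step_generation(st)
  before <- pool_counts(st)
  after <- pool_counts(reseed(st, 1e6))
  expect_equal(sum(after), 1e6)
  expect_equal(after / sum(after), before / sum(before), tolerance = 1e-12)
  # target equal to current total: identity
  same <- pool_counts(reseed(st, sum(before)))
  expect_equal(same, before, tolerance = 1e-12)

  # multinomial reseed is unbiased for per-strain fractions
  stm <- new_pool(toy_library(30, lo = 0.7, hi = 1, n = 2), TRUE,
                  "multinomial", "inherit", init_per_strain = 200,
                  max_generations = 40)
  for (i in 1:5) stm <- step_generation(stm)
  frac0 <- pool_counts(stm) / sum(pool_counts(stm))
  set.seed(99)
  reps <- replicate(400, {
    cc <- pool_counts(reseed(stm, 500, mode = "multinomial"))
    cc[1] / sum(cc)
  })
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - frac0[1]), 3 * se + 1e-12)
})

test_that("neutral competition leaves relative abundances at their start", {
  lib <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 2)
  sch <- make_schedule(sampling_days = c(0, 6, 16))
  tr <- run_screen(lib, sch, foa_on = FALSE, mode = "expected",
                   clock = "reset")
  for (d in unique(tr$day)) {
    fr <- tr$rel_abundance[tr$day == d]
    expect_equal(fr, rep(0.5, 2), tolerance = 1e-12,
                 info = paste("day", d))
    expect_equal(sum(fr), 1, tolerance = 1e-9)
  }
  # identical strains give identical trajectories under selection too
  trs <- run_screen(lib, sch, foa_on = TRUE, mode = "expected",
                    clock = "reset")
  expect_equal(trs$rel_abundance[trs$barcode_id == "s01"],
               trs$rel_abundance[trs$barcode_id == "s02"],
               tolerance = 1e-12)
})

test_that("long-lived strains enrich monotonically under counter-selection", {
  lib <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 2)
  lib$mean_lifespan[2] <- 42  # +40 percent
  sch <- make_schedule(sampling_days = c(6, 16))
  for (ck in c("reset", "inherit")) {
    tr <- run_screen(lib, sch, foa_on = TRUE, mode = "expected", clock = ck)
    f6 <- tr$rel_abundance[tr$day == 6 & tr$barcode_id == "s02"]
    f16 <- tr$rel_abundance[tr$day == 16 & tr$barcode_id == "s02"]
    expect_gt(f6, 0.5)
    expect_gt(f16, f6)
  }
})

test_that("stochastic mode converges to the expected mode", {
  lib <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 2)
  lib$mean_lifespan[2] <- 42
  sch <- make_schedule(sampling_days = 16)
  exp_f <- run_screen(lib, sch, foa_on = TRUE, mode = "expected",
                      clock = "inherit")
  exp16 <- exp_f$rel_abundance[exp_f$barcode_id == "s02"]
  for (target in c(1e2, 1e5)) {
    schs <- make_schedule(reseed_target_size = target, sampling_days = 16)
    sim <- vapply(1:12, function(s) {
      # a 100-cell bottleneck can legitimately go extinct under selection;
      # convergence is asserted on the surviving replicates
      tryCatch(
        {
          tr <- run_screen(lib, schs, foa_on = TRUE, mode = "multinomial",
                           seed = s, clock = "inherit")
          tr$rel_abundance[tr$barcode_id == "s02"]
        },
        error = function(e) NA_real_)
    }, 1)
    err <- abs(mean(sim, na.rm = TRUE) - exp16)
    if (target == 1e2) err_small <- err else err_large <- err
    if (target == 1e5) expect_false(anyNA(sim))
  }
  expect_lt(err_large, err_small + 0.02)
  expect_lt(err_large, 0.02)
})

test_that("defective strains deplete on both reporters, age-dependent only late", {
  # clone-survival factor: cells present relative to unselected doubling
  lib <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 2)
  lib$silencing_defect[2] <- TRUE
  surv <- function(reporter, t) {
    st <- new_pool(lib, foa_on = TRUE, mode = "expected", clock = "inherit",
                   reporter = reporter, init_per_strain = 1,
                   max_generations = 48)
    for (i in seq_len(t)) st <- step_generation(st)
    unname(pool_counts(st) / 2^t)
  }
  q6 <- surv("query", 18); q16 <- surv("query", 48)  # 3 generations per day
  c6 <- surv("control", 18); c16 <- surv("control", 48)
  expect_lt(q6[2], 0.05)   # defective: selected away on the query by day 6
  expect_lt(c6[2], 0.05)   # and on the control library equally
  expect_gt(q6[1], 0.5)    # age-dependent strain largely intact at day 6
  expect_lt(q16[1], 0.1)   # but selected away by day 16 on the query
  expect_equal(c16[1], 1)  # and untouched on the control at any horizon
})

test_that("run_screen is deterministic given mode and seed, errs on extinction", {
  lib <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 2)
  sch <- make_schedule(reseed_target_size = 1e3, sampling_days = c(6, 16))
  a <- run_screen(lib, sch, TRUE, "multinomial", seed = 5, clock = "inherit")
  b <- run_screen(lib, sch, TRUE, "multinomial", seed = 5, clock = "inherit")
  expect_identical(a, b)

  one <- toy_library(30, cv = 0.35, lo = 0.7, hi = 1, n = 2)[1, ]
  class(one) <- c("strain_library", "data.frame")
  tr <- run_screen(one, sch, FALSE, "expected")
  expect_true(all(tr$rel_abundance == 1))

  short <- toy_library(2, lo = 1, hi = 1, n = 2)
  expect_error(
    run_screen(short, make_schedule(generations_per_day = 10), TRUE,
               clock = "inherit"),
    "extinct.*day 1")
})
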