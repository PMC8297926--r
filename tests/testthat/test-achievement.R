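test_that("proportion and efficiency scores match hand arithmetic", {
  expect_equal(proportion_correct(0, 40), 0)
  expect_equal(proportion_correct(40, 40), 1)
  expect_equal(proportion_correct(27, 40), 0.675)
  expect_error(proportion_correct(1, 0), class = "mrsma_validation_error")
  expect_error(proportion_correct(41, 40), class = "mrsma_validation_error")

  expect_equal(tempo_efficiency(33, 40, 300), 33 / 40)  # divisor 1 at full time
  expect_equal(tempo_efficiency(40, 40, 150), 2)
  expect_equal(tempo_efficiency(20, 40, 600), 0.25)
  expect_error(tempo_efficiency(20, 40, 0), class = "mrsma_validation_error")
  expect_error(tempo_efficiency(20, 40, -5), class = "mrsma_validation_error")
})

test_that("efficiency is monotone in time and correct count", {
  times <- seq(60, 300, by = 30)
  eff <- tempo_efficiency(30, 40, times)
  expect_true(all(diff(eff) < 0))
  eff2 <- tempo_efficiency(10:40, 40, 200)
  expect_true(all(diff(eff2) > 0))
})

test_that("composite equals the hand-computed z-mean on a 10-row fixture", {
  set.seed(7)
  cog <- data.frame(
    id = sprintf("A%02d", 1:10), timepoint = 1,
    numops_correct = sample(20:40, 10), numops_attempted = 40,
    reasoning_correct = sample(25:50, 10), reasoning_attempted = 50,
    tempo_correct = sample(30:75, 10), tempo_attempted = 78,
    tempo_time_s = runif(10, 120, 300)
  )
  got <- composite_ma(cog)
  # independent arithmetic: explicit (x - mean) / sd per component
  z <- function(x) (x - mean(x)) / sd(x)
  p1 <- cog$numops_correct / 40
  p2 <- cog$reasoning_correct / 50
  p3 <- (cog$tempo_correct / 78) / (cog$tempo_time_s / 300)
  expect_equal(got$ma_composite, (z(p1) + z(p2) + z(p3)) / 3, tolerance = 1e-12)
  expect_true(all(abs(colMeans(got[c("z_numops", "z_reasoning",
                                     "z_tempo_efficiency")])) < 1e-12))
  expect_equal(unname(apply(got[3:5], 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("symmetric scores give opposite composites; degenerate input errors", {
  cog <- data.frame(
    id = c("a", "b"), timepoint = 1,
    numops_correct = c(10, 30), numops_attempted = 40,
    reasoning_correct = c(20, 40), reasoning_attempted = 50,
    tempo_correct = c(20, 60), tempo_attempted = 80,
    tempo_time_s = c(200, 200)
  )
  got <- composite_ma(cog)
  expect_equal(got$ma_composite[1], -got$ma_composite[2])
  expect_equal(mean(got$ma_composite), 0, tolerance = 1e-12)

  cog$numops_correct <- 20                 # a constant component
  expect_error(composite_ma(cog), class = "mrsma_degenerate_error")
  expect_error(composite_ma(cog), "numerical operations")
})

test_that("composite is invariant to affine rescaling and row permutation", {
  set.seed(11)
  cog <- data.frame(
    id = sprintf("B%02d", 1:12), timepoint = 1,
    numops_correct = sample(10:40, 12), numops_attempted = 40,
    reasoning_correct = sample(20:50, 12), reasoning_attempted = 50,
    tempo_correct = sample(30:75, 12), tempo_attempted = 80,
    tempo_time_s = runif(12, 100, 290)
  )
  base <- composite_ma(cog)
  # doubling both count and total leaves the proportion, hence z, unchanged
  cog2 <- cog
  cog2$numops_correct <- cog$numops_correct * 2
  cog2$numops_attempted <- 80
  expect_equal(composite_ma(cog2)$ma_composite, base$ma_composite, tolerance = 1e-12)
  perm <- sample(12)
  got <- composite_ma(cog[perm, ])
  expect_equal(got$ma_composite[order(got$id)],
               base$ma_composite[order(base$id)], tolerance = 1e-12)
})

test_that("missing components follow the requested policy", {
  set.seed(3)
  cog <- data.frame(
    id = sprintf("C%02d", 1:8), timepoint = 1,
    numops_correct = sample(10:40, 8), numops_attempted = 40,
    reasoning_correct = sample(20:50, 8), reasoning_attempted = 50,
    tempo_correct = sample(30:75, 8), tempo_attempted = 80,
    tempo_time_s = runif(8, 100, 290)
  )
  cog$tempo_time_s[1] <- NA
  avail <- composite_ma(cog)
  expect_equal(avail$n_components[1], 2)
  expect_false(is.na(avail$ma_composite[1]))
  strict <- composite_ma(cog, na_policy = "complete")
  expect_true(is.na(strict$ma_composite[1]))
})

test_that("matrix-reasoning relations behave at the edges and in the cohort", {
  set.seed(21)
  age <- runif(200, 80, 280)
  x <- rnorm(200)
  expect_equal(matrix_relations(x, x, age)$spearman_r, 1)
  # age-driven association vanishes once age is partialled out
  ma_lin <- 2 * age + 1 + rnorm(200, 0, 0.5)
  mx_lin <- -age + rnorm(200, 0, 0.5)
  rel <- matrix_relations(ma_lin, mx_lin, age)
  expect_lt(abs(rel$spearman_r), 1)        # raw correlation is strong/negative
  expect_lt(abs(rel$partial_r), 0.2)
  expect_error(matrix_relations(rep(1, 200), x, age),
               class = "mrsma_degenerate_error")
  expect_error(matrix_relations(x[1:3], x[1:3], age[1:3]),
               class = "mrsma_validation_error")

  mr <- matrix_relations(c(x[1:30], NA), c(rnorm(30), 1), c(age[1:30], 100))
  expect_equal(mr$n, 30)
  expect_equal(mr$spearman_df, 28)
  expect_equal(mr$partial_df, 27)
})

test_that("generator cohorts land in the documented correlation bands", {
  rs <- ps <- numeric(3)
  for (s in 1:3) {
    fr <- analysis_frame(generate_cohort(cohort_config(seed = 300 + s)))
    mr <- matrix_relations(fr$ma_t1, fr$matrix_t1, fr$age_months_t1)
    rs[s] <- mr$spearman_r; ps[s] <- mr$partial_r
  }
  expect_true(all(rs > 0.7 & rs < 0.9))
  expect_true(all(ps > 0.3 & ps < 0.6))
})
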