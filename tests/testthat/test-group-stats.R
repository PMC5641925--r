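test_that("null and separated groups behave as expected in both branches", {
  set.seed(1)
  x <- rnorm(40); g <- rep(letters[1:4], each = 10)
  for (tst in c("anova", "kruskal_wallis")) {
    out <- compare_groups(x, g, tst)
    expect_gt(out$p_value, 0.05)
    expect_true(all(out$pairwise$adj_p > 0.05))
  }
  y <- c(rnorm(10), rnorm(10) + 10)  # 10 SD shift
  h <- rep(c("a", "b"), each = 10)
  for (tst in c("anova", "kruskal_wallis")) {
    out <- compare_groups(y, h, tst)
    expect_lt(out$pairwise$adj_p[1], 0.001)
  }
  expect_error(compare_groups(rnorm(3), c("a", "a", "b")), ">= 2")
})

test_that("two-group ANOVA matches the two-sample t-test (F = t^2)", {
  set.seed(5)
  x <- c(rnorm(8, 0), rnorm(9, 0.7)); g <- rep(c("a", "b"), c(8, 9))
  out <- compare_groups(x, g, "anova")
  tt <- t.test(x ~ g, var.equal = TRUE)
  expect_equal(out$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(out$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Kruskal-Wallis branch is invariant under monotone transforms", {
  set.seed(6)
  x <- rexp(30); g <- rep(c("a", "b", "c"), each = 10)
  o1 <- compare_groups(x, g, "kruskal_wallis")
  o2 <- compare_groups(exp(x), g, "kruskal_wallis")
  o3 <- compare_groups(log(x + 1), g, "kruskal_wallis")
  expect_equal(o1$statistic, o2$statistic)
  expect_equal(o1$pairwise$adj_p, o2$pairwise$adj_p)
  expect_equal(o1$pairwise$adj_p, o3$pairwise$adj_p)
})

test_that("family-wise error of the adjusted pairwise tests is controlled", {
  set.seed(123)
  fwe <- mean(replicate(300, {
    out <- compare_groups(rnorm(15), rep(c("a", "b", "c"), each = 5),
                          "anova")
    any(out$pairwise$adj_p < 0.05)
  }))
  expect_lte(fwe, 0.08)
})

test_that("intake-weight correlation links per-animal medians to maxima", {
  # intake exactly proportional to maximum attained weight -> rho = 1
  n <- 12
  intake <- seq(2.5, 4, length.out = n)
  rec <- do.call(rbind, lapply(seq_len(n), function(i) {
    tibble::tibble(
      animal_id = sprintf("a%02d", i), cohort_weeks = 13,
      week = c(0, 4, 8, 0, 4, 8),
      variable = rep(c("food_g_day", "bw_g"), each = 3),
      value = c(rep(intake[i], 3), 30, 30 + 4 * intake[i], 28),
      dropout = i <= 2)
  }))
  out <- intake_weight_correlation(rec)
  expect_equal(out$rho, 1, tolerance = 1e-9)
  expect_equal(out$n_animals, n)
  out_ex <- intake_weight_correlation(rec, include_dropouts = FALSE)
  expect_equal(out_ex$n_animals, n - 2)
  expect_error(intake_weight_correlation(rec[rec$variable == "bw_g", ]),
               ">= 3 animals")
})

test_that("permuted intake-weight pairings have mean correlation near 0", {
  set.seed(9)
  n <- 20
  base_bw <- rnorm(n, 40, 5)
  rhos <- replicate(200, {
    intake <- sample(rnorm(n, 3.2, 0.3))
    rec <- do.call(rbind, lapply(seq_len(n), function(i) {
      tibble::tibble(animal_id = sprintf("a%02d", i), cohort_weeks = 13,
                     week = c(0, 0), variable = c("food_g_day", "bw_g"),
                     value = c(intake[i], base_bw[i]), dropout = FALSE)
    }))
    intake_weight_correlation(rec)$rho
  })
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("random dropout barely moves the fixed effects; informative
           dropout moves them more", {
  tr <- trajectory_truth(c(30, 1.5, -0.04, 0), random_sd = c(3, 0.05),
                         resid_sd = 1.5)
  max_delta <- function(records) {
    max(abs(dropout_sensitivity(records, "bw_g", 2,
                                random = "intercept")$delta_se))
  }
  set.seed(40)
  mcar <- sapply(1:15, function(r) {
    sim <- simulate_trajectories(
      cohort_design(sizes = c(30, 40), termination_weeks = c(13, 28),
                    dropout_rate = 10 / 115), tr, "bw_g")
    max_delta(sim$records)
  })
  expect_gte(mean(mcar < 1), 0.9)
  # dropout tied to the outcome (heaviest animals truncated early)
  informative <- sapply(1:15, function(r) {
    sim <- simulate_trajectories(
      cohort_design(sizes = c(30, 40), termination_weeks = c(13, 28),
                    dropout_rate = 0), tr, "bw_g")
    rec <- sim$records
    heavy <- sim$animals$animal_id[order(-sim$animals$b0)][1:10]
    drop_rows <- rec$animal_id %in% heavy & rec$week > 8
    rec <- rec[!drop_rows, ]
    rec$dropout <- rec$animal_id %in% heavy
    max_delta(rec)
  })
  expect_gt(mean(informative), mean(mcar))
})

test_that("absence of dropouts returns an identical pair with a warning", {
  sim <- simulate_trajectories(
    cohort_design(sizes = 20, termination_weeks = 28, dropout_rate = 0,
                  seed = 2),
    trajectory_truth(c(30, 1, -0.02, 0), random_sd = c(2, 0),
                     resid_sd = 1), "bw_g")
  expect_warning(out <- dropout_sensitivity(sim$records, "bw_g", 2,
                                            random = "intercept"),
                 "no dropout")
  expect_true(all(out$delta_se == 0))
})
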