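rand_props <- function(n, types = c("A", "B"), seed = 1) {
  set.seed(seed)
  p <- matrix(runif(n * length(types)), n)
  p <- p / rowSums(p)
  dimnames(p) <- list(paste0("s", seq_len(n)), types)
  p
}

test_that("evaluating an estimator against itself is perfect", {
  tru <- rand_props(8, seed = 2)
  rep_ <- evaluate_estimates(tru, tru)
  expect_equal(rep_$per_type$correlation, c(1, 1))
  expect_equal(rep_$per_type$rmse, c(0, 0))
  expect_equal(rep_$per_type$mean_estimate, rep_$per_type$mean_true)
  expect_equal(rep_$per_type$sd_estimate, rep_$per_type$sd_true)
  expect_equal(rep_$bias$mean_difference, 0)
  expect_equal(rep_$bias$p_value, 1)  # zero-variance differences, noted
  expect_match(rep_$bias$note, "zero variance")
})

test_that("a constant offset shows up as pure bias", {
  tru <- rand_props(20, seed = 3) / 2  # keep room for the offset
  est <- tru + 0.1
  rep_ <- evaluate_estimates(est, tru)
  expect_equal(rep_$per_type$rmse, c(0.1, 0.1))
  expect_equal(rep_$per_type$correlation, c(1, 1))
  expect_lt(rep_$bias$p_value, 1e-10)
  expect_equal(rep_$bias$mean_difference, 0.1)
})

test_that("per-type metrics match an independently coded oracle", {
  set.seed(9)
  tru <- rand_props(10, seed = 9)
  est <- clamp01(tru + matrix(rnorm(20, 0, 0.05), 10))
  rep_ <- evaluate_estimates(est, tru)
  for (i in 1:2) {
    e <- est[, i]; t_ <- tru[, i]
    expect_equal(rep_$per_type$rmse[i], sqrt(sum((e - t_)^2) / length(e)))
    expect_equal(rep_$per_type$correlation[i],
                 sum((e - mean(e)) * (t_ - mean(t_))) /
                   sqrt(sum((e - mean(e))^2) * sum((t_ - mean(t_))^2)))
    expect_equal(rep_$per_type$sd_estimate[i],
                 sqrt(sum((e - mean(e))^2) / (length(e) - 1)))
  }
  expect_equal(rep_$mean_rmse, mean(rep_$per_type$rmse))
})

test_that("squared RMSE decomposes into squared bias plus error variance", {
  set.seed(4)
  tru <- rand_props(400, seed = 4)
  est <- tru + matrix(rnorm(800, 0.02, 0.03), 400)
  rep_ <- evaluate_estimates(est, tru)
  for (i in 1:2) {
    e <- est[, i] - tru[, i]
    expect_equal(rep_$per_type$rmse[i]^2,
                 mean(e)^2 + mean((e - mean(e))^2), tolerance = 1e-12)
  }
})

test_that("evaluation is invariant to sample order and excludes missing pairwise", {
  tru <- rand_props(10, seed = 5)
  est <- clamp01(tru + matrix(rnorm(20, 0, 0.03), 10))
  r1 <- evaluate_estimates(est, tru)
  perm <- sample(10)
  r2 <- evaluate_estimates(est[perm, ], tru)
  expect_equal(r2$per_type, r1$per_type)

  est_na <- est
  est_na[1:2, "A"] <- NA
  r3 <- evaluate_estimates(est_na, tru)
  expect_equal(r3$per_type$n, c(8L, 10L))
})

test_that("undefined correlations are flagged rather than fabricated", {
  tru <- rand_props(4, seed = 6)
  est <- tru
  est[, "A"] <- 0.5  # constant estimates
  rep_ <- evaluate_estimates(est, tru)
  expect_true(is.na(rep_$per_type$correlation[1]))
  # fewer than 3 pairs
  rep2 <- evaluate_estimates(tru[1:2, ], tru[1:2, ])
  expect_true(all(is.na(rep2$per_type$correlation)))
  expect_error(bias_test(tru[1, "A", drop = FALSE], tru[1, "A", drop = FALSE]),
               "2 paired")
})

test_that("the bias test is calibrated under the null", {
  set.seed(77)
  pvals <- replicate(60, {
    tru <- matrix(runif(20), 10, dimnames = list(paste0("s", 1:10),
                                                 c("A", "B")))
    est <- tru + matrix(rnorm(20, 0, 0.05), 10)
    bias_test(est, tru)$p_value
  })
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.12)
  expect_gt(mean(pvals), 0.3)  # roughly uniform p-values, not degenerate
})

test_that("leave-one-out emits one row per amplicon plus an exact baseline", {
  cfg <- simulation_config(seed = 44)
  s <- run_synth_study(cfg, methods = "wnnls")
  loo <- leave_one_out(s$bulk_meth, s$panel, s$truth$proportions,
                       method = "wnnls")
  expect_equal(nrow(loo), 17 + 1)
  expect_equal(loo$excluded_amplicon[1], "none")
  base <- evaluate_estimates(deconvolve_cohort(s$bulk_meth, s$panel,
                                               method = "wnnls"),
                             s$truth$proportions)
  expect_identical(loo$mean_rmse[1], base$mean_rmse)
  expect_identical(loo$mean_correlation[1], base$mean_correlation)
  expect_identical(attr(loo, "reports")$none$per_type, base$per_type)
})

test_that("excluding an uninformative amplicon leaves noise-free estimates unchanged", {
  means <- rbind(A = c(0.9, 0.1, 0.5, 0.4), B = c(0.1, 0.9, 0.5, 0.4))
  colnames(means) <- paste0("g", 1:4)
  panel <- manual_panel(means, amplicon = c("amp1", "amp2", "flat", "flat"))
  tru <- rand_props(6, seed = 11)
  bulk <- tru %*% means  # exact mixtures: the flat amplicon fits perfectly
  loo <- leave_one_out(bulk, panel, tru, method = "wnnls")
  base <- loo[loo$excluded_amplicon == "none", -1]
  flat <- loo[loo$excluded_amplicon == "flat", -1]
  expect_equal(unlist(flat), unlist(base), tolerance = 1e-6)
})

test_that("losing the only amplicon for a rare type degrades that type most", {
  set.seed(55)
  types <- c("A", "B", "C", "D")
  # amp4 carries the only markers separating the rare type D; jittered
  # baselines keep the reduced design full rank (but barely informative for D)
  means <- matrix(runif(32, 0.05, 0.15), 4, 8,
                  dimnames = list(types, paste0("g", 1:8)))
  means["A", 1:2] <- 0.9; means["B", 3:4] <- 0.9; means["C", 5:6] <- 0.9
  means["D", 7:8] <- 0.9
  amps <- rep(paste0("amp", 1:4), each = 2)
  panel <- manual_panel(means, amplicon = amps)
  tru <- cbind(A = runif(12, 0.2, 0.4), B = runif(12, 0.1, 0.3),
               C = runif(12, 0.3, 0.5), D = runif(12, 0.02, 0.1))
  tru <- tru / rowSums(tru)
  rownames(tru) <- paste0("s", 1:12)
  bulk <- tru %*% means + matrix(rnorm(12 * 8, 0, 0.01), 12)
  loo <- leave_one_out(bulk, panel, tru, method = "wnnls")
  drop_cor <- loo$cor_D[1] - loo$cor_D[-1]
  expect_equal(loo$excluded_amplicon[-1][which.max(drop_cor)], "amp4")
})
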