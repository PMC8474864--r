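two_type_panel <- function() {
  means <- matrix(c(0.9, 0.1, 0.5, 0.1, 0.9, 0.5), 2, 3, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("g1", "g2", "g3")))
  manual_panel(means)
}

test_that("a bulk equal to one reference profile is called pure", {
  cfg <- simulation_config(subject_sd = 0, var_cpg_fraction = 0, seed = 2)
  prof <- simulate_reference(cfg)$truth$profiles
  panel <- manual_panel(prof)
  y <- prof["CD14", ]
  for (est in list(estimate_ols(y, panel), estimate_wnnls(y, panel))) {
    expect_equal(unname(est$proportions["CD14"]), 1)
    expect_equal(unname(est$proportions[c("CD3", "CD15", "CD19")]),
                 rep(0, 3), tolerance = 1e-9)
    expect_equal(unname(est$residuals), rep(0, ncol(prof)), tolerance = 1e-9)
  }
})

test_that("the two-type normal equations are solved exactly", {
  panel <- two_type_panel()
  y <- c(g1 = 0.7, g2 = 0.3, g3 = 0.5)  # = 0.75*A + 0.25*B
  est <- estimate_ols(y, panel)
  expect_equal(unname(est$raw), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(unname(est$proportions), c(0.75, 0.25), tolerance = 1e-12)
  estw <- estimate_wnnls(y, panel)
  expect_equal(unname(estw$proportions), c(0.75, 0.25), tolerance = 1e-9)
})

test_that("the raw OLS solution matches a grid search over the SSE surface", {
  grid <- as.matrix(expand.grid(p1 = seq(0, 1, 0.01), p2 = seq(0, 1, 0.01)))
  for (seed in 1:20) {
    set.seed(seed)
    m <- 6
    means <- rbind(A = c(runif(3, 0.7, 0.95), runif(3, 0.05, 0.3)),
                   B = c(runif(3, 0.05, 0.3), runif(3, 0.7, 0.95)))
    colnames(means) <- paste0("g", 1:m)
    p_true <- runif(1, 0.1, 0.9)
    y <- drop(c(p_true, 1 - p_true) %*% means) + rnorm(m, 0, 0.005)
    names(y) <- colnames(means)
    est <- estimate_ols(y, manual_panel(means))
    sse <- colSums((t(grid %*% means) - y)^2)
    best <- grid[which.min(sse), ]
    expect_lt(max(abs(est$raw - best)), 0.011)
  }
})

test_that("results are invariant to CpG order and equivariant to cell-type order", {
  cfg <- simulation_config(seed = 19)
  s <- run_synth_study(cfg, methods = "wnnls")
  y <- s$bulk_meth$beta[1, ]
  base <- estimate_wnnls(y, s$panel)

  perm <- sample(length(y))
  p_cpg <- s$panel
  p_cpg$means <- p_cpg$means[, perm]
  p_cpg$vars <- p_cpg$vars[, perm]
  p_cpg$markers <- p_cpg$markers[perm, ]
  expect_equal(estimate_wnnls(y[perm], p_cpg)$proportions, base$proportions,
               tolerance = 1e-8)

  tperm <- c(3, 1, 4, 2)
  p_ct <- s$panel
  p_ct$means <- p_ct$means[tperm, ]
  p_ct$vars <- p_ct$vars[tperm, ]
  p_ct$celltypes <- p_ct$celltypes[tperm]
  got <- estimate_wnnls(y, p_ct)$proportions
  expect_equal(got, base$proportions[names(got)], tolerance = 1e-8)
})

test_that("zero cross-subject dispersion reduces the weighted fit to equal weights", {
  panel <- two_type_panel()  # vars all zero
  y <- c(g1 = 0.65, g2 = 0.35, g3 = 0.52)
  est <- estimate_wnnls(y, panel, nu = 1e-4)
  expect_equal(unname(est$weights), rep(1e4, 3))
  # and a huge variance floor converges to the same equal-weight solution
  noisy <- panel
  noisy$vars <- matrix(runif(6, 0, 0.05), 2, 3, dimnames = dimnames(panel$means))
  est_inf <- estimate_wnnls(y, noisy, nu = 1e8)
  expect_equal(est_inf$proportions, est$proportions, tolerance = 1e-6)
})

test_that("high cross-subject variance CpGs receive lower final weights", {
  cfg <- simulation_config(seed = 23, var_cpg_fraction = 0.5,
                           var_cpg_factor = 10)
  s <- run_synth_study(cfg, methods = "wnnls")
  res <- attr(s$est_wnnls, "results")[[1]]
  p <- res$proportions[rownames(s$panel$vars)]
  sig <- drop(p^2 %*% s$panel$vars[, names(res$weights)])
  # weights are a monotone decreasing function of p' S_g p
  expect_true(all(diff(res$weights[order(sig)]) <= 1e-12))
  noisy <- names(sort(sig, decreasing = TRUE))[1:5]
  quiet <- names(sort(sig))[1:5]
  expect_gt(min(res$weights[quiet]), max(res$weights[noisy]))
})

test_that("noise-free mixtures are recovered to numerical precision", {
  cfg <- simulation_config(subject_sd = 0, var_cpg_fraction = 0, seed = 4)
  ref <- simulate_reference(cfg)
  panel <- manual_panel(ref$truth$profiles,
                        amplicon = ref$truth$markers$amplicon_id)
  for (i in seq_len(nrow(ref$truth$proportions))) {
    y <- ref$truth$expected_bulk[i, ]
    truth_p <- ref$truth$proportions[i, ]
    expect_equal(estimate_ols(y, panel)$proportions[names(truth_p)], truth_p,
                 tolerance = 1e-8)
    expect_equal(estimate_wnnls(y, panel)$proportions[names(truth_p)], truth_p,
                 tolerance = 1e-8)
  }
})

test_that("both estimators recover proportions across a simulated cohort", {
  cfg <- simulation_config(n_bulk_samples = 50, proportions_mode = "dirichlet",
                           dirichlet_alpha = c(2.6, 1.2, 5.4, 0.8),
                           depth = 3000, subject_sd = 0.03, seed = 91)
  s <- run_synth_study(cfg)
  for (rep_ in list(s$report_wnnls, s$report_ols))
    expect_true(all(rep_$per_type$correlation >= 0.95))
  expect_lte(s$report_wnnls$mean_rmse, s$report_ols$mean_rmse)
})

test_that("estimated proportions always lie on the simplex", {
  cfg <- simulation_config(seed = 37, depth = 120)  # shallow, noisy
  s <- run_synth_study(cfg)
  for (est in list(s$est_wnnls, s$est_ols)) {
    p <- as.matrix(est[, c("CD14", "CD15", "CD19", "CD3")])
    expect_true(all(p >= 0))
    expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  }
})

test_that("degenerate designs fail loudly", {
  means <- matrix(c(0.9, 0.1, 0.9, 0.1, 0.5, 0.5), 2, 3, byrow = TRUE,
                  dimnames = list(c("A", "B"), c("g1", "g2", "g3")))
  means["B", ] <- means["A", ]  # collinear
  expect_error(estimate_ols(c(g1 = 0.5, g2 = 0.5, g3 = 0.5),
                            manual_panel(means)), "collinear")
  panel <- two_type_panel()
  expect_error(estimate_ols(c(g1 = 0.5), panel), "fewer observed markers")
  expect_error(estimate_wnnls(c(g1 = 0.5, g2 = 0.2, g3 = 0.3), panel, nu = 0),
               "nu")
})

test_that("cohort estimation honours missing and critical markers", {
  cfg <- simulation_config(seed = 29)
  s <- run_synth_study(cfg, methods = "wnnls")
  beta <- s$bulk_meth$beta
  # knock out one non-critical amplicon for sample 1, a critical one for sample 2
  non_crit <- s$panel$markers$cpg_id[s$panel$markers$amplicon_id == "P9"]
  crit <- s$panel$markers$cpg_id[s$panel$markers$amplicon_id == "P14"]
  beta[1, non_crit] <- NA
  beta[2, crit] <- NA
  est <- deconvolve_cohort(beta, s$panel, method = "wnnls",
                           critical_markers = c("P14", "P17"))
  expect_false(est$critical_marker_violation[1])
  expect_equal(est$n_markers_used[1], ncol(beta) - length(non_crit))
  expect_true(est$critical_marker_violation[2])
  expect_true(all(is.na(est[2, s$panel$celltypes])))

  # identical bulks give identical results
  dup <- rbind(b1 = s$bulk_meth$beta[3, ], b2 = s$bulk_meth$beta[3, ])
  est2 <- deconvolve_cohort(dup, s$panel, method = "wnnls")
  expect_equal(unname(unlist(est2[1, -1])), unname(unlist(est2[2, -1])))
})
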