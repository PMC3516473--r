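# Component p-values, HEW calibration and decision, BH correction, the
# multilocus HKA fit and clade diversity tests.

test_that("component p-values respect tails and the add-one bound", {
  nul <- null_distribution(20, 8, 999, seed = 1)
  m <- nul$m
  # observation below every simulated H -> minimal attainable p
  pv <- component_pvalues(list(H_norm = min(nul$H) - 1, EW_F = 0.9, D = NULL), nul)
  expect_equal(unname(pv["p_H"]), 1 / (m + 1))
  # F at the null median -> p_EW about 0.5
  pv2 <- component_pvalues(list(H_norm = 0, EW_F = stats::median(nul$F)), nul)
  expect_lt(abs(pv2["p_EW"] - 0.5), 0.05)
  # undefined observation propagates as NA
  pv3 <- component_pvalues(list(H_norm = NA, EW_F = 0.5, D = NA), nul)
  expect_true(is.na(pv3["p_H"]) && is.na(pv3["p_D"]))
})

test_that("component p-values are uniform under the null model", {
  set.seed(2)
  nul <- null_distribution(25, 6, 999, seed = 3)
  ps <- replicate(2000, {
    st <- hewscan:::.sim_sample_stats(
      mutate_fixed_theta(simulate_genealogy(25), 6))
    if (st$S == 0) NA
    else component_pvalues(list(H_norm = st$H, EW_F = st$F), nul)["p_H"]
  })
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("threshold calibration matches product-measure closed forms", {
  set.seed(4)
  u <- data.frame(p_H = runif(2e5), p_EW = runif(2e5))
  t_ind <- calibrate_hew_threshold(u, alpha = 0.05)
  expect_lt(abs(t_ind - sqrt(0.05)), 0.01)
  v <- data.frame(p_H = u$p_H, p_EW = u$p_H)  # perfectly correlated
  t_cor <- calibrate_hew_threshold(v, alpha = 0.05)
  expect_lt(abs(t_cor - 0.05), 0.005)
  # monotone nondecreasing in alpha
  ts <- sapply(c(0.01, 0.05, 0.1, 0.2), function(a)
    calibrate_hew_threshold(u, alpha = a))
  expect_true(all(diff(ts) >= 0))
  expect_error(calibrate_hew_threshold(u[1:10, ], 0.05), "1000")
})

test_that("the calibrated threshold holds its size on the calibration set", {
  nul <- null_distribution(30, 10, 2000, seed = 5)
  t <- calibrate_hew_threshold(nul$calib, alpha = 0.05)
  joint <- mean(nul$calib$p_H <= t & nul$calib$p_EW <= t)
  expect_lte(joint, 0.05)
  t2 <- calibrate_hew_threshold(nul$calib, alpha = 0.049999)
  expect_gte(t, 0.05)  # joint calibration admits larger-than-marginal t
  expect_equal(t, t2)
})

test_that("the HEW decision requires both tails to be extreme", {
  nul <- null_distribution(20, 8, 1500, seed = 6)
  t <- calibrate_hew_threshold(nul$calib, 0.05)
  r1 <- hew_test(0.001, 0.001, t, nul$calib)
  expect_true(r1$reject)
  expect_equal(r1$compound_p, 1 / (nul$m + 1))
  r2 <- hew_test(0.5, 0.001, t, nul$calib)
  expect_false(r2$reject)
  r3 <- hew_test(NA, 0.01, t, nul$calib)
  expect_true(is.na(r3$reject))
})

test_that("BH adjustment matches a hand-coded step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  step_up <- function(p) {  # textbook transcription
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    adj <- pmin(1, cummin(m / (m:1) * p[o]))
    adj[ro]
  }
  set.seed(7)
  for (r in 1:10) {
    p <- runif(sample(3:30, 1))
    expect_equal(bh_adjust(p), step_up(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withNA <- bh_adjust(c(0.01, NA, 0.04))
  expect_true(is.na(withNA[2]))
})

test_that("the HKA moment fit matches an independent numerical solve", {
  loci <- data.frame(S = c(24, 40, 12), div = c(18, 33, 15),
                     n = c(20, 16, 30), L = c(500, 480, 520))
  a <- sapply(loci$n, function(n) sum(1 / (1:(n - 1))))
  fit <- hewscan:::.hka_fit(loci$S, loci$div, a)
  # independent route: drive the residuals of the defining equation system
  # (per-locus totals plus the divergence-sum constraint) to zero with a
  # general-purpose optimizer
  obj <- function(par) {
    w <- exp(par[1:3]); T_ <- exp(par[4])
    sum((loci$S + loci$div - w * (a + T_ + 1))^2) +
      (sum(loci$div) - (T_ + 1) * sum(w))^2
  }
  opt <- optim(c(log(rep(5, 3)), log(1)), obj, method = "BFGS",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(opt$value, 1e-6)
  expect_lt(abs(fit$T - exp(opt$par[4])), 1e-3)
  expect_lt(max(abs(fit$w - exp(opt$par[1:3]))), 1e-3)
  # the fit satisfies the moment equations exactly
  expect_equal(sum(fit$w * a) + sum(fit$w * (fit$T + 1)),
               sum(loci$S) + sum(loci$div), tolerance = 1e-9)
})

test_that("HKA flags planted polymorphism deficits and fits exact data", {
  # data exactly proportional to expectations -> X^2 = 0, p ~ 1
  n <- c(20, 20); a <- sum(1 / (1:19))
  w <- c(5, 10); T_ <- 2
  loci0 <- data.frame(S = w * a, div = w * (T_ + 1), n = n, L = 500)
  h0 <- hka_test(loci0, reps = 300, seed = 8)
  expect_lt(h0$x2, 1e-10)
  expect_gt(h0$p, 0.95)
  # a 5x deficit of S at one locus dominates the deviation sum
  loci1 <- data.frame(S = c(50, 60, 10), div = c(40, 45, 40),
                      n = 20, L = 500)
  h1 <- hka_test(loci1, reps = 300, seed = 9)
  expect_equal(which.max(h1$fit$deviation), 3L)
})

test_that("HKA simulation p-values are uniform under the fitted null", {
  set.seed(10)
  n <- c(15, 15); a <- sapply(n, function(x) sum(1 / (1:(x - 1))))
  w <- c(6, 9); T_ <- 1.5
  ps <- replicate(200, {
    g1 <- simulate_genealogy(n[1]); g2 <- simulate_genealogy(n[2])
    loci <- data.frame(
      S = c(rpois(1, w[1] / 2 * g1$total_length),
            rpois(1, w[2] / 2 * g2$total_length)),
      div = c(rpois(1, w[1] * (T_ + rexp(1))),
              rpois(1, w[2] * (T_ + rexp(1)))),
      n = n, L = 500)
    tryCatch(hka_test(loci, reps = 400)$p, error = function(e) NA)
  })
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("HEW separates sweep classes from neutrality as expected", {
  # Partial sweeps leave both signature components (high-frequency derived
  # alleles via escaped lineages, and excess haplotype homozygosity), so
  # rejection must be far above the neutral rate.  Completed star sweeps
  # cannot move the H component without recombination, but they concentrate
  # the compound p near zero relative to neutral loci.
  set.seed(20)
  ref <- make_reference_gene(500, NULL, seed = 21)
  nulls <- new.env(parent = emptyenv())
  a50 <- sum(1 / (1:49))
  eval_locus <- function(scen, seed, f = 0.8) {
    sim <- simulate_population_sample(
      scenario_config(scen, n = 50, theta = 10, tau = 0.01, sweep_f = f),
      ref, seed = seed)
    S <- sum(hewscan:::.segregating_cols(sim$aln$mat))
    if (S == 0) return(c(NA, NA))
    pol <- polarize_sites(sim$aln, sim$outgroup)
    obs <- list(H_norm = fay_wu_h_norm(unfolded_sfs(sim$aln, pol)),
                EW_F = ew_homozygosity(sim$aln)$F)
    key <- as.character(S)
    if (is.null(nulls[[key]]))
      nulls[[key]] <- null_distribution(50, S / a50, 1000, seed = 5e4 + S,
                                        min_defined = 1000)
    nul <- nulls[[key]]
    pv <- component_pvalues(obs, nul)
    hw <- hew_test(pv["p_H"], pv["p_EW"],
                   calibrate_hew_threshold(nul$calib, 0.05), nul$calib)
    c(reject = hw$reject, cp = hw$compound_p)
  }
  neu <- t(sapply(1:60, function(i) eval_locus("neutral_constant", 3000 + i)))
  par <- t(sapply(1:60, function(i) eval_locus("partial_sweep", 4000 + i)))
  com <- t(sapply(1:60, function(i) eval_locus("complete_sweep", 5000 + i)))
  neutral_rate <- mean(neu[, 1], na.rm = TRUE)
  expect_lte(neutral_rate, 0.05 + 2.58 * sqrt(0.05 * 0.95 / 60))
  expect_gt(mean(par[, 1], na.rm = TRUE), 5 * max(neutral_rate, 0.02))
  expect_gt(mean(com[, 2] < 0.2, na.rm = TRUE),
            5 * mean(neu[, 2] < 0.2, na.rm = TRUE) / 2)
  expect_lt(median(com[, 2], na.rm = TRUE), median(neu[, 2], na.rm = TRUE))
})

test_that("HKA neighbor selection skips HEW-significant loci", {
  loci <- data.frame(locus = c("a", "b", "c", "d", "e"),
                     position = c(10, 20, 30, 40, 50),
                     hew_significant = c(FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(hka_select_neighbors(loci, "c"), c("a", "d"))
  expect_equal(hka_select_neighbors(loci, "a"), "d")
  expect_error(hka_select_neighbors(loci, "zz"), "not found")
})

test_that("clade diversity tests find planted deficits and calibrate at the median", {
  set.seed(11)
  cond <- clade_conditioned_sample(40, 18, 35, reps = 2000, seed = 12)
  # observed at the conditioned-null median -> p about 0.5
  obs_med <- list(
    A = list(n = 22, h = stats::median(cond$stats$h_A),
             S = stats::median(cond$stats$S_A),
             k = stats::median(cond$stats$k_A)),
    B = list(n = 18, h = stats::median(cond$stats$h_B),
             S = stats::median(cond$stats$S_B),
             k = stats::median(cond$stats$k_B)))
  ct <- clade_diversity_test(obs_med, cond)
  expect_true(all(abs(ct$p_S - 0.5) < 0.15))
  # observed S below every simulated value -> minimal p
  obs_low <- obs_med
  obs_low$B$S <- -1; obs_low$B$k <- 0; obs_low$B$h <- 0
  ct2 <- clade_diversity_test(obs_low, cond)
  expect_equal(ct2$p_S[ct2$clade == "B"], 1 / (nrow(cond$stats) + 1))
  # swept fixture: a diversity-starved clade is significantly unlikely
  obs_sweep <- obs_med
  obs_sweep$B <- list(n = 18, h = 1, S = 0, k = 0)
  ct3 <- clade_diversity_test(obs_sweep, cond)
  expect_lt(ct3$p_k[ct3$clade == "B"], 0.05)
  expect_error(clade_diversity_test(list(A = list(n = 9, h = 1, S = 1, k = 1),
                                         B = list(n = 2, h = 1, S = 1, k = 1)),
                                    cond), "sizes")
})
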