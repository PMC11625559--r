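# Univariable MR estimators: exact small cases against hand-derived or
# independent-oracle values, plus the structural invariants.

test_that("Wald ratio arithmetic and guards", {
  expect_close(mr_wald_ratio(0.1, 0.01, 0.05, 0.01)$beta, 0.5)
  expect_equal(mr_wald_ratio(0.1, 0.01, 0, 0.01)$beta, 0)
  expect_close(mr_wald_ratio(0.2, 0.01, 0.05, 0.01)$se, 0.05)
  expect_error(mr_wald_ratio(0, 0.01, 0.05, 0.01), "degenerate")
})

test_that("IVW reproduces hand-solved weighted least squares", {
  # symmetric case: equal bx and sy, ratios 0.4 and 0.6 -> 0.5
  h <- hset(bx = c(0.1, 0.1), by = c(0.04, 0.06), sy = c(0.02, 0.02))
  expect_close(mr_ivw(h)$estimate$beta, 0.5)

  # normal equations by hand: w = 1e4, 2.5e3 -> beta = 110/425
  h2 <- hset(bx = c(0.2, 0.1), by = c(0.05, 0.04), sy = c(0.01, 0.02))
  fit <- mr_ivw(h2, model = "fixed")
  expect_close(fit$estimate$beta, 110 / 425)
  # fixed-effect variance is exactly 1/sum(w bx^2)
  expect_close(fit$estimate$se, sqrt(1 / (1e4 * 0.04 + 2.5e3 * 0.01)))

  # shared ratio -> perfect fit, Q = 0, p = 1
  h3 <- hset(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15))
  fit3 <- mr_ivw(h3)
  expect_close(fit3$estimate$beta, 0.5)
  expect_close(fit3$heterogeneity$q_stat, 0)
  expect_equal(fit3$heterogeneity$pval, 1)
  expect_equal(fit3$heterogeneity$df, 2)
})

test_that("IVW with a single SNP falls back to the Wald ratio", {
  h <- hset(bx = 0.2, by = 0.05, sy = 0.01)
  expect_warning(fit <- mr_ivw(h), "Wald")
  expect_close(fit$estimate$beta, 0.25)
  expect_close(fit$estimate$se, 0.05)
})

test_that("random-effects IVW inflates the SE only under excess heterogeneity", {
  h <- hset(bx = c(0.1, 0.2, 0.3, 0.15), by = c(0.08, 0.04, 0.21, 0.02),
            sy = c(0.01, 0.02, 0.015, 0.01))
  fx <- mr_ivw(h, model = "fixed")
  rnd <- mr_ivw(h, model = "random")
  expect_equal(rnd$estimate$beta, fx$estimate$beta)
  q <- fx$heterogeneity$q_stat
  expect_close(rnd$estimate$se,
               fx$estimate$se * sqrt(max(1, q / 3)))
})

test_that("maximum likelihood agrees with its limits", {
  # noiseless line -> exact recovery
  h <- hset(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.10, 0.15))
  expect_close(mr_maximum_likelihood(h)$beta, 0.5, tol = 1e-6)

  # sx -> 0 limit: matches fixed-effect IVW to 1e-6
  set.seed(9)
  h2 <- hset(bx = runif(8, 0.05, 0.3), by = rnorm(8, 0.02, 0.02),
             sx = rep(1e-8, 8), sy = runif(8, 0.01, 0.03))
  ml <- mr_maximum_likelihood(h2)
  ivw <- mr_ivw(h2, model = "fixed")
  expect_close(ml$beta, ivw$estimate$beta, tol = 1e-6)
  expect_close(ml$se, ivw$estimate$se, tol = 1e-4)

  # two-SNP just-identified case sits between the Wald ratios
  h3 <- hset(bx = c(0.1, 0.2), by = c(0.03, 0.12),
             sx = c(0.01, 0.01), sy = c(0.01, 0.01))
  ratios <- c(0.3, 0.6)
  est <- mr_maximum_likelihood(h3)$beta
  expect_true(est > min(ratios) && est < max(ratios))
})

test_that("MR-Egger recovers exact affine structure and matches the WLS oracle", {
  h <- hset(bx = c(0.1, 0.2, 0.3), by = 0.5 * c(0.1, 0.2, 0.3))
  e <- mr_egger(h)
  expect_close(e$estimate$beta, 0.5)
  expect_close(e$pleiotropy$egger_intercept, 0)

  h2 <- hset(bx = c(0.1, 0.2, 0.3), by = 0.02 + 0.5 * c(0.1, 0.2, 0.3))
  e2 <- mr_egger(h2)
  expect_close(e2$estimate$beta, 0.5)
  expect_close(e2$pleiotropy$egger_intercept, 0.02)
  expect_equal(e2$heterogeneity$df, 1)

  # generic 4-point set vs lm() as independent oracle
  bx <- c(0.12, 0.21, 0.33, 0.08)
  by <- c(0.05, 0.11, 0.13, 0.06)
  sy <- c(0.01, 0.02, 0.015, 0.012)
  e3 <- mr_egger(hset(bx, by, sy = sy))
  ofit <- lm(by ~ bx, weights = 1 / sy^2)
  expect_close(e3$estimate$beta, unname(coef(ofit)["bx"]))
  expect_close(e3$pleiotropy$egger_intercept, unname(coef(ofit)[1]))
  # SEs match lm up to the floored inflation convention
  s <- summary(ofit)
  infl_lm <- s$sigma
  expect_close(e3$estimate$se,
               s$coefficients["bx", "Std. Error"] / infl_lm *
                 max(1, infl_lm))
})

test_that("Egger with the intercept pinned to zero reproduces IVW", {
  set.seed(21)
  bx <- runif(6, 0.05, 0.3)
  by <- rnorm(6, 0.2 * bx, 0.01)
  sy <- runif(6, 0.01, 0.02)
  ivw <- mr_ivw(hset(bx, by, sy = sy), model = "fixed")$estimate$beta
  # oracle: origin-constrained weighted regression via lm()
  ofit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  expect_close(ivw, unname(coef(ofit)))
})

test_that("weighted median interpolates the weighted CDF correctly", {
  # equal weights, odd n -> the sample median
  h <- hset_ratios(c(0.1, 0.2, 0.3))
  expect_close(mr_weighted_median(h, n_boot = 0)$beta, 0.2)

  # hand-evaluated CDF interpolation: weights 0.5/0.25/0.25 -> 1/6 above 0.1
  h2 <- hset(bx = c(1, 1, 1), by = c(0.1, 0.2, 0.3),
             sx = rep(1e-8, 3), sy = c(0.1, 0.1 * sqrt(2), 0.1 * sqrt(2)))
  expect_close(mr_weighted_median(h2, n_boot = 0)$beta, 0.1 + 0.1 * 0.25 / 0.375)

  # equal weights, even n: interpolated midpoint
  h3 <- hset_ratios(c(0.1, 0.2, 0.4, 0.5))
  expect_close(mr_weighted_median(h3, n_boot = 0)$beta, 0.3)

  # bootstrap SE is deterministic under a seed
  se1 <- mr_weighted_median(h3, n_boot = 200, seed = 5)$se
  se2 <- mr_weighted_median(h3, n_boot = 200, seed = 5)$se
  expect_identical(se1, se2)
  expect_true(se1 > 0)
})

test_that("weighted median with equal weights equals the sample median for odd n", {
  set.seed(33)
  for (rep in 1:5) {
    r <- rnorm(7, 0.2, 0.3)
    h <- hset_ratios(r)
    expect_close(mr_weighted_median(h, n_boot = 0)$beta, median(r))
  }
})

test_that("mode-based estimation finds the majority mode", {
  # fine-grid density oracle, independent of the implementation path
  oracle_mode <- function(r, w, bw_factor = 1) {
    s <- mad(r); if (s == 0) s <- sd(r)
    bw <- bw_factor * 0.9 * s * length(r)^(-1 / 5)
    grid <- seq(min(r) - 3 * bw, max(r) + 3 * bw, length.out = 50000)
    dens <- sapply(grid, function(x) sum(w * dnorm((x - r) / bw)))
    grid[which.max(dens)]
  }
  r <- c(0.2, 0.2, 0.2, 0.9)
  h <- hset_ratios(r)
  est <- mr_mode(h, n_boot = 0)$beta
  expect_close(est, oracle_mode(r, rep(0.25, 4)), tol = 1e-2)
  expect_lt(abs(est - 0.2), 0.12)  # majority mode, not the outlier

  # all ratios equal -> that ratio exactly
  expect_equal(mr_mode(hset_ratios(rep(0.3, 4)), n_boot = 0)$beta, 0.3)

  # uniform weights make simple and weighted modes identical
  h2 <- hset_ratios(c(0.1, 0.25, 0.3, 0.32))
  expect_equal(mr_mode(h2, weighted = FALSE, n_boot = 0)$beta,
               mr_mode(h2, weighted = TRUE, n_boot = 0)$beta)

  # seeded bootstrap SE is reproducible
  expect_identical(mr_mode(h2, n_boot = 100, seed = 3)$se,
                   mr_mode(h2, n_boot = 100, seed = 3)$se)
})

test_that("Cochran's Q matches the two-term hand computation and is permutation-invariant", {
  h <- hset_ratios(c(0.2, 0.4), ratio_se = c(0.1, 0.1))
  beta_ref <- mr_ivw(h, model = "fixed")$estimate$beta
  expect_close(beta_ref, 0.3)
  q <- cochran_q(h, beta_ref)
  expect_close(q$q_stat, 2)
  expect_equal(q$df, 1)

  set.seed(4)
  h2 <- hset(bx = runif(6, 0.1, 0.3), by = rnorm(6, 0.05, 0.03),
             sy = runif(6, 0.01, 0.03))
  perm <- h2$data[sample(6), ]
  expect_close(cochran_q(h2)$q_stat, cochran_q(perm)$q_stat)
})

test_that("leave-one-out exposes the influential variant", {
  h <- hset(bx = c(0.1, 0.2, 0.3), by = c(0.05, 0.1, 0.15))
  loo <- mr_leave_one_out(h)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$excluded, c("rs1", "rs2", "rs3", "(all)"))
  for (j in 1:3)
    expect_close(loo$beta[j],
                 mr_ivw(h$data[-j, ])$estimate$beta)

  # planted huge-ratio SNP: its exclusion row moves the estimate the most
  set.seed(8)
  bx <- runif(10, 0.1, 0.3)
  by <- rnorm(10, 0.2 * bx, 0.005)
  by[4] <- by[4] + 0.2
  h2 <- hset(bx, by)
  loo2 <- mr_leave_one_out(h2)
  all_beta <- loo2$beta[loo2$excluded == "(all)"]
  shifts <- abs(loo2$beta[1:10] - all_beta)
  expect_equal(which.max(shifts), 4)
})

test_that("the full estimator suite returns a coherent table", {
  sim <- simulate_two_sample(sim_config(m_instruments = 30, seed = 3))
  h <- harmonize_pair(sim$exposure, sim$outcome)
  out <- mr_all(h, n_boot = 50, seed = 1)
  expect_equal(nrow(out$estimates), 6)
  expect_setequal(out$estimates$method,
                  c("IVW (multiplicative random effects)", "Maximum likelihood",
                    "MR-Egger", "Weighted median", "Simple mode",
                    "Weighted mode"))
  expect_true(all(out$estimates$or > 0))
  expect_close(out$estimates$or, exp(out$estimates$beta))
})
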