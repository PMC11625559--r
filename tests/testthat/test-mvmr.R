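# Multivariable MR estimators.

make_mes <- function(seed = 1, n = 12, p = 2, theta = c(0.2, -0.1),
                     pleio = rep(0, n)) {
  set.seed(seed)
  bx <- matrix(runif(n * p, 0.05, 0.3), n, p)
  sx <- matrix(0.01, n, p)
  sy <- runif(n, 0.01, 0.02)
  by <- drop(bx %*% theta) + pleio + rnorm(n, 0, sy)
  multi_exposure_set(paste0("rs", 1:n), bx, sx, by, sy,
                     exposure_names = paste0("X", 1:p))
}

test_that("single-exposure MVMR-IVW equals univariable IVW exactly", {
  set.seed(2)
  bx <- runif(8, 0.05, 0.3)
  sy <- runif(8, 0.01, 0.02)
  by <- rnorm(8, 0.25 * bx, sy)
  m <- multi_exposure_set(paste0("rs", 1:8), cbind(bx), cbind(rep(0.01, 8)),
                          by, sy, "X")
  uv <- mr_ivw(hset(bx, by, sy = sy))
  mv <- mvmr_ivw(m)
  expect_close(mv$estimates$beta, uv$estimate$beta)
  expect_close(mv$estimates$se, uv$estimate$se)
  expect_close(mv$heterogeneity$q_stat, uv$heterogeneity$q_stat)
})

test_that("MVMR-IVW solves the weighted normal equations (lm oracle)", {
  m <- make_mes(seed = 5, n = 4, p = 2)
  w <- 1 / m$se_outcome^2
  ofit <- lm(m$beta_outcome ~ 0 + m$beta_exposures, weights = w)
  mv <- mvmr_ivw(m)
  expect_close(mv$estimates$beta, unname(coef(ofit)))

  # zero outcome betas -> zero estimates
  m0 <- m
  m0$beta_outcome <- rep(0, 4)
  expect_close(mvmr_ivw(m0)$estimates$beta, c(0, 0))
})

test_that("MVMR-IVW is invariant to exposure column order", {
  m <- make_mes(seed = 6)
  m_rev <- multi_exposure_set(m$snp_ids, m$beta_exposures[, 2:1],
                              m$se_exposures[, 2:1], m$beta_outcome,
                              m$se_outcome, m$exposure_names[2:1])
  a <- mvmr_ivw(m)$estimates
  b <- mvmr_ivw(m_rev)$estimates
  expect_close(a$beta[a$exposure == "X1"], b$beta[b$exposure == "X1"])
  expect_close(a$beta[a$exposure == "X2"], b$beta[b$exposure == "X2"])
})

test_that("collinear exposures raise an error naming the offender", {
  set.seed(7)
  bx1 <- runif(6, 0.05, 0.3)
  bx <- cbind(bx1, 2 * bx1)
  m <- multi_exposure_set(paste0("rs", 1:6), bx, matrix(0.01, 6, 2),
                          rnorm(6, 0.2 * bx1, 0.01), rep(0.01, 6),
                          c("A", "B"))
  expect_error(mvmr_ivw(m), "collinear.*B")
})

test_that("identification requires more SNPs than exposures", {
  expect_error(
    multi_exposure_set("rs1", cbind(0.1, 0.2), cbind(0.01, 0.01), 0.05, 0.01,
                       c("A", "B")),
    "more instruments")
})

test_that("MVMR-Egger recovers affine structure and reduces to univariable Egger", {
  # exact linear data with a common intercept c = 0.015
  set.seed(8)
  bx <- matrix(runif(20, 0.05, 0.3), 10, 2)
  by <- 0.015 + drop(bx %*% c(0.2, -0.1))
  m <- multi_exposure_set(paste0("rs", 1:10), bx, matrix(0.01, 10, 2),
                          by, rep(0.01, 10), c("A", "B"))
  e <- mvmr_egger(m)
  expect_close(e$pleiotropy$egger_intercept, 0.015)
  expect_close(e$estimates$beta, c(0.2, -0.1))

  # single exposure: equals univariable MR-Egger
  set.seed(9)
  bx1 <- runif(8, 0.05, 0.3)
  sy <- runif(8, 0.01, 0.02)
  by1 <- rnorm(8, 0.01 + 0.2 * bx1, sy)
  m1 <- multi_exposure_set(paste0("rs", 1:8), cbind(bx1),
                           cbind(rep(0.01, 8)), by1, sy, "A")
  uv <- mr_egger(hset(bx1, by1, sy = sy))
  mv <- mvmr_egger(m1)
  expect_close(mv$estimates$beta, uv$estimate$beta)
  expect_close(mv$pleiotropy$egger_intercept, uv$pleiotropy$egger_intercept)
  expect_close(mv$pleiotropy$intercept_se, uv$pleiotropy$intercept_se)
})

test_that("the Lasso keeps everything at huge penalties and rejects lambda = 0", {
  m <- make_mes(seed = 10)
  base <- mvmr_ivw(m)
  las <- mvmr_lasso(m, lambda_grid = 1e9)
  expect_length(las$excluded_snps, 0)
  expect_close(las$estimates$beta, base$estimates$beta)
  expect_error(mvmr_lasso(m, lambda_grid = 0), "saturated|identified")
})

test_that("the Lasso excludes a planted pleiotropic SNP", {
  hits <- sapply(1:25, function(s) {
    pleio <- rep(0, 12)
    pleio[3] <- 0.15   # ~10x the outcome SE
    m <- make_mes(seed = 200 + s, pleio = pleio)
    "rs3" %in% mvmr_lasso(m)$excluded_snps
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Lasso post-selection heterogeneity respects the stopping rule", {
  m <- make_mes(seed = 11, n = 15)
  las <- mvmr_lasso(m)
  expect_lte(las$q_post, las$df_post)
  expect_equal(sort(c(las$excluded_snps, las$retained_snps)),
               sort(m$snp_ids))
})

test_that("MVMR-median recovers noiseless coefficients and matches the univariable median", {
  set.seed(12)
  bx <- matrix(runif(20, 0.05, 0.3), 10, 2)
  by <- drop(bx %*% c(0.2, -0.1))
  m <- multi_exposure_set(paste0("rs", 1:10), bx, matrix(0.01, 10, 2),
                          by, rep(0.01, 10), c("A", "B"))
  fit <- mvmr_median(m, n_boot = 0)
  expect_close(fit$estimates$beta, c(0.2, -0.1), tol = 1e-6)

  # single exposure, equal weights and equal bx: both estimators give the
  # plain median of the Wald ratios
  ratios <- c(0.1, 0.22, 0.3, 0.35, 0.6)
  bx1 <- rep(1, 5)
  m1 <- multi_exposure_set(paste0("rs", 1:5), cbind(bx1),
                           cbind(rep(0.01, 5)), ratios, rep(0.05, 5), "A")
  uv <- mr_weighted_median(hset_ratios(ratios, rep(0.05, 5)), n_boot = 0)
  l1 <- mvmr_median(m1, n_boot = 0)
  expect_close(l1$estimates$beta, median(ratios), tol = 1e-5)
  expect_close(uv$beta, median(ratios))

  # seeded bootstrap SE is reproducible
  m2 <- make_mes(seed = 13)
  expect_identical(mvmr_median(m2, n_boot = 50, seed = 4)$estimates$se,
                   mvmr_median(m2, n_boot = 50, seed = 4)$estimates$se)
})

test_that("all four MVMR methods agree on clean data", {
  m <- make_mes(seed = 14, n = 40)
  est <- function(x) x$estimates$beta
  ivw <- est(mvmr_ivw(m))
  eg <- est(mvmr_egger(m))
  la <- est(mvmr_lasso(m))
  me <- est(mvmr_median(m, n_boot = 0))
  se <- mvmr_ivw(m)$estimates$se
  for (other in list(eg, la, me))
    expect_true(all(abs(ivw - other) < 6 * se))
})
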