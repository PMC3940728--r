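test_that("degenerate constant counts give log intercept and zero dispersion", {
  y <- rep(4, 30)
  f <- fit_quasi_poisson(y, matrix(1, 30, 1))
  expect_equal(unname(f$beta[1]), log(4), tolerance = 1e-8)
  expect_equal(f$phi, 0, tolerance = 1e-12)
  expect_true(is.na(f$wald[1]))
})

test_that("an 8-observation fit matches glm and a direct ML oracle", {
  y <- c(0, 1, 2, 1, 3, 0, 5, 2)
  x <- c(-1, -0.5, 0, 0.5, 1, 1.5, 2, 2.5)
  X <- cbind(intercept = 1, x = x)
  f <- fit_quasi_poisson(y, X)

  # route 1: stats::glm with the quasipoisson family
  g <- glm(y ~ x, family = quasipoisson())
  expect_equal(unname(f$beta), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$phi, summary(g)$dispersion, tolerance = 1e-6)
  expect_equal(unname(f$se), unname(summary(g)$coefficients[, 2]),
               tolerance = 1e-6)

  # route 2: generic numerical maximization of the Poisson likelihood
  nll <- function(b) -sum(dpois(y, exp(X %*% b), log = TRUE))
  op <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(f$beta), op$par, tolerance = 1e-4)
  mu <- exp(X %*% op$par)
  phi_oracle <- sum((y - mu)^2 / mu) / (8 - 2)
  expect_equal(f$phi, phi_oracle, tolerance = 1e-4)
})

test_that("equidispersed Poisson data give phi near 1", {
  set.seed(20)
  n <- 5000
  x <- rnorm(n)
  y <- rpois(n, exp(0.5 + 0.2 * x))
  f <- fit_quasi_poisson(y, cbind(1, x))
  expect_gte(f$phi, 0.9)
  expect_lte(f$phi, 1.1)
  expect_equal(f$se, f$se_poisson * sqrt(f$phi), tolerance = 1e-12)
})

test_that("degenerate inputs raise informative errors", {
  expect_error(fit_quasi_poisson(rep(0, 20), matrix(1, 20, 1)),
               "all counts are zero")
  X <- cbind(intercept = 1, a = 1:20, b = 2 * (1:20))
  expect_error(fit_quasi_poisson(rpois(20, 2), X), "collinear")
  expect_error(fit_quasi_poisson(c(-1, rpois(19, 2)), matrix(1, 20, 1)),
               "non-negative")
})

test_that("allele relabeling flips the dosage effect sign exactly", {
  set.seed(21)
  n <- 400
  dos <- rbinom(n, 2, 0.3)
  y <- rpois(n, exp(0.3 + 0.2 * dos))
  X1 <- cbind(1, dos)
  X2 <- cbind(1, 2 - dos)
  f1 <- fit_quasi_poisson(y, X1)
  f2 <- fit_quasi_poisson(y, X2)
  expect_equal(f1$beta[2], -f2$beta[2], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(f1$se[2], f2$se[2], tolerance = 1e-8)
})

test_that("gwas_scan is deterministic and recovers a causal effect", {
  cfg <- two_age_cfg(n = 1500, m = 60, seed = 22)
  G <- simulate_genotypes(cfg)
  panel <- simulate_phenotype_panel(G, cfg)
  # inject a known genetic effect of 0.3 log counts per allele
  dos <- G$dosages[, 30]
  lam <- exp(log(1.5) + 0.3 * dos)
  set.seed(23)
  panel$score_17 <- as.integer(rpois(1500, lam * rgamma(1500, 3, 3)))
  t1 <- gwas_scan(G, panel, 17)
  t2 <- gwas_scan(G, panel, 17)
  expect_identical(t1, t2)
  j <- which(t1$snp_id == G$snp_map$snp_id[30])
  expect_lt(abs(t1$beta[j] - 0.3), 2.5 * t1$se[j])
  expect_lt(t1$p[j], 1e-4)
  expect_true(all(t1$p > 0 & t1$p <= 1, na.rm = TRUE))
})

test_that("genomic control matches the chi-square median oracle", {
  tab <- data.frame(snp_id = paste0("s", 1:5), chrom = "1",
                    bp = 1:5, wald = sqrt(c(1, 2, 3, 4, 5)),
                    p = 2 * pnorm(-sqrt(c(1, 2, 3, 4, 5))))
  class(tab) <- c("assoc_table", "data.frame")
  gc <- genomic_control(tab)
  # frozen oracle: median(wald^2) / qchisq(0.5, 1) = 3 / 0.4549364
  expect_equal(gc$lambda, 6.594328, tolerance = 1e-6)
  expect_equal(gc$lambda_used, gc$lambda)

  # identity when the median equals the null median
  tab2 <- tab
  tab2$wald <- sqrt(c(0.1, 0.3, qchisq(0.5, 1), 0.9, 1.5))
  gc2 <- genomic_control(tab2)
  expect_equal(gc2$lambda, 1, tolerance = 1e-12)
  expect_equal(gc2$table$p_gc,
               pchisq(tab2$wald^2, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  # deflated scans are floored at 1 unless asked otherwise
  tab3 <- tab
  tab3$wald <- sqrt(c(0.01, 0.05, 0.1, 0.2, 0.3))
  gc3 <- genomic_control(tab3)
  expect_lt(gc3$lambda, 1)
  expect_equal(gc3$lambda_used, 1)
  gc3b <- genomic_control(tab3, floor_lambda = FALSE)
  expect_equal(gc3b$lambda_used, gc3b$lambda)
})

test_that("GC correction preserves the p-value ordering", {
  set.seed(24)
  tab <- data.frame(snp_id = paste0("s", 1:200), chrom = "1",
                    bp = 1:200, wald = rnorm(200, 0, 1.4))
  tab$p <- 2 * pnorm(-abs(tab$wald))
  class(tab) <- c("assoc_table", "data.frame")
  gc <- genomic_control(tab)
  expect_gt(gc$lambda, 1)
  expect_identical(order(gc$table$p_gc), order(tab$p))
})
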