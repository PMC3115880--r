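test_that("factorial fit: cell means and pooled residual variance", {
  # identical replicates -> zero variance, coefficients equal cell values
  cm <- matrix(seq(1, 8), 1, 8, dimnames = list("G1", NULL))
  em <- make_em(cm, reps = 3, noise_sd = 0)
  fit <- fit_factorial(em)
  expect_equal(unname(fit$coef[1, ]), seq(1, 8))
  expect_equal(unname(fit$s2), 0)
  expect_equal(fit$df, 16)

  # hand-computable 2-cell toy: wt only, 3 reps per treatment
  d <- make_design(reps = 3)
  wt <- d$genotype == "wt"
  dwt <- d[wt, ]; class(dwt) <- class(d)
  y <- c(1, 2, 3, 7, 8, 12)  # control reps then ABA reps
  emwt <- expression_matrix(matrix(y, 1, 6, dimnames = list("G1", NULL)), dwt)
  fwt <- fit_factorial(emwt)
  expect_equal(unname(fwt$coef[1, ]), c(mean(y[1:3]), mean(y[4:6])))
  pooled <- (sum((y[1:3] - 2)^2) + sum((y[4:6] - 9)^2)) / 4
  expect_equal(unname(fwt$s2), pooled)

  # empty cell is an error naming the cell
  d2 <- d[!(d$genotype == "agb1" & d$treatment == "ABA"), ]
  class(d2) <- class(d)
  em2 <- expression_matrix(matrix(rnorm(nrow(d2)), 1,
                                  dimnames = list("G1", NULL)), d2)
  expect_error(fit_factorial(em2), "agb1:ABA")
})

test_that("prior estimation recovers known scaled-F hyperparameters", {
  # zero dispersion: all variances equal -> d0 = Inf, s02 = common value
  pr0 <- estimate_prior(rep(0.04, 100), 16)
  expect_equal(pr0$d0, Inf)
  expect_equal(pr0$s02, 0.04)

  # s2 ~ s02 * F(d, d0) with d0 = 4, s02 = 0.04: recovered within 20%
  set.seed(1)
  s2 <- 0.04 * rf(5000, 16, 4)
  pr <- estimate_prior(s2, 16)
  expect_lt(abs(pr$d0 - 4) / 4, 0.2)
  expect_lt(abs(pr$s02 - 0.04) / 0.04, 0.2)

  expect_error(estimate_prior(c(0.1, 0.2), c(4, 4)), "30 genes")
  expect_error(estimate_prior(rep(0, 100), 16), "zero")
})

test_that("moderated t matches limma on simulated factorial data", {
  sim <- simulate_experiment(sim_config(n_genes = 1500, seed = 8))
  em <- sim$matrix
  fit <- fit_factorial(em)
  pr <- estimate_prior(fit$s2, fit$df)

  f <- factor(paste(em$design$genotype, em$design$treatment, sep = ":"),
              levels = paste(fit$cells$genotype, fit$cells$treatment,
                             sep = ":"))
  X <- stats::model.matrix(~ 0 + f)
  lf <- limma::lmFit(em$values, X)
  cm <- matrix(0, ncol(X), 1)
  rownames(cm) <- colnames(X)
  cm["fwt:ABA", 1] <- 1; cm["fwt:control", 1] <- -1
  eb <- limma::eBayes(limma::contrasts.fit(lf, cm))

  expect_equal(pr$d0, eb$df.prior, tolerance = 1e-8)
  expect_equal(pr$s02, eb$s2.prior, tolerance = 1e-8)
  ctr <- as.numeric(fit$cells$genotype == "wt" & fit$cells$treatment == "ABA") -
         as.numeric(fit$cells$genotype == "wt" & fit$cells$treatment == "control")
  mine <- moderated_t(fit, pr, ctr)
  expect_equal(mine$t, unname(eb$t[, 1]), tolerance = 1e-10)
  expect_equal(mine$p, unname(eb$p.value[, 1]), tolerance = 1e-10)
  expect_equal(mine$log2FC, unname(eb$coefficients[, 1]), tolerance = 1e-10)
})

test_that("moderated t limit cases: d0 = 0 is the ordinary t, d0 = Inf uses s02", {
  sim <- simulate_experiment(sim_config(n_genes = 60, seed = 3))
  fit <- fit_factorial(sim$matrix)
  ctr <- as.numeric(fit$cells$genotype == "wt" & fit$cells$treatment == "ABA") -
         as.numeric(fit$cells$genotype == "wt" & fit$cells$treatment == "control")

  # independent ordinary-t oracle through lm() on the first 5 genes
  plain <- moderated_t(fit, list(d0 = 0, s02 = 1), ctr)
  f <- factor(paste(sim$matrix$design$genotype, sim$matrix$design$treatment,
                    sep = ":"),
              levels = paste(fit$cells$genotype, fit$cells$treatment, sep = ":"))
  for (i in 1:5) {
    lmfit <- lm(sim$matrix$values[i, ] ~ 0 + f)
    s2 <- sum(residuals(lmfit)^2) / lmfit$df.residual
    t_or <- (coef(lmfit)["fwt:ABA"] - coef(lmfit)["fwt:control"]) /
      sqrt(s2 * (1 / 3 + 1 / 3))
    expect_equal(plain$t[i], unname(t_or), tolerance = 1e-10)
    expect_equal(plain$p[i],
                 2 * pt(abs(t_or), lmfit$df.residual, lower.tail = FALSE),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }

  inf <- moderated_t(fit, list(d0 = Inf, s02 = 0.09), ctr)
  lfc <- as.vector(fit$coef %*% ctr)
  expect_equal(inf$t, lfc / (sqrt(sum(ctr^2 / fit$cell_n)) * 0.3))
  expect_equal(inf$p, 2 * pnorm(abs(inf$t), lower.tail = FALSE))
})

test_that("BH adjustment: hand case, edge cases, dominance property", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p))                       # adjusted >= raw
    expect_true(all(adj <= 1))
    expect_equal(adj, p.adjust(p, "BH"))             # independent reference
  }
})

test_that("call_de categorizes planted modes and honors thresholds", {
  sim <- simulate_experiment(sim_config(n_genes = 60, noise_sd = 0,
                                        fractions = c(
      aba_induced_only = 0.3, aba_repressed_only = 0.2,
      aba_gprotein_dependent = 0.2), seed = 4))
  res <- call_de(sim$matrix)
  got <- res$calls[match(sim$truth$gene, res$calls$gene), ]
  expect_equal(got$category[sim$truth$mode == "aba_induced_only"],
               rep("gprotein_independent_aba", 18))
  expect_equal(got$direction[sim$truth$mode == "aba_induced_only"],
               rep("induced", 18))
  expect_equal(got$category[sim$truth$mode == "aba_gprotein_dependent"],
               rep("gprotein_dependent_aba", 12))
  expect_equal(got$category[sim$truth$mode == "null"], rep("none", 18))

  # with d0 forced to 0 the calls equal an ordinary-t pipeline
  sim2 <- simulate_experiment(sim_config(n_genes = 300, seed = 12))
  a <- call_de(sim2$matrix, prior = list(d0 = 0, s02 = 1))
  fit <- fit_factorial(sim2$matrix)
  ctrs <- abatrans:::standard_contrasts(fit$cells)
  p_aba <- moderated_t(fit, list(d0 = 0, s02 = 1), ctrs$aba)$p
  geno <- sapply(ctrs$genotype, function(cc)
    moderated_t(fit, list(d0 = 0, s02 = 1), cc)$p)
  sig <- p_aba < 1e-4 & bh_adjust(p_aba) < 0.001
  expect_equal(a$calls$category == "gprotein_independent_aba",
               unname(sig & !apply(geno < 0.01, 1, any)))
  expect_equal(a$calls$category == "gprotein_dependent_aba",
               unname(sig & apply(geno < 0.01, 1, any)))
})
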