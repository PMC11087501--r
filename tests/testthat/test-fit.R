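# Oracle for moderated fits: per-gene weighted least squares via lm().
brute_wls <- function(expr, design, weights = NULL, col) {
  t(vapply(seq_len(nrow(expr)), function(g) {
    dat <- data.frame(y = expr[g, ], design[, -1, drop = FALSE], check.names = FALSE)
    fit <- if (is.null(weights)) lm(y ~ ., data = dat) else
      lm(y ~ ., data = dat, weights = weights[g, ])
    sm <- summary(fit)
    co <- sm$coefficients[col, ]
    c(coef = co[["Estimate"]], se = co[["Std. Error"]], t = co[["t value"]],
      sigma2 = sm$sigma^2)
  }, c(coef = 0, se = 0, t = 0, sigma2 = 0)))
}

make_fit_data <- function(seed = 9, G = 80, n = 24) {
  set.seed(seed)
  design <- cbind(`(Intercept)` = 1, grp = rep(0:1, each = n / 2),
                  cov = rnorm(n))
  expr <- matrix(rnorm(G * n, sd = rep(runif(G, 0.5, 2), n)), G, n,
                 dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:n)))
  expr[1:10, design[, "grp"] == 1] <- expr[1:10, design[, "grp"] == 1] + 1
  weights <- matrix(runif(G * n, 0.5, 2), G, n, dimnames = dimnames(expr))
  list(expr = expr, design = design, weights = weights)
}

test_that("d0 = 0 reproduces the ordinary WLS t exactly", {
  d <- make_fit_data()
  for (w in list(NULL, d$weights)) {
    fit <- fit_moderated(d$expr, d$design, "grp", weights = w, d0 = 0)
    oracle <- brute_wls(d$expr, d$design, w, "grp")
    expect_equal(fit$table$logFC, unname(oracle[, "coef"]), tolerance = 1e-10)
    expect_equal(fit$table$t, unname(oracle[, "t"]), tolerance = 1e-10)
    expect_equal(fit$df_total, nrow(d$design) - 3)
  }
})

test_that("the posterior variance follows (d0 s0^2 + d s^2) / (d0 + d) per gene", {
  d <- make_fit_data()
  fit <- fit_moderated(d$expr, d$design, "grp")
  oracle <- brute_wls(d$expr, d$design, NULL, "grp")
  s2 <- oracle[, "sigma2"]
  df <- nrow(d$design) - 3
  d0 <- fit$params$d0; s0_2 <- fit$params$s0_2
  post <- (d0 * s0_2 + df * s2) / (d0 + df)
  se_unscaled <- oracle[, "se"] / sqrt(s2)
  expect_equal(fit$table$t, unname(oracle[, "coef"] / (se_unscaled * sqrt(post))),
               tolerance = 1e-8)
  # closed-form spot check of the pooling rule itself
  expect_equal((4 * 1 + 4 * 2) / (4 + 4), 1.5)

  # d0 -> Inf pins every posterior variance at s0^2
  fit_inf <- fit_moderated(d$expr, d$design, "grp", d0 = Inf)
  expect_equal(fit_inf$table$t,
               unname(oracle[, "coef"] / (se_unscaled * sqrt(s0_2))),
               tolerance = 1e-8)
})

test_that("moderated statistics agree with the limma eBayes reference", {
  d <- make_fit_data(seed = 17)
  fit <- fit_moderated(d$expr, d$design, "grp")
  lfit <- limma::eBayes(limma::lmFit(d$expr, d$design))
  expect_equal(fit$params$s0_2, lfit$s2.prior, tolerance = 1e-8)
  expect_equal(fit$params$d0, lfit$df.prior, tolerance = 1e-6)
  expect_equal(fit$table$t, unname(lfit$t[, "grp"]), tolerance = 1e-6)
  expect_equal(fit$table$P.Value, unname(lfit$p.value[, "grp"]), tolerance = 1e-6)
})

test_that("joint moderated F is used for multi-column contrasts", {
  set.seed(23)
  n <- 30; G <- 50
  design <- cbind(`(Intercept)` = 1, a = rnorm(n), b = rnorm(n))
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(sprintf("g%d", 1:G), sprintf("s%d", 1:n)))
  expr[1, ] <- expr[1, ] + design[, "a"] * 2
  fit <- fit_moderated(expr, design, c("a", "b"))
  expect_equal(fit$stat_type, "F")
  expect_lt(fit$table$P.Value[1], 0.001)
  expect_true(all(fit$table$t >= 0))
})

test_that("BH adjustment equals the step-up definition and handles edge cases", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_equal(adjust_bh(0.37), 0.37)
  expect_warning(q <- adjust_bh(c(0.01, NA, 0.5)), "NA")
  expect_true(is.na(q[2]))
  set.seed(3)
  for (r in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_bh(p), brute_bh(p), tolerance = 1e-12)
    expect_true(all(adjust_bh(p) >= p))
  }
})

test_that("residualization centers, standardizes and removes modelled covariates", {
  set.seed(41)
  n <- 30; G <- 40
  covar <- rnorm(n)
  expr <- matrix(rnorm(G * n), G, n,
                 dimnames = list(sprintf("g%d", 1:G), sprintf("s%d", 1:n))) +
    tcrossprod(rnorm(G), covar)
  r0 <- residualize(expr, cbind(rep(1, n)))
  expect_equal(unname(rowMeans(r0)), rep(0, G), tolerance = 1e-12)
  expect_equal(unname(apply(r0, 1, sd)), rep(1, G), tolerance = 1e-12)

  r1 <- residualize(expr, cbind(1, covar))
  cors <- apply(r1, 1, cor, y = covar)
  expect_lt(max(abs(cors)), 1e-10)

  # a planted sex effect NOT in the null stays separable in the residuals
  sex <- rep(c(0, 1), each = n / 2)
  expr2 <- expr
  expr2[1, ] <- expr2[1, ] + sex * 2
  r2 <- residualize(expr2, cbind(1, covar))
  expect_lt(t.test(r2[1, sex == 1], r2[1, sex == 0])$p.value, 0.01)

  const <- rbind(expr, flat = rep(3, n))
  expect_warning(r3 <- residualize(const, cbind(rep(1, n))), "zero residual")
  expect_false("flat" %in% rownames(r3))
})

test_that("donor-clustered robust errors are roughly calibrated under the null", {
  set.seed(61)
  # two regions, repeated donors, no true region-by-group effect
  n_donor <- 30
  meta <- tibble::tibble(
    donor = rep(sprintf("d%02d", 1:n_donor), 2),
    grp = rep(rep(0:1, each = n_donor / 2), 2),
    region = rep(c("A", "B"), each = n_donor)
  )
  design <- model.matrix(~ grp * region, data = meta)
  G <- 150
  donor_fx <- matrix(rnorm(G * n_donor), G, n_donor)
  expr <- donor_fx[, match(meta$donor, sprintf("d%02d", 1:n_donor))] +
    matrix(rnorm(G * nrow(meta), sd = 0.5), G, nrow(meta))
  dimnames(expr) <- list(sprintf("g%d", 1:G), sprintf("s%d", seq_len(nrow(meta))))
  fit <- fit_moderated(expr, design, "grp:regionB", cluster = meta$donor)
  frac <- mean(fit$table$P.Value < 0.05)
  expect_gt(frac, 0.01)
  expect_lt(frac, 0.11)
  expect_equal(fit$method, "cluster-robust")
})
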