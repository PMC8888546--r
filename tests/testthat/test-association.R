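test_that("inverse-normal transform matches the Blom quantile formula", {
  got <- inverse_normal_transform(c(5, 1, 3))
  want <- qnorm((c(3, 1, 2) - 3 / 8) / (3 + 1 / 4))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got[3], 0, tolerance = 1e-12)
  expect_equal(got[1], 0.8694, tolerance = 1e-4)
  expect_equal(got[1], -got[2], tolerance = 1e-12)
})

test_that("INT is rank-preserving, centred, and propagates missing values", {
  set.seed(20)
  x <- rnorm(200)
  y <- inverse_normal_transform(x)
  expect_equal(cor(x, y, method = "spearman"), 1)
  expect_equal(sum(y), 0, tolerance = 1e-10) # antisymmetry, tie-free
  expect_lt(abs(mean(y)), 0.05)
  expect_true(sd(y) > 0.9 && sd(y) < 1.1)

  x[c(3, 17)] <- NA
  y2 <- inverse_normal_transform(x)
  expect_true(all(is.na(y2[c(3, 17)])))
  expect_equal(sum(is.na(y2)), 2)

  expect_error(inverse_normal_transform(rep(1, 5)), "degenerate")
  # ties get average ranks: equal inputs map to equal outputs
  y3 <- inverse_normal_transform(c(1, 2, 2, 3))
  expect_equal(y3[2], y3[3])
})

test_that("OLS coefficients equal the normal-equation closed form", {
  set.seed(21)
  n <- 40
  X <- cbind(1, rnorm(n), rnorm(n), rnorm(n))
  y <- rnorm(n)
  beta_closed <- solve(crossprod(X), crossprod(X, y))
  res <- fit_topic_prs(y, X[, 2], covars = data.frame(a = X[, 3], b = X[, 4]),
                       transform = FALSE)
  expect_equal(res$beta_hat, beta_closed[2], tolerance = 1e-10)
})

test_that("with orthogonal covariates the PRS slope equals the simple slope", {
  n <- 64
  prs <- rep(c(-1, 1), n / 2)
  c1 <- rep(c(-1, -1, 1, 1), n / 4)          # orthogonal to prs
  y <- rep(c(1, 2, 2, 4), n / 4)
  r_adj <- fit_topic_prs(y, prs, covars = data.frame(c1 = c1), transform = FALSE)
  r_simple <- fit_topic_prs(y, prs, transform = FALSE)
  expect_equal(r_adj$beta_hat, r_simple$beta_hat, tolerance = 1e-8)
})

test_that("collinear designs fail loudly with the offending column named", {
  set.seed(22)
  n <- 30
  x <- rnorm(n)
  expect_error(
    fit_topic_prs(rnorm(n), x, covars = data.frame(dup = 2 * x),
                  transform = FALSE),
    "collinear.*dup")
})

test_that("adding one predictor: nested-model F equals the squared t", {
  set.seed(23)
  for (i in 1:5) {
    n <- 80
    full <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    y <- 0.3 * full$a + 0.2 * full$c + rnorm(n)
    cmp <- compare_models(y, full, full[c("a", "b")])
    fit <- lm(y ~ ., data = data.frame(y = y, full))
    tc <- summary(fit)$coefficients["c", ]
    expect_equal(cmp$F, unname(tc["t value"]^2), tolerance = 1e-10)
    expect_equal(cmp$p_anova, unname(tc["Pr(>|t|)"]), tolerance = 1e-10)
    # and agreement with R's own nested-model ANOVA
    a <- anova(lm(y ~ a + b, data = full), fit)
    expect_equal(cmp$F, a$F[2], tolerance = 1e-10)
    expect_equal(cmp$p_anova, a$`Pr(>F)`[2], tolerance = 1e-10)
  }
})

test_that("degenerate or non-nested model comparisons are rejected", {
  y <- rnorm(20)
  X <- data.frame(a = rnorm(20), b = rnorm(20))
  expect_error(compare_models(y, X, X), "strict sub-model")
  expect_error(compare_models(y, X[, "a", drop = FALSE],
                              data.frame(z = rnorm(20))), "not nested")
})

test_that("comparison against the intercept-only model works", {
  set.seed(24)
  y <- rnorm(50)
  X <- data.frame(a = rnorm(50))
  cmp <- compare_models(y, X, NULL)
  fit <- lm(y ~ a, data = X)
  expect_equal(cmp$F, unname(summary(fit)$fstatistic["value"]),
               tolerance = 1e-10)
})

test_that("variance decomposition matches the drop-one refit oracle", {
  set.seed(25)
  for (i in 1:10) {
    n <- 100
    X <- as.data.frame(matrix(rnorm(n * 4), n, 4))
    names(X) <- paste0("x", 1:4)
    y <- as.numeric(as.matrix(X) %*% c(0.5, -0.3, 0, 0.2)) + rnorm(n)
    vd <- variance_decomposition(y, X)
    want <- oracle_sr2(y, X)
    expect_equal(setNames(vd$sr2, vd$predictor), want, tolerance = 1e-10)
    expect_equal(vd$pct_variance, 100 * vd$sr2)
  }
})

test_that("orthogonal standardized predictors decompose R2 additively", {
  n <- 32
  x1 <- rep(c(-1, 1), n / 2)
  x2 <- rep(c(-1, -1, 1, 1), n / 4)
  x3 <- rep(c(-1, -1, -1, -1, 1, 1, 1, 1), n / 8)
  set.seed(31)
  y <- 1 * x1 + 0.5 * x2 + 0.25 * x3 + rnorm(n, sd = 0.5)
  X <- data.frame(x1 = x1, x2 = x2, x3 = x3)
  vd <- variance_decomposition(y, X)
  expect_equal(sum(vd$sr2), attr(vd, "r2_full"), tolerance = 1e-8)
  expect_equal(vd$sr2, vapply(X, function(x) cor(x, y)^2, numeric(1)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("duplicated predictors suppress each other's unique contribution", {
  set.seed(26)
  n <- 60
  x <- rnorm(n)
  y <- x + rnorm(n, sd = 0.2)
  X <- data.frame(a = x, b = x + rnorm(n, sd = 1e-6))
  vd <- variance_decomposition(y, X)
  expect_true(all(vd$sr2 < 0.01))
  expect_gt(attr(vd, "r2_full"), 0.9)
})

test_that("association scan covers the full grid and honours exclusions", {
  set.seed(27)
  n <- 60
  theta <- matrix(rgamma(n * 3, 1), n, 3)
  theta <- theta / rowSums(theta)
  rownames(theta) <- paste0("s", 1:n)
  prof <- function(trait) {
    sc <- matrix(rnorm(n * 7), n, 7,
                 dimnames = list(paste0("s", 1:n),
                                 names(prs_config()$tranches)))
    structure(list(scores = sc, trait = trait), class = "prs_profile")
  }
  covars <- data.frame(age = runif(n, 4, 18), sex = rbinom(n, 1, 0.5),
                       row.names = paste0("s", 1:n))
  sc <- association_scan(theta, list(asd = prof("asd"), pain = prof("pain")),
                         covars, exclude_topics = 2L)
  expect_equal(nrow(sc$table), 2 * 2 * 7)
  expect_false(any(sc$table$topic == 2))
  expect_true(all(c("p_bonf", "p_bh", "sr2", "partial_r2") %in%
                    names(sc$table)))
  expect_equal(dim(sc$neglog10p$asd), c(2, 7))
  expect_true(all(sc$table$p > 0 & sc$table$p <= 1))
  expect_true(all(sc$table$sr2 >= 0 & sc$table$sr2 <= 1))

  bad <- prof("bad")
  rownames(bad$scores)[1] <- "zz"
  expect_error(association_scan(theta, list(bad = bad), covars),
               "subject-id mismatch.*zz")
})
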