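test_that("probit MLE matches an independent likelihood maximisation", {
  set.seed(31)
  for (trial in 1:3) {
    x <- matrix(rnorm(20), ncol = 1)
    eta <- -0.3 + 1.2 * x[, 1]
    y <- rbinom(20, 1, pnorm(eta))
    if (length(unique(y)) < 2) next
    fit <- fit_probit(x, y)
    if (fit$ridge) next # separation handled by its own test below
    # independent oracle: Nelder-Mead on the probit log-likelihood
    nll <- function(b) {
      p <- pnorm(b[1] + b[2] * x[, 1])
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      -sum(y * log(p) + (1 - y) * log(1 - p))
    }
    oracle <- optim(c(0, 0), nll, method = "Nelder-Mead",
                    control = list(reltol = 1e-14, maxit = 5000))$par
    expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
  }
})

test_that("separated data trigger the ridge fallback yet rank perfectly", {
  x <- matrix(c(-3, -2, -1.5, 1.5, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fit_probit(x, y)
  expect_true(fit$ridge)
  p <- predict(fit, x)
  expect_equal(roc_metrics(p, y)$auc, 1)
})

test_that("an all-zero predictor collapses to class-prevalence probabilities", {
  set.seed(5)
  y <- rep(c(0, 1, 1, 1), 5)
  x <- matrix(0, 20, 1)
  fit <- fit_probit(x, y)
  p <- predict(fit, matrix(0, 1, 1))
  expect_equal(as.numeric(p), mean(y), tolerance = 1e-2)
  expect_lt(abs(fit$beta[2]), 1e-2)
  expect_error(fit_probit(x, rep(1, 20)), "both classes")
})

test_that("AUC equals exhaustive concordant-pair counting with ties at one half", {
  expect_equal(roc_metrics(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0))$auc, 0.75)
  m <- roc_metrics(c(0, 1, 1, 0, 0, 1), c(0, 1, 1, 0, 0, 1))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  set.seed(8)
  for (trial in 1:20) {
    n <- sample(8:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 2) # induces ties
    auc_pkg <- roc_metrics(p, y)$auc
    pos <- p[y == 1]
    neg <- p[y == 0]
    conc <- 0
    for (a in pos) for (b in neg) {
      conc <- conc + (a > b) + 0.5 * (a == b)
    }
    expect_equal(auc_pkg, conc / (length(pos) * length(neg)),
                 tolerance = 1e-12)
    # label reversal flips the AUC
    expect_equal(roc_metrics(p, 1 - y)$auc, 1 - auc_pkg, tolerance = 1e-12)
  }

  const <- roc_metrics(rep(0.4, 10), c(rep(0, 5), rep(1, 5)))
  expect_equal(const$auc, 0.5)
  expect_true(const$degenerate)
})

test_that("DeLong intervals bracket the point estimate", {
  set.seed(12)
  y <- rbinom(40, 1, 0.5)
  y[1:2] <- c(0, 1)
  p <- plogis(rnorm(40) + y)
  m <- roc_metrics(p, y)
  expect_lte(m$ci_low, m$auc)
  expect_gte(m$ci_high, m$auc)
  expect_gte(m$ci_low, 0)
  expect_lte(m$ci_high, 1)
  expect_gte(m$p_value, 0)
})

test_that("LOOCV separates well-separated signature cohorts and not null ones", {
  sep <- simulated_signature_cohort(
    10, means = c(A = 0.3, B = 0.7), sds = c(A = 0.08, B = 0.08), seed = 1
  )
  res <- loocv_pairwise(sep, "A", "B")
  expect_gte(res$summary$auc, 0.9)
  expect_equal(nrow(res$folds), 20)
  expect_true(all(res$folds$prob >= 0 & res$folds$prob <= 1))

  null <- simulated_signature_cohort(
    10, means = c(A = 0.5, B = 0.5), sds = c(A = 0.1, B = 0.1), seed = 2
  )
  res_null <- loocv_pairwise(null, "A", "B")
  expect_lt(res_null$summary$auc, 0.85)

  expect_error(
    loocv_pairwise(simulated_signature_cohort(
      2, means = c(A = 0.4, B = 0.6), sds = c(A = 0.1, B = 0.1), seed = 3
    ), "A", "B"),
    "at least 3"
  )
})

test_that("each LOOCV fold trains without the held-out sample (no leakage)", {
  sigs <- simulated_signature_cohort(
    5, means = c(A = 0.35, B = 0.65), sds = c(A = 0.1, B = 0.1), seed = 4
  )
  res <- loocv_pairwise(sigs, "A", "B")
  y <- as.numeric(sigs$meta$group == "B")
  t_grid <- sigs$t
  psis <- t(apply(sigs$f, 1, to_srdf, t_grid = t_grid))
  for (i in c(1, 6)) {
    train <- setdiff(seq_len(nrow(psis)), i)
    model <- tangent_pca(psis[train, , drop = FALSE], t_grid)
    k_use <- max(1L, min(model$k, length(train) - 3L))
    fit <- fit_probit(model$scores[, seq_len(k_use), drop = FALSE], y[train])
    manual <- predict(fit,
                      matrix(project_scores(sigs$f[i, ], model)[seq_len(k_use)],
                             nrow = 1))
    expect_equal(res$folds$prob[i], as.numeric(manual), tolerance = 1e-10)
  }
})

test_that("all-pairs tables enumerate unordered pairs with flags and corrections", {
  sigs <- simulated_signature_cohort(
    6, means = c(A = 0.25, B = 0.5, C = 0.75),
    sds = c(A = 0.07, B = 0.07, C = 0.07), seed = 5
  )
  res <- run_all_pairs(sigs)
  expect_equal(nrow(res), 3)
  expect_true(all(res$group_1 < res$group_2))
  expect_equal(res$significant, res$auc >= 0.75)
  expect_true(all(res$p_adj >= res$p_value - 1e-15, na.rm = TRUE))
  # two groups: a single row, Bonferroni divisor one
  two <- run_all_pairs(simulated_signature_cohort(
    6, means = c(A = 0.3, B = 0.7), sds = c(A = 0.08, B = 0.08), seed = 6
  ))
  expect_equal(nrow(two), 1)
  expect_equal(two$p_adj, pmin(1, two$p_value))
})

test_that("the Morisita-Horn baseline classifier uses the same machinery on a scalar", {
  set.seed(44)
  mh_table <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:24),
    image_id = sprintf("i%02d", 1:24),
    group = rep(c("A", "B"), each = 12),
    mh = c(rbeta(12, 8, 2), rbeta(12, 2, 8))
  )
  res <- mh_pairwise(mh_table)
  expect_equal(nrow(res), 1)
  expect_gte(res$auc, 0.9)

  null_tab <- dplyr::mutate(mh_table, mh = rbeta(24, 4, 4))
  res_null <- mh_pairwise(null_tab)
  expect_lt(res_null$auc, 0.85)
})
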