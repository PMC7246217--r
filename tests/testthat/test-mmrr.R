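test_that("unfold follows the stated pair order and round-trips", {
  m3 <- rand_sym(3)
  expect_length(unfold(m3), 3)
  m4 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  v <- 1:6
  idx <- 1
  for (i in 2:4) for (j in seq_len(i - 1)) {
    m4[i, j] <- m4[j, i] <- v[idx]; idx <- idx + 1
  }
  expect_equal(as.numeric(unfold(m4)), 1:6)  # (2,1),(3,1),(3,2),(4,1),(4,2),(4,3)
  set.seed(1)
  m <- rand_sym(7)
  expect_equal(fold_pairs(unfold(m), rownames(m)), m)
})

test_that("the model enumeration yields 4 + 9 per barrier variable", {
  b7 <- c("b1", "b2", "b3", "b1+b2", "b1+b3", "b2+b3", "b1+b2+b3")
  expect_length(build_model_set(TRUE, TRUE, b7), 67)
  expect_length(build_model_set(TRUE, TRUE, character()), 4)
  expect_length(build_model_set(TRUE, TRUE, "b1"), 13)
  expect_error(build_model_set(TRUE, TRUE, c("b1", "b1")), "duplicate")
  expect_error(build_model_set(FALSE, FALSE, character()), "at least one")
  # each spec respects the interaction-parent rule
  expect_error(mmrr_spec(b_geo = TRUE), "requires")
  labels <- vapply(build_model_set(TRUE, TRUE, b7), function(s) s$label, character(1))
  expect_false(anyDuplicated(labels) > 0)
})

test_that("MMRR coefficients equal the normal-equation OLS solution", {
  set.seed(21)
  S <- 5
  Y <- rand_sym(S); G <- rand_sym(S); E <- rand_sym(S); B <- rand_sym(S)
  B[] <- (B > 0) * 1; B <- B * t(B); diag(B) <- 0
  dimnames(B) <- dimnames(Y)
  spec <- mmrr_spec(geo = TRUE, env = TRUE, barrier = "b1", b_geo = TRUE)
  fit <- mmrr_fit(Y, list(geo = G, env = E, b1 = B), spec, nperm = 9, seed = 1)
  z <- function(v) (v - mean(v)) / stats::sd(v)
  X <- cbind(1, unfold(B), z(unfold(G)), z(unfold(E)), unfold(B) * z(unfold(G)))
  beta <- solve(t(X) %*% X, t(X) %*% unfold(Y))
  expect_equal(fit$coefficients$estimate, as.numeric(beta), tolerance = 1e-10)
  # R^2 against lm on the unfolded vectors (same intercept-bearing design)
  lmfit <- lm(as.numeric(unfold(Y)) ~ X[, -1])
  expect_equal(fit$r_squared, summary(lmfit)$r.squared, tolerance = 1e-10)
})

test_that("a perfectly explanatory predictor gets slope 1 and the minimal p-value", {
  set.seed(4)
  G <- rand_sym(6)
  Gz <- (G - mean(unfold(G))) / stats::sd(unfold(G))
  diag(Gz) <- 0
  fit <- mmrr_fit(Gz, list(geo = Gz), mmrr_spec(geo = TRUE), nperm = 99, seed = 2)
  expect_equal(fit$coefficients$estimate[2], 1, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$coefficients$p_value[2], 1 / 100)
})

test_that("permutation runs are bit-reproducible under a fixed seed", {
  set.seed(11)
  Y <- rand_sym(6); G <- rand_sym(6)
  f1 <- mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 199, seed = 42)
  f2 <- mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 199, seed = 42)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$f_p_value, f2$f_p_value)
})

test_that("singular designs are flagged inestimable and excluded from ranking", {
  set.seed(2)
  Y <- rand_sym(5); G <- rand_sym(5)
  Bconst <- matrix(0, 5, 5, dimnames = dimnames(Y))  # constant barrier
  bad <- mmrr_fit(Y, list(geo = G, b1 = Bconst), mmrr_spec(barrier = "b1"), nperm = 9)
  expect_s3_class(bad, "mmrr_inestimable")
  good <- mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 9)
  tab <- rank_models(list(bad, good))
  expect_equal(nrow(tab), 1)
  expect_equal(attr(tab, "dropped"), "b1")
})

test_that("AICc follows the closed form and its identity with AIC", {
  expect_equal(aicc((10 - 2 * 3) / -2, k = 3, n = 20), 11.5)  # AIC 10, K 3, n 20
  expect_error(aicc(0, k = 19, n = 20), "insufficient")
  set.seed(6)
  Y <- rand_sym(8); G <- rand_sym(8)
  fit <- mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 9)
  aic <- -2 * fit$loglik + 2 * fit$k
  expect_equal(fit$aicc - aic, 2 * fit$k * (fit$k + 1) / (fit$n - fit$k - 1),
               tolerance = 1e-12)
  expect_gte(fit$aicc, aic)
  expect_equal(fit$n, 8 * 7 / 2)
})

test_that("Akaike weights normalize, rank consistently, and give printed evidence ratios", {
  mkfit <- function(label, loglik, k = 3, n = 28) {
    structure(list(spec = list(label = label), loglik = loglik, k = k, n = n,
                   r_squared = NA_real_,
                   aicc = aicc(loglik, k = k, n = n)), class = "mmrr_fit")
  }
  single <- rank_models(list(mkfit("m1", -10)))
  expect_equal(single$weight, 1)
  pair <- rank_models(list(mkfit("m1", -10), mkfit("m2", -10)))
  expect_equal(pair$weight, c(0.5, 0.5))
  expect_true(isTRUE(attr(pair, "ties")))
  # weights 0.268 vs 0.179 correspond to delta-AICc 2*log(w1/w2); the
  # evidence ratio of the best over the runner-up is then ~1.497
  dAICc <- 2 * log(0.268 / 0.179)
  two <- rank_models(list(mkfit("best", 0), mkfit("runner", -dAICc / 2)))
  expect_equal(two$evidence_ratio[2], 0.268 / 0.179, tolerance = 1e-10)
  expect_equal(two$evidence_ratio[2], 1.5, tolerance = 0.01)
  set.seed(13)
  lls <- rnorm(10, -20, 3)
  tab <- rank_models(lapply(seq_along(lls), function(i) mkfit(paste0("m", i), lls[i])))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(tab$aicc))
  expect_equal(tab$delta_aicc[1], 0)
})

test_that("adding a pure-noise predictor never lowers R2 and raises AICc in median", {
  set.seed(77)
  d_r2 <- d_aicc <- numeric(200)
  for (i in 1:200) {
    Y <- rand_sym(8); G <- rand_sym(8); E <- rand_sym(8)
    f1 <- mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 1, seed = i)
    f2 <- mmrr_fit(Y, list(geo = G, env = E), mmrr_spec(geo = TRUE, env = TRUE),
                   nperm = 1, seed = i)
    d_r2[i] <- f2$r_squared - f1$r_squared
    d_aicc[i] <- f2$aicc - f1$aicc
  }
  expect_true(all(d_r2 >= -1e-12))
  expect_gt(median(d_aicc), 0)
})

test_that("group means recover a built-in barrier shift within 2 SE", {
  set.seed(55)
  S <- 8
  side <- rep(c(0, 1), each = 4)
  B <- outer(side, side, function(a, b) (a != b) * 1)
  labels <- sprintf("S%d", 1:S)
  dimnames(B) <- list(labels, labels)
  G <- rand_sym(S)
  ok <- 0
  for (rep in 1:20) {
    Y <- 0.02 + 0.05 * B + rand_sym(S) * 0.01
    diag(Y) <- 0
    fit <- mmrr_fit(Y, list(geo = G, b1 = B),
                    mmrr_spec(geo = TRUE, barrier = "b1"), nperm = 9, seed = rep)
    gm <- group_means(fit)
    diffm <- gm$mean[gm$level == 1] - gm$mean[gm$level == 0]
    se <- sqrt(sum(gm$se^2))
    if (abs(diffm - 0.05) < 2 * se) ok <- ok + 1
  }
  expect_gte(ok, 17)  # ~95% coverage, allow sampling slack
  # barrier-only model: predicted level means equal observed level means of Y
  Y <- 0.2 + 0.3 * B; diag(Y) <- 0
  fit2 <- mmrr_fit(Y, list(b1 = B), mmrr_spec(barrier = "b1"), nperm = 9)
  gm2 <- group_means(fit2)
  expect_equal(gm2$mean, c(0.2, 0.5), tolerance = 1e-10)
  expect_error(group_means(mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 9)),
               "no barrier")
})

test_that("tidy and glance expose the fit in broom form", {
  set.seed(3)
  Y <- rand_sym(6); G <- rand_sym(6)
  fit <- mmrr_fit(Y, list(geo = G), mmrr_spec(geo = TRUE), nperm = 19)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("term", "estimate", "std_error", "statistic", "p_value"))
  gl <- glance(fit)
  expect_equal(gl$n, 15)
  expect_equal(gl$model, "geo")
})
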