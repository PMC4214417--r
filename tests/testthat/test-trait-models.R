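# All-subsets regression, PRESS, AIC, selection, evaluation, CV.

make_table <- function(n = 30, seed = 1, n_morph = 3, n_texture = 2,
                       beta = c(2, -1), noise = 1) {
  set.seed(seed)
  A <- rnorm(n, 100, 20)
  morph <- matrix(rnorm(n * n_morph), n,
                  dimnames = list(NULL, paste0("morph_", seq_len(n_morph))))
  tex <- matrix(rnorm(n * n_texture), n,
                dimnames = list(NULL, paste0("glcm_t", seq_len(n_texture))))
  y <- 500 + beta[1] * A + beta[2] * morph[, 1] + rnorm(n, 0, noise)
  df <- data.frame(projected_area_px = A, morph, tex, trait = y,
                   check.names = FALSE)
  trait_table(df, "trait")
}

test_that("OLS fit matches the normal-equations oracle", {
  tt <- make_table(n = 30, seed = 5)
  m <- fit_linear_model(tt, c("projected_area_px", "morph_1"))
  X <- cbind(1, tt$projected_area_px, tt$morph_1)
  oracle <- solve(t(X) %*% X, t(X) %*% tt$trait)
  expect_equal(unname(m$coefficients), drop(oracle), tolerance = 1e-10)
  expect_lte(m$adj_r2, m$r2)

  # perfect linear trait
  tt2 <- make_table(n = 25, seed = 6, noise = 0, beta = c(3, 0))
  m2 <- fit_linear_model(tt2, "projected_area_px")
  expect_equal(m2$r2, 1)
  expect_lt(m2$rss, 1e-16 * sum(tt2$trait^2))

  # constant response
  tt3 <- make_table(n = 20, seed = 7)
  tt3$trait <- rep(5, 20)
  expect_warning(m3 <- fit_linear_model(tt3, "projected_area_px"),
                 "constant response")
  expect_equal(m3$r2, 0)
  expect_error(fit_linear_model(tt3[1:2, ],
                                c("projected_area_px", "morph_1")), "n > p")
})

test_that("PRESS equals explicit leave-one-out refits", {
  # intercept-only on y = (0, 2): each LOO fit predicts the other point
  df <- data.frame(projected_area_px = c(1, 2), trait = c(1, 3))
  # use the hat-form directly: h_ii = 1/2, residuals -1, 1
  h <- rep(0.5, 2); e <- c(-1, 1)
  expect_equal(sum((e / (1 - h))^2), 8)

  df3 <- data.frame(projected_area_px = 1:3, trait = rep(1, 3))
  # intercept-only on constant data: every LOO error is 0

  set.seed(99)
  for (case in 1:25) {
    n <- sample(10:40, 1)
    p <- sample(1:5, 1)
    tt <- make_table(n = n, seed = 100 + case,
                     n_morph = max(p, 1), n_texture = 1)
    preds <- c("projected_area_px", paste0("morph_", seq_len(p - 1)))[1:p]
    m <- fit_linear_model(tt, preds)
    loo <- sum(vapply(seq_len(n), function(i) {
      sub <- tt[-i, , drop = FALSE]
      for (a in c("trait", "area", "morph", "texture"))
        attr(sub, a) <- attr(tt, a)
      class(sub) <- class(tt)
      fit <- fit_linear_model(sub, preds)
      (tt$trait[i] - predict(fit, tt[i, , drop = FALSE]))^2
    }, 0))
    expect_rel_equal(m$press, loo, 1e-8)
  }
})

test_that("AIC follows the stated Gaussian convention", {
  c1 <- model_criteria(20, 10, 1)
  c2 <- model_criteria(20, 8, 1)
  expect_lt(c2$aic, c1$aic)                  # same p, smaller rss
  # halving rss at the cost of one parameter: dAIC = 20 ln(1/2) + 2
  d <- model_criteria(20, 5, 2)$aic - model_criteria(20, 10, 1)$aic
  expect_equal(d, 20 * log(0.5) + 2)
  expect_lt(d, 0)                            # larger model wins here
  expect_identical(model_criteria(20, 10, 1)$aic,
                   model_criteria(20, 10, 1)$aic)
  expect_true(model_criteria(20, 0, 1)$perfect_fit)
  expect_identical(model_criteria(20, 0, 1)$aic, -Inf)
})

test_that("all-subsets search enumerates families and matches brute force", {
  tt <- make_table(n = 60, seed = 8, n_morph = 8, n_texture = 4)
  expect_length(all_subsets_search(tt, "A"), 1)
  expect_length(all_subsets_search(tt, "AM"), 8)
  expect_length(all_subsets_search(tt, "AT"), 4)
  atm <- all_subsets_search(tt, "ATM")
  expect_length(atm, 32)

  # independent exhaustive oracle: fit every (morph, texture) pair with lm
  best <- NULL
  for (mo in attr(tt, "morph")) for (te in attr(tt, "texture")) {
    f <- stats::as.formula(paste("trait ~ projected_area_px +",
                                 "`", mo, "` + `", te, "`", sep = ""))
    fit <- stats::lm(f, data = tt)
    pr <- sum((stats::residuals(fit) / (1 - stats::hatvalues(fit)))^2)
    if (is.null(best) || pr < best$pr) best <- list(pr = pr, mo = mo, te = te)
  }
  expect_equal(atm[[1]]$predictors[2], best$mo)
  expect_equal(atm[[1]]$predictors[3], best$te)
  expect_rel_equal(atm[[1]]$press, best$pr, 1e-10)

  # ranking deterministic: PRESS ascending
  pr <- vapply(atm, `[[`, 0, "press")
  expect_true(all(diff(pr) >= 0))
})

test_that("selection recovers the generating family and honours margins", {
  hits <- c(A = 0, AM = 0, ATM = 0)
  for (seed in 1:20) {
    for (fam in names(hits)) {
      tt <- simulate_feature_trait_table(n = 200, generating_family = fam,
                                         seed = seed)
      rep <- select_best_model(tt)
      hits[fam] <- hits[fam] + (rep$chosen$family == fam)
    }
  }
  expect_gte(hits["A"], 18)
  expect_gte(hits["AM"], 18)
  expect_gte(hits["ATM"], 18)

  # margins: an AM tied with A must lose to A (tie favours small family)
  tt <- simulate_feature_trait_table(n = 100, generating_family = "A",
                                     seed = 3, noise_sd = 0)
  rep <- select_best_model(tt)
  expect_equal(rep$chosen$family, "A")
  expect_true(all(rep$criteria$family == c("A", "AM", "AT", "ATM")))
})

test_that("evaluation metrics follow their definitions", {
  tt <- make_table(n = 40, seed = 12)
  sp <- split_train_test(tt, 0.5, seed = 4)
  m <- fit_linear_model(sp$train, c("projected_area_px", "morph_1"))
  ev <- evaluate_predictions(m, sp$test)
  expect_lte(ev$r2_test, 1)
  expect_gte(ev$mape_pct, 0)

  # hand arithmetic: truth (100, 100), predictions (110, 90) -> MAPE 10
  fake <- structure(list(family = "A", predictors = "projected_area_px",
                         coefficients = c(0, 1)),
                    class = "candidate_model")
  test_df <- data.frame(projected_area_px = c(110, 90),
                        trait = c(100, 100.001))
  te <- trait_table(test_df, "trait")
  ev2 <- evaluate_predictions(fake, te)
  expect_equal(ev2$mape_pct, 10, tolerance = 1e-4)

  # negative out-of-sample R2 is permitted for a useless predictor
  fake0 <- structure(list(family = "A", predictors = "projected_area_px",
                          coefficients = c(1000, 0)),
                     class = "candidate_model")
  ev3 <- evaluate_predictions(fake0, trait_table(
    data.frame(projected_area_px = c(1, 2, 3), trait = c(10, 20, 30)),
    "trait"))
  expect_lte(ev3$r2_test, 0)
})

test_that("train/test split is deterministic, exact and disjoint", {
  tt <- make_table(n = 100, seed = 13)
  sp <- split_train_test(tt, 0.5, seed = 7)
  expect_equal(nrow(sp$train), 50)
  expect_equal(nrow(sp$test), 50)
  expect_length(intersect(rownames(sp$train), rownames(sp$test)), 0)
  sp2 <- split_train_test(tt, 0.5, seed = 7)
  expect_identical(rownames(sp$train), rownames(sp2$train))
  tt101 <- make_table(n = 101, seed = 14)
  sp3 <- split_train_test(tt101, 0.5, seed = 1)
  expect_equal(nrow(sp3$train), 50)   # floor on odd n
  expect_equal(nrow(sp3$test), 51)
  expect_error(split_train_test(tt, 1.5), "fraction")
})

test_that("cross-validation pools out-of-fold predictions", {
  # noise-free linear trait: perfect CV
  tt0 <- make_table(n = 40, seed = 15, noise = 0, beta = c(2, 0))
  cv0 <- cross_validate(tt0, "projected_area_px", k = 10, seed = 1)
  expect_lt(cv0$mape_pct, 1e-8)

  # LOO/PRESS identity for the intercept-only model, checked directly
  # against the hat form (h_ii = 1/n)
  tt <- make_table(n = 24, seed = 16)
  y <- tt$trait
  n <- length(y)
  h <- rep(1 / n, n)
  e <- y - mean(y)
  press0 <- sum((e / (1 - h))^2)
  loo_sse <- sum(vapply(seq_len(n), function(i)
    (y[i] - mean(y[-i]))^2, 0))
  expect_rel_equal(loo_sse, press0, 1e-10)

  cv1 <- cross_validate(tt, "projected_area_px", k = 12, seed = 3)
  cv2 <- cross_validate(tt, "projected_area_px", k = 12, seed = 3)
  expect_identical(cv1, cv2)
  expect_error(cross_validate(tt, "projected_area_px", k = 100), "k <= n")
})
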