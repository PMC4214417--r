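# Feature-grouped all-subsets regression for biomass and leaf-area
# prediction.
#
# Candidate families: A (projected area only), AM (area + one
# morphological feature), AT (area + one texture feature), ATM (area + one
# of each).  Candidates are scored by PRESS (primary), AIC and adjusted
# R-squared; a larger family replaces a smaller one only when it is
# "noticeably better" under configurable margins.

#' Build a trait table
#'
#' A data frame of feature columns plus one measured trait, with the
#' feature grouping (which columns are morphological, which are texture)
#' attached as attributes.
#'
#' @param df Data frame containing `area_col`, the feature columns and
#'   `trait_col`.
#' @param trait_col Name of the measured-trait column (must be positive:
#'   MAPE needs positive truth).
#' @param area_col Name of the projected-area column.
#' @param morph_cols,texture_cols Feature grouping; defaults infer texture
#'   columns from the `glcm_` prefix and treat the remaining numeric
#'   feature columns as morphological.
#' @param stage Optional stage label.
#' @return `trait_table` (a classed data frame).
#' @export
trait_table <- function(df, trait_col, area_col = "projected_area_px",
                        morph_cols = NULL, texture_cols = NULL,
                        stage = "unknown") {
  stopifnot(trait_col %in% names(df), area_col %in% names(df))
  if (is.null(texture_cols))
    texture_cols <- grep("^glcm_", names(df), value = TRUE)
  if (is.null(morph_cols))
    morph_cols <- setdiff(names(df)[vapply(df, is.numeric, TRUE)],
                          c(trait_col, area_col, texture_cols, "n_views"))
  df <- df[stats::complete.cases(df[c(area_col, morph_cols, texture_cols,
                                      trait_col)]), , drop = FALSE]
  if (any(df[[trait_col]] <= 0))
    stop("measured trait must be positive for all retained rows")
  structure(df, trait = trait_col, area = area_col, morph = morph_cols,
            texture = texture_cols, stage = stage,
            class = c("trait_table", "data.frame"))
}

#' Fit an OLS candidate model
#'
#' Ordinary least squares of the trait on the named predictors (intercept
#' always included), with `r2`, `adj_r2`, the Gaussian-likelihood AIC
#' (`n log(rss/n) + 2 (p + 2)`) and the leverage-form PRESS attached.
#'
#' @param table A [trait_table()].
#' @param predictors Character vector of predictor column names.
#' @param family Optional family tag stored on the result.
#' @return `candidate_model` list.
#' @export
fit_linear_model <- function(table, predictors, family = NA_character_) {
  y <- table[[attr(table, "trait")]]
  n <- length(y)
  p <- length(predictors)
  if (n <= p + 1L) stop("need n > p + 1 observations")
  X <- cbind(`(Intercept)` = 1, as.matrix(table[predictors]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("design matrix is rank deficient")
  coef <- qr.coef(qrX, y)
  fitted <- drop(X %*% coef)
  res <- y - fitted
  rss <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    warning("constant response: r2 set to 0")
    r2 <- 0; adj <- 0
  } else {
    r2 <- 1 - rss / sst
    adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  }
  h <- rowSums(qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]^2)
  structure(list(family = family, predictors = predictors,
                 coefficients = coef, n = n, p = p, rss = rss, r2 = r2,
                 adj_r2 = adj, aic = ols_aic(n, rss, p),
                 leverages = h, residuals = res, fitted = fitted,
                 press = press_from_fit(res, h)),
            class = "candidate_model")
}

press_from_fit <- function(res, h) {
  if (any(h >= 1 - 1e-12))
    stop("leverage of 1: a point is interpolated exactly, PRESS undefined")
  sum((res / (1 - h))^2)
}

#' PRESS statistic of a fitted candidate
#'
#' Leverage form `sum((e_i / (1 - h_ii))^2)`, algebraically equal to the
#' sum of squared leave-one-out prediction errors.
#'
#' @param model A `candidate_model`.
#' @return PRESS value.
#' @export
press_statistic <- function(model) {
  press_from_fit(model$residuals, model$leverages)
}

ols_aic <- function(n, rss, p) {
  if (rss <= 0) return(-Inf)          # perfect-fit sentinel
  n * log(rss / n) + 2 * (p + 2)
}

#' AIC and adjusted R-squared from summary statistics
#'
#' The Gaussian OLS convention `AIC = n log(rss/n) + 2 (p + 2)` counting
#' `p` slopes, the intercept and the error variance as parameters; the
#' additive constant is irrelevant to ranking.
#'
#' @param n Observations.
#' @param rss Residual sum of squares.
#' @param p Number of slope parameters.
#' @return List with `aic` (`-Inf` with `perfect_fit = TRUE` when
#'   `rss == 0`).
#' @export
model_criteria <- function(n, rss, p) {
  if (n <= p + 2L) stop("need n > p + 2")
  list(aic = ols_aic(n, rss, p), perfect_fit = rss <= 0)
}

#' Predict from a candidate model
#' @param object A `candidate_model`.
#' @param newdata Data frame containing the predictor columns.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.candidate_model <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata[object$predictors]))
  drop(X %*% object$coefficients)
}

#' Enumerate and rank all candidates of a model family
#'
#' Family A has the single area-only model; AM one candidate per
#' morphological descriptor; AT one per texture descriptor; ATM one per
#' (morph, texture) pair.  Ranked by PRESS ascending, ties broken by AIC
#' then lexicographic predictor names.
#'
#' @param table A [trait_table()].
#' @param family `"A"`, `"AM"`, `"AT"` or `"ATM"`.
#' @return List of `candidate_model`s, best first.
#' @export
all_subsets_search <- function(table, family = c("A", "AM", "AT", "ATM")) {
  family <- match.arg(family)
  area <- attr(table, "area")
  morph <- attr(table, "morph")
  tex <- attr(table, "texture")
  sets <- switch(family,
    A = list(area),
    AM = { if (length(morph) == 0) stop("empty morphological pool")
           lapply(morph, function(m) c(area, m)) },
    AT = { if (length(tex) == 0) stop("empty texture pool")
           lapply(tex, function(t) c(area, t)) },
    ATM = { if (length(morph) == 0 || length(tex) == 0)
              stop("empty descriptor pool")
            unlist(lapply(morph, function(m)
              lapply(tex, function(t) c(area, m, t))), recursive = FALSE) })
  fits <- lapply(sets, function(s) fit_linear_model(table, s, family))
  key <- order(vapply(fits, `[[`, 0, "press"),
               vapply(fits, `[[`, 0, "aic"),
               vapply(fits, function(f) paste(f$predictors, collapse = "|"),
                      ""))
  fits[key]
}

#' Select the final model across families
#'
#' Starting from the area-only incumbent, a larger family replaces the
#' incumbent only if its best candidate improves PRESS by at least
#' `rel_press` (relative) AND adjusted R-squared by at least `abs_adj`
#' (absolute).  Comparisons follow the partial order A < {AM, AT} < ATM;
#' ties favour the smaller family (and AM before AT on exact ties).
#'
#' @param table A [trait_table()].
#' @param rel_press Relative PRESS improvement margin, default 0.05.
#' @param abs_adj Absolute adjusted-R2 improvement margin, default 0.01.
#' @return `selection_report`: per-family bests, criteria table and the
#'   chosen model.
#' @export
select_best_model <- function(table, rel_press = 0.05, abs_adj = 0.01) {
  bests <- lapply(c(A = "A", AM = "AM", AT = "AT", ATM = "ATM"),
                  function(f) all_subsets_search(table, f)[[1]])
  better <- function(challenger, incumbent) {
    challenger$press <= (1 - rel_press) * incumbent$press &&
      challenger$adj_r2 >= incumbent$adj_r2 + abs_adj
  }
  chosen <- bests$A
  mid <- Filter(function(m) better(m, chosen), list(bests$AM, bests$AT))
  if (length(mid) > 0) {
    pr <- vapply(mid, `[[`, 0, "press")
    chosen <- mid[[which.min(pr)]]   # exact tie keeps AM (listed first)
  }
  if (better(bests$ATM, chosen)) chosen <- bests$ATM
  crit <- do.call(rbind, lapply(bests, function(m)
    data.frame(family = m$family,
               predictors = paste(m$predictors, collapse = "+"),
               press = m$press, aic = m$aic, adj_r2 = m$adj_r2, r2 = m$r2)))
  structure(list(per_family = bests, chosen = chosen, criteria = crit,
                 margins = c(rel_press = rel_press, abs_adj = abs_adj)),
            class = "selection_report")
}

#' Test-set prediction metrics
#'
#' `r2_test = 1 - SSE/SST` over the test rows (may be negative out of
#' sample) and `mape_pct = 100/n * sum(|yhat - y| / y)`.
#'
#' @param model A `candidate_model`.
#' @param test A [trait_table()] disjoint from the training rows.
#' @return List with `r2_test`, `mape_pct`, `n_test`.
#' @export
evaluate_predictions <- function(model, test) {
  y <- test[[attr(test, "trait")]]
  if (any(y <= 0)) stop("test truth must be positive")
  if (stats::var(y) == 0) stop("zero test variance")
  yhat <- predict(model, test)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  list(r2_test = 1 - sse / sst,
       mape_pct = 100 * mean(abs(yhat - y) / y),
       n_test = length(y))
}

#' Deterministic train/test split
#'
#' @param table A [trait_table()].
#' @param fraction Training fraction (default 0.5, floor for the training
#'   size on odd n).
#' @param seed Integer seed controlling the permutation.
#' @return List with `train` and `test` trait tables.
#' @export
split_train_test <- function(table, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(table)
  if (n < 4L) stop("need at least 4 rows")
  n_train <- floor(fraction * n)
  ord <- local({ set.seed(seed); sample.int(n) })
  keep_attrs <- function(rows) {
    out <- table[rows, , drop = FALSE]
    for (a in c("trait", "area", "morph", "texture", "stage"))
      attr(out, a) <- attr(table, a)
    class(out) <- class(table)
    out
  }
  list(train = keep_attrs(sort(ord[seq_len(n_train)])),
       test = keep_attrs(sort(ord[(n_train + 1):n])))
}

#' k-fold cross-validation of a predictor set
#'
#' Seeded fold assignment; out-of-fold predictions are pooled and scored
#' exactly as [evaluate_predictions()].
#'
#' @param table A [trait_table()].
#' @param predictors Predictor column names.
#' @param k Number of folds (default 10; `k = n` gives leave-one-out).
#' @param seed Fold-assignment seed.
#' @return List with `r2_test`, `mape_pct`, `n_test`, `sse`.
#' @export
cross_validate <- function(table, predictors, k = 10L, seed = 1L) {
  n <- nrow(table)
  if (k < 2L || k > n) stop("need 2 <= k <= n")
  fold <- local({ set.seed(seed)
                  sample(rep_len(seq_len(k), n)) })
  y <- table[[attr(table, "trait")]]
  yhat <- numeric(n)
  for (f in seq_len(k)) {
    tr <- which(fold != f); te <- which(fold == f)
    sub <- table[tr, , drop = FALSE]
    for (a in c("trait", "area", "morph", "texture", "stage"))
      attr(sub, a) <- attr(table, a)
    class(sub) <- class(table)
    m <- fit_linear_model(sub, predictors)
    yhat[te] <- predict(m, table[te, , drop = FALSE])
  }
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  list(r2_test = 1 - sse / sst,
       mape_pct = 100 * mean(abs(yhat - y) / y),
       n_test = n, sse = sse)
}
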