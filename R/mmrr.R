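#' Unfold a symmetric distance matrix into its pairwise vector
#'
#' Lower-triangle entries in a fixed, deterministic pair order:
#' (2,1), (3,1), (3,2), (4,1), ... — i.e., lexicographic by (row, column)
#' with row > column. All matrices entering a matrix regression are
#' unfolded with this same convention.
#'
#' @param D symmetric matrix with row/column labels.
#' @return Numeric vector of length S(S-1)/2 with attribute `pairs`, a
#'   two-column matrix of site labels.
#' @export
unfold <- function(D) {
  S <- nrow(D)
  stopifnot(ncol(D) == S)
  i <- rep(2:S, times = 1:(S - 1))
  j <- unlist(lapply(2:S, function(r) seq_len(r - 1)))
  v <- D[cbind(i, j)]
  attr(v, "pairs") <- cbind(rownames(D)[i], rownames(D)[j])
  v
}

check_labels <- function(Y, Xs) {
  lab <- rownames(Y)
  bad <- names(Xs)[!vapply(Xs, function(m) identical(rownames(m), lab), logical(1))]
  if (length(bad) > 0) {
    stop("predictor matrices with mismatched site labels: ", paste(bad, collapse = ", "))
  }
}

#' Candidate model specification over distance predictors
#'
#' @param geo,env include the geographic / environmental distance term.
#' @param barrier name of the barrier variable included, or `NA`.
#' @param b_geo,b_env include the barrier x geo / barrier x env interaction
#'   (requires both parents).
#' @return A list of class `mmrr_spec` with a human-readable `label`.
#' @export
mmrr_spec <- function(geo = FALSE, env = FALSE, barrier = NA_character_,
                      b_geo = FALSE, b_env = FALSE) {
  if (b_geo && (!geo || is.na(barrier))) stop("b_geo interaction requires geo and a barrier")
  if (b_env && (!env || is.na(barrier))) stop("b_env interaction requires env and a barrier")
  terms <- c(
    if (!is.na(barrier)) barrier,
    if (geo) "geo", if (env) "env",
    if (b_geo) paste0(barrier, ":geo"),
    if (b_env) paste0(barrier, ":env")
  )
  structure(
    list(geo = geo, env = env, barrier = barrier, b_geo = b_geo, b_env = b_env,
         label = if (length(terms) == 0) "1" else paste(terms, collapse = " + ")),
    class = "mmrr_spec"
  )
}

#' Enumerate the candidate model set
#'
#' Four barrier-free models (intercept-only, geo, env, geo + env) plus,
#' for each barrier variable B, nine models: B alone, B with each
#' combination of geo/env, and the interaction-bearing forms
#' B + geo + B:geo, B + env + B:env, B + geo + env + B:geo,
#' B + geo + env + B:env, and B + geo + env + B:geo + B:env. With the
#' seven barrier variables of a three-barrier system this yields
#' 4 + 9 x 7 = 67 candidate models.
#'
#' @param have_geo,have_env whether the geo / env predictors are available.
#' @param barrier_names character vector of barrier-variable names.
#' @return List of [mmrr_spec] objects.
#' @export
build_model_set <- function(have_geo = TRUE, have_env = TRUE, barrier_names = character()) {
  if (!have_geo && !have_env && length(barrier_names) == 0) {
    stop("at least one predictor family is required")
  }
  if (anyDuplicated(barrier_names)) stop("duplicate barrier variable names")
  specs <- list(mmrr_spec())
  if (have_geo) specs <- c(specs, list(mmrr_spec(geo = TRUE)))
  if (have_env) specs <- c(specs, list(mmrr_spec(env = TRUE)))
  if (have_geo && have_env) specs <- c(specs, list(mmrr_spec(geo = TRUE, env = TRUE)))
  for (b in barrier_names) {
    specs <- c(specs, list(
      mmrr_spec(barrier = b),
      if (have_geo) mmrr_spec(geo = TRUE, barrier = b),
      if (have_env) mmrr_spec(env = TRUE, barrier = b),
      if (have_geo && have_env) mmrr_spec(geo = TRUE, env = TRUE, barrier = b),
      if (have_geo) mmrr_spec(geo = TRUE, barrier = b, b_geo = TRUE),
      if (have_env) mmrr_spec(env = TRUE, barrier = b, b_env = TRUE),
      if (have_geo && have_env) mmrr_spec(geo = TRUE, env = TRUE, barrier = b, b_geo = TRUE),
      if (have_geo && have_env) mmrr_spec(geo = TRUE, env = TRUE, barrier = b, b_env = TRUE),
      if (have_geo && have_env) mmrr_spec(geo = TRUE, env = TRUE, barrier = b, b_geo = TRUE, b_env = TRUE)
    ))
  }
  specs[!vapply(specs, is.null, logical(1))]
}

spec_design <- function(spec, geo_z, env_z, bvec, n) {
  X <- matrix(1, n, 1)
  colnames(X) <- "(Intercept)"
  add <- function(X, v, nm) {
    X <- cbind(X, v); colnames(X)[ncol(X)] <- nm; X
  }
  if (!is.na(spec$barrier)) X <- add(X, bvec, spec$barrier)
  if (spec$geo) X <- add(X, geo_z, "geo")
  if (spec$env) X <- add(X, env_z, "env")
  if (spec$b_geo) X <- add(X, bvec * geo_z, paste0(spec$barrier, ":geo"))
  if (spec$b_env) X <- add(X, bvec * env_z, paste0(spec$barrier, ":env"))
  X
}

ols_stats <- function(X, y) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) return(NULL)
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / max(n - p, 1)
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  fstat <- if (p > 1 && rss > 0) ((tss - rss) / (p - 1)) / (rss / (n - p)) else Inf
  loglik <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  list(beta = beta, se = se, t = tstat, r2 = r2, f = fstat,
       loglik = loglik, V = XtXinv * sigma2, n = n, p = p)
}

#' Fit one model by multiple matrix regression with randomization
#'
#' Ordinary least squares on the unfolded lower triangles, with
#' significance assessed by jointly permuting the rows and columns of the
#' response matrix (predictors fixed). Quantitative predictors (geo, env)
#' are standardized to zero mean, unit variance over the site pairs;
#' barrier variables enter as numeric level counts. The permutation
#' p-value counts the observed configuration:
#' p = (1 + #\{|t_perm| >= |t_obs|\}) / (1 + nperm), and analogously for
#' the overall F statistic.
#'
#' @param Y response distance matrix (e.g., pairwise FST).
#' @param Xs named list of predictor matrices; quantitative ones under
#'   names `geo` and/or `env`, barrier matrices under their own names.
#' @param spec an [mmrr_spec].
#' @param nperm number of permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return An object of class `mmrr_fit` (or of class `mmrr_inestimable`
#'   when the design is singular), with coefficient table, R^2, F,
#'   log-likelihood, K, AICc and the data needed for prediction.
#' @export
mmrr_fit <- function(Y, Xs, spec, nperm = 999, seed = 1) {
  check_labels(Y, Xs)
  stopifnot(nperm >= 1)
  y <- unfold(Y)
  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }
  geo_z <- if ("geo" %in% names(Xs)) zscore(unfold(Xs$geo)) else NULL
  env_z <- if ("env" %in% names(Xs)) zscore(unfold(Xs$env)) else NULL
  if (!is.na(spec$barrier) && is.null(Xs[[spec$barrier]])) {
    stop("barrier matrix '", spec$barrier, "' not supplied")
  }
  bvec <- if (!is.na(spec$barrier)) unfold(Xs[[spec$barrier]]) else NULL
  X <- spec_design(spec, geo_z, env_z, bvec, length(y))
  obs <- ols_stats(X, y)
  if (is.null(obs)) {
    return(structure(list(spec = spec, reason = "singular design"),
                     class = "mmrr_inestimable"))
  }
  S <- nrow(Y)
  set.seed(seed)
  exceed_t <- rep(0, ncol(X))
  exceed_f <- 0
  for (b in seq_len(nperm)) {
    perm <- sample.int(S)
    yp <- unfold(Y[perm, perm])
    st <- ols_stats(X, yp)
    if (is.null(st)) next
    exceed_t <- exceed_t + (abs(st$t) >= abs(obs$t))
    exceed_f <- exceed_f + (st$f >= obs$f)
  }
  p_t <- (1 + exceed_t) / (1 + nperm)
  p_f <- (1 + exceed_f) / (1 + nperm)
  k <- obs$p + 1  # coefficients + residual variance
  fit <- structure(list(
    spec = spec,
    coefficients = tibble::tibble(
      term = colnames(X), estimate = as.numeric(obs$beta),
      std_error = obs$se, statistic = as.numeric(obs$t), p_value = p_t
    ),
    r_squared = obs$r2, f_statistic = obs$f, f_p_value = p_f,
    loglik = obs$loglik, k = k, n = obs$n,
    vcov = obs$V, y = y, X = X, barrier_levels = if (!is.null(bvec)) sort(unique(bvec)) else NULL,
    nperm = nperm, seed = seed
  ), class = "mmrr_fit")
  fit$aicc <- aicc(fit)
  fit
}

#' @export
print.mmrr_fit <- function(x, ...) {
  cat(sprintf("<mmrr_fit> FST ~ %s\n  R2 = %.3f, F p = %.4g, AICc = %.2f (n = %d pairs, %d permutations)\n",
              x$spec$label, x$r_squared, x$f_p_value, x$aicc, x$n, x$nperm))
  print(x$coefficients)
  invisible(x)
}

#' Small-sample corrected AIC
#'
#' AIC = -2 logLik + 2K and AICc = AIC + 2K(K+1)/(n-K-1), with K counting
#' the regression coefficients (including the intercept) plus one for the
#' residual variance.
#'
#' @param fit an `mmrr_fit`, or a numeric log-likelihood.
#' @param k,n parameter count and sample size (when `fit` is numeric).
#' @return AICc value.
#' @export
aicc <- function(fit, k = NULL, n = NULL) {
  if (inherits(fit, "mmrr_fit")) {
    ll <- fit$loglik; k <- fit$k; n <- fit$n
  } else {
    ll <- fit
  }
  if (n - k - 1 <= 0) stop("insufficient observations for AICc (n - K - 1 <= 0)")
  aic <- -2 * ll + 2 * k
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Rank fitted models by AICc
#'
#' Computes Delta-AICc, Akaike weights w_i = exp(-Delta_i / 2) normalized
#' to sum one, and the evidence ratio w_best / w_i of the best model over
#' each model. Ties keep the order in which the fits were supplied.
#'
#' @param fits list of `mmrr_fit` objects (inestimable fits are dropped
#'   and reported in the `dropped` attribute).
#' @return A tibble of class `mmrr_ranking`: `model`, `k`, `r_squared`,
#'   `loglik`, `aicc`, `delta_aicc`, `weight`, `evidence_ratio`.
#' @export
rank_models <- function(fits) {
  est <- vapply(fits, inherits, logical(1), "mmrr_fit")
  dropped <- fits[!est]
  fits <- fits[est]
  if (length(fits) == 0) stop("no estimable model fits")
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$spec$label, k = f$k, r_squared = f$r_squared,
                   loglik = f$loglik, aicc = f$aicc)
  })
  tab <- dplyr::mutate(tab,
    delta_aicc = .data$aicc - min(.data$aicc),
    weight = exp(-.data$delta_aicc / 2) / sum(exp(-.data$delta_aicc / 2)),
    evidence_ratio = max(.data$weight) / .data$weight
  )
  ord <- order(tab$aicc)
  tab <- tab[ord, ]
  if (any(duplicated(tab$aicc))) attr(tab, "ties") <- TRUE
  attr(tab, "fits") <- fits[ord]
  attr(tab, "dropped") <- vapply(dropped, function(f) f$spec$label, character(1))
  class(tab) <- c("mmrr_ranking", class(tab))
  tab
}

#' Model-predicted mean response per barrier level
#'
#' Evaluates the fitted regression at each observed barrier level with
#' all quantitative covariates held at their means (zero after
#' standardization); standard errors come from the coefficient
#' covariance matrix.
#'
#' @param fit an `mmrr_fit` whose model contains a barrier term.
#' @return Tibble (`level`, `mean`, `se`, `n_pairs`).
#' @export
group_means <- function(fit) {
  if (is.na(fit$spec$barrier)) stop("model contains no barrier term")
  bcol <- which(colnames(fit$X) == fit$spec$barrier)
  bvec <- fit$X[, bcol]
  levels <- sort(unique(bvec))
  purrr::map_dfr(levels, function(l) {
    x <- rep(0, ncol(fit$X))
    x[1] <- 1            # intercept
    x[bcol] <- l
    # interactions are barrier x standardized covariate, zero at covariate means
    est <- sum(x * fit$coefficients$estimate)
    se <- sqrt(drop(t(x) %*% fit$vcov %*% x))
    tibble::tibble(level = l, mean = est, se = se, n_pairs = sum(bvec == l))
  })
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @export
tidy.mmrr_fit <- function(x, ...) x$coefficients

#' @export
glance.mmrr_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec$label, r_squared = x$r_squared,
    f_statistic = x$f_statistic, f_p_value = x$f_p_value,
    loglik = x$loglik, k = x$k, aicc = x$aicc, n = x$n, nperm = x$nperm
  )
}
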