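#' Joint site frequency spectrum container
#'
#' A `jsfs` is an (n1+1) x (n2+1) numeric matrix of allele-count
#' configurations across two populations, with attributes `n1`, `n2`,
#' `folded`, and a logical `mask` of cells excluded from likelihoods
#' (always the monomorphic corners; after folding also the redundant
#' half of the table).
#'
#' @param mat numeric matrix, dims (n1+1) x (n2+1).
#' @param folded logical.
#' @param mask logical matrix of the same shape, `TRUE` = excluded.
#' @return Object of class `jsfs`.
#' @export
jsfs <- function(mat, folded = FALSE, mask = NULL) {
  n1 <- nrow(mat) - 1L; n2 <- ncol(mat) - 1L
  if (is.null(mask)) mask <- matrix(FALSE, n1 + 1, n2 + 1)
  mask[1, 1] <- TRUE
  mask[n1 + 1, n2 + 1] <- TRUE
  structure(mat, n1 = n1, n2 = n2, folded = folded, mask = mask, class = "jsfs")
}

#' @export
print.jsfs <- function(x, ...) {
  cat(sprintf("<jsfs> %d x %d (%s), total mass %.2f over unmasked cells\n",
              attr(x, "n1"), attr(x, "n2"),
              if (attr(x, "folded")) "folded" else "unfolded",
              sum(x[!attr(x, "mask")])))
  invisible(x)
}

#' Fold a joint SFS by pooled minor allele
#'
#' Cell (i, j) is combined with its complement (n1-i, n2-j); cells whose
#' pooled derived count exceeds half the pooled sample size are masked,
#' and self-complementary mass on the i + j = (n1+n2)/2 diagonal is
#' halved so the total is conserved. Folding a folded spectrum is a
#' no-op.
#'
#' @param x a [jsfs].
#' @return The folded [jsfs].
#' @export
fold_jsfs <- function(x) {
  if (attr(x, "folded")) return(x)
  n1 <- attr(x, "n1"); n2 <- attr(x, "n2")
  m <- unclass(x); attributes(m) <- list(dim = dim(x))
  rev_m <- m[(n1 + 1):1, (n2 + 1):1, drop = FALSE]
  tot <- outer(0:n1, 0:n2, `+`)
  folded <- m + rev_m
  half <- (n1 + n2) / 2
  folded[tot == half] <- folded[tot == half] / 2
  folded[tot > half] <- 0
  mask <- attr(x, "mask") | tot > half
  jsfs(folded, folded = TRUE, mask = mask)
}

#' Observed folded joint SFS from genotypes
#'
#' Each locus is projected down to a fixed number of sampled haploid
#' alleles per population by hypergeometric expectation, summed over
#' loci, then folded by the pooled minor allele and corner-masked.
#' Loci with fewer called alleles than the projection size in either
#' population are dropped (count reported in attribute `n_dropped`).
#'
#' @param g a [geno] object.
#' @param grouping named vector mapping site -> `"pop1"` or `"pop2"`.
#' @param projection integer length-2: haploid projection sizes (n1, n2).
#' @return A folded [jsfs].
#' @export
folded_jsfs <- function(g, grouping, projection = c(10, 10)) {
  site <- sites_of(g)
  pop <- unname(grouping[site])
  if (!all(stats::na.omit(unique(pop)) %in% c("pop1", "pop2"))) {
    stop("grouping must map sites to 'pop1'/'pop2'")
  }
  n1 <- projection[1]; n2 <- projection[2]
  m1 <- g$calls[!is.na(pop) & pop == "pop1", , drop = FALSE]
  m2 <- g$calls[!is.na(pop) & pop == "pop2", , drop = FALSE]
  if (nrow(m1) == 0 || nrow(m2) == 0) stop("both populations must contain individuals")
  c1 <- 2 * colSums(!is.na(m1)); d1 <- colSums(m1, na.rm = TRUE)
  c2 <- 2 * colSums(!is.na(m2)); d2 <- colSums(m2, na.rm = TRUE)
  usable <- c1 >= n1 & c2 >= n2
  out <- matrix(0, n1 + 1, n2 + 1)
  for (l in which(usable)) {
    p1 <- stats::dhyper(0:n1, d1[l], c1[l] - d1[l], n1)
    p2 <- stats::dhyper(0:n2, d2[l], c2[l] - d2[l], n2)
    out <- out + outer(p1, p2)
  }
  res <- fold_jsfs(jsfs(out))
  attr(res, "n_dropped") <- sum(!usable)
  res
}

#' Expected folded JSFS under a two-population divergence model
#'
#' Monte-Carlo expectation of the branch-length-weighted folded joint
#' SFS under the structured coalescent, proportional to the expected
#' spectrum per unit scaled mutation rate theta. Seven models are
#' supported: SI (strict isolation), IM (continuous migration), AM
#' (migration only during an episode of length `Tam` that begins at the
#' split), SC (isolation since the split, migration for the last `Tsc`),
#' and the heterogeneous-migration variants IM2M / AM2M / SC2M mixing a
#' fraction `P` of loci migrating at (m12, m21) with 1 - P at
#' (me12, me21). Times are in units of 2 Nref generations; sizes are
#' relative to Nref; migration rates are per-lineage backward rates on
#' the same time scale.
#'
#' @param model one of `"SI","IM","AM","SC","IM2M","AM2M","SC2M"`.
#' @param params named list/vector: `N1`, `N2`, `Ts`, and as the model
#'   requires `m12`, `m21`, `me12`, `me21`, `Tam`, `Tsc`, `P`.
#' @param sizes haploid sample sizes c(n1, n2).
#' @param nreps number of simulated genealogies (>= 1000 recommended).
#' @param seed integer seed (set before simulation; `NULL` leaves the
#'   RNG stream untouched).
#' @return A folded [jsfs] of expected branch lengths.
#' @export
expected_jsfs <- function(model, params, sizes = c(10, 10), nreps = 5000, seed = NULL) {
  model <- match.arg(model, c("SI", "IM", "AM", "SC", "IM2M", "AM2M", "SC2M"))
  p <- as.list(params)
  need <- demog_model_params(model)
  miss <- setdiff(need, names(p))
  if (length(miss) > 0) stop("missing parameter(s) for ", model, ": ", paste(miss, collapse = ", "))
  if (!is.null(p$Tsc) && p$Tsc > p$Ts) stop("Tsc must not exceed Ts")
  if (!is.null(p$Tam) && p$Tam > p$Ts) stop("Tam must not exceed Ts")
  if (nreps < 1000) warning("nreps < 1000: expected spectrum will be noisy")
  if (!is.null(seed)) set.seed(seed)
  sim_one <- function(m12, m21) {
    win <- switch(model,
      SI = c(0, 0),
      IM = , IM2M = c(0, p$Ts),
      AM = , AM2M = c(p$Ts - p$Tam, p$Ts),
      SC = , SC2M = c(0, p$Tsc)
    )
    if (model == "SI") { m12 <- 0; m21 <- 0 }
    coal_jsfs_cpp(sizes[1], sizes[2], p$N1, p$N2, m12, m21,
                  p$Ts, win[1], win[2], 1.0, as.integer(nreps))
  }
  raw <- if (model %in% c("IM2M", "AM2M", "SC2M")) {
    p$P * sim_one(p$m12, p$m21) + (1 - p$P) * sim_one(p$me12, p$me21)
  } else if (model == "SI") {
    sim_one(0, 0)
  } else {
    sim_one(p$m12, p$m21)
  }
  fold_jsfs(jsfs(raw))
}

demog_model_params <- function(model) {
  switch(model,
    SI   = c("N1", "N2", "Ts"),
    IM   = c("N1", "N2", "m12", "m21", "Ts"),
    AM   = c("N1", "N2", "m12", "m21", "Ts", "Tam"),
    SC   = c("N1", "N2", "m12", "m21", "Ts", "Tsc"),
    IM2M = c("N1", "N2", "m12", "m21", "me12", "me21", "Ts", "P"),
    AM2M = c("N1", "N2", "m12", "m21", "me12", "me21", "Ts", "Tam", "P"),
    SC2M = c("N1", "N2", "m12", "m21", "me12", "me21", "Ts", "Tsc", "P")
  )
}

# composite Poisson log-likelihood with theta profiled analytically
jsfs_loglik <- function(obs, expected, floor_eps = 1e-12) {
  mask <- attr(obs, "mask")
  o <- as.numeric(obs)[!mask]
  e <- as.numeric(expected)[!mask]
  if (any(e <= 0 & o > 0)) {
    e <- pmax(e, floor_eps)
  }
  use <- e > 0
  o <- o[use]; e <- e[use]
  theta <- sum(o) / sum(e)
  list(loglik = sum(o * log(theta * e) - theta * e - lgamma(o + 1)), theta = theta)
}

# transform between the optimizer's unconstrained space and natural params
demog_transform <- function(model) {
  nm <- demog_model_params(model)
  to_natural <- function(x) {
    p <- list()
    for (i in seq_along(nm)) {
      v <- x[i]
      p[[nm[i]]] <- switch(nm[i],
        P = stats::plogis(v),
        Tam = , Tsc = NA_real_,   # filled below as fraction of Ts
        exp(v)
      )
      if (nm[i] %in% c("Tam", "Tsc")) p[[nm[i]]] <- stats::plogis(v)  # fraction
    }
    if (!is.null(p$Tam)) p$Tam <- p$Tam * p$Ts
    if (!is.null(p$Tsc)) p$Tsc <- p$Tsc * p$Ts
    p
  }
  from_natural <- function(p) {
    vapply(nm, function(n) {
      switch(n,
        P = stats::qlogis(min(max(p[[n]], 1e-6), 1 - 1e-6)),
        Tam = stats::qlogis(min(max(p[[n]] / p$Ts, 1e-6), 1 - 1e-6)),
        Tsc = stats::qlogis(min(max(p[[n]] / p$Ts, 1e-6), 1 - 1e-6)),
        log(max(p[[n]], 1e-8))
      )
    }, numeric(1))
  }
  list(names = nm, to_natural = to_natural, from_natural = from_natural)
}

demog_default_start <- function(model) {
  list(N1 = 1, N2 = 1, m12 = 1, m21 = 1, me12 = 0.05, me21 = 0.05,
       Ts = 1, Tam = 0.2, Tsc = 0.2, P = 0.7)[demog_model_params(model)]
}

#' Fit one divergence model to an observed folded JSFS
#'
#' Maximizes the composite Poisson likelihood over unmasked cells, with
#' the mutation scaling theta profiled analytically as
#' sum(obs)/sum(expected). The derivative-free search (Nelder-Mead on
#' log/logit-transformed parameters) is restarted `runs` times from
#' perturbed starting points; the run with the lowest AIC is kept.
#' AIC = 2k - 2 logLik with k the number of free demographic parameters
#' (theta, being profiled, is not counted).
#'
#' @param obs observed folded [jsfs].
#' @param model model name (see [expected_jsfs()]).
#' @param runs number of optimization restarts (study protocol: 20).
#' @param seed integer seed.
#' @param nreps genealogies per likelihood evaluation.
#' @param maxit Nelder-Mead iteration cap per run.
#' @return Object of class `demog_fit`: `model`, `params` (natural
#'   scale), `theta`, `loglik`, `k`, `aic`, and the per-run trace.
#' @export
fit_model <- function(obs, model, runs = 20, seed = 1, nreps = 2000, maxit = 150) {
  stopifnot(runs >= 1)
  model <- match.arg(model, c("SI", "IM", "AM", "SC", "IM2M", "AM2M", "SC2M"))
  tr <- demog_transform(model)
  sizes <- c(attr(obs, "n1"), attr(obs, "n2"))
  objective <- function(x, sim_seed) {
    p <- tr$to_natural(x)
    if (any(!is.finite(unlist(p)))) return(1e10)
    e <- suppressWarnings(
      expected_jsfs(model, p, sizes = sizes, nreps = nreps, seed = sim_seed)
    )
    ll <- jsfs_loglik(obs, e)$loglik
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  set.seed(seed)
  start0 <- tr$from_natural(demog_default_start(model))
  trace <- vector("list", runs)
  for (r in seq_len(runs)) {
    x0 <- start0 + if (r == 1) 0 else stats::rnorm(length(start0), 0, 1)
    sim_seed <- sample.int(.Machine$integer.max, 1)
    o <- try(stats::optim(x0, objective, sim_seed = sim_seed,
                          method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = 1e-6)),
             silent = TRUE)
    if (inherits(o, "try-error")) next
    trace[[r]] <- list(par = o$par, value = o$value, sim_seed = sim_seed)
  }
  trace <- trace[!vapply(trace, is.null, logical(1))]
  if (length(trace) == 0) stop("all optimization runs failed for model ", model)
  k <- length(tr$names)
  vals <- vapply(trace, `[[`, numeric(1), "value")
  best <- trace[[which.min(vals)]]
  p_best <- tr$to_natural(best$par)
  # final evaluation at higher precision for the reported likelihood
  e <- suppressWarnings(
    expected_jsfs(model, p_best, sizes = sizes, nreps = 4 * nreps, seed = best$sim_seed)
  )
  fin <- jsfs_loglik(obs, e)
  structure(list(
    model = model, params = p_best, theta = fin$theta,
    loglik = fin$loglik, k = k, aic = 2 * k - 2 * fin$loglik,
    runs = length(trace),
    run_values = sort(-vals),
    seed = seed, nreps = nreps
  ), class = "demog_fit")
}

#' @export
print.demog_fit <- function(x, ...) {
  cat(sprintf("<demog_fit> %s: logLik = %.2f, AIC = %.2f (k = %d, theta = %.2f, %d runs)\n",
              x$model, x$loglik, x$aic, x$k, x$theta, x$runs))
  cat("  ", paste(sprintf("%s=%.3g", names(x$params), unlist(x$params)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.demog_fit <- function(x, ...) {
  tibble::tibble(term = names(x$params), estimate = unlist(x$params))
}

#' @export
glance.demog_fit <- function(x, ...) {
  tibble::tibble(model = x$model, loglik = x$loglik, k = x$k,
                 aic = x$aic, theta = x$theta, runs = x$runs)
}

#' Compare the seven divergence models on one observed spectrum
#'
#' Fits SI, IM, AM, SC, IM2M, AM2M and SC2M to the observed folded JSFS
#' and ranks them by AIC. A model whose optimization fails is recorded
#' with `NA` and the others are still ranked.
#'
#' @inheritParams fit_model
#' @param models model names to fit (default all seven).
#' @return A tibble (`model`, `k`, `loglik`, `aic`, `delta_aic`, `best`)
#'   ordered by AIC, with the fit objects in attribute `fits`.
#' @export
compare_models <- function(obs, seed = 1, runs = 20, nreps = 2000, maxit = 150,
                           models = c("SI", "IM", "AM", "SC", "IM2M", "AM2M", "SC2M")) {
  fits <- list()
  for (i in seq_along(models)) {
    f <- try(fit_model(obs, models[i], runs = runs, seed = seed + i,
                       nreps = nreps, maxit = maxit), silent = TRUE)
    fits[[models[i]]] <- if (inherits(f, "try-error")) NULL else f
  }
  tab <- purrr::map_dfr(models, function(m) {
    f <- fits[[m]]
    if (is.null(f)) {
      tibble::tibble(model = m, k = NA_integer_, loglik = NA_real_, aic = NA_real_)
    } else {
      tibble::tibble(model = m, k = f$k, loglik = f$loglik, aic = f$aic)
    }
  })
  tab <- dplyr::arrange(tab, .data$aic)
  tab <- dplyr::mutate(tab,
                       delta_aic = .data$aic - min(.data$aic, na.rm = TRUE),
                       best = dplyr::row_number() == 1 & !is.na(.data$aic))
  attr(tab, "fits") <- fits
  tab
}

#' Write / read a folded JSFS as plain text
#'
#' Layout compatible with the common SFS text convention: a header line
#' with the dimensions and fold status, the table values in row-major
#' order, and a mask line of 0/1 flags.
#'
#' @param x a [jsfs]; `path` a file path.
#' @return `write_jsfs`: `path` invisibly; `read_jsfs`: a [jsfs].
#' @export
write_jsfs <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %s", attr(x, "n1") + 1, attr(x, "n2") + 1,
                     if (attr(x, "folded")) "folded" else "unfolded"), con)
  writeLines(paste(format(as.numeric(t(unclass(x))), digits = 17), collapse = " "), con)
  writeLines(paste(as.integer(t(attr(x, "mask"))), collapse = " "), con)
  invisible(path)
}

#' @rdname write_jsfs
#' @param path file path.
#' @export
read_jsfs <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  d1 <- as.integer(hdr[1]); d2 <- as.integer(hdr[2])
  vals <- scan(text = lines[2], quiet = TRUE)
  msk <- scan(text = lines[3], quiet = TRUE)
  m <- matrix(vals, d1, d2, byrow = TRUE)
  jsfs(m, folded = identical(hdr[3], "folded"),
       mask = matrix(msk == 1, d1, d2, byrow = TRUE))
}
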