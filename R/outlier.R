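#' Fit a trimmed chi-square null to the per-locus FST distribution
#'
#' Following the OutFLANK logic: loci with pooled heterozygosity at or
#' below `he_min` are excluded (strict `He > he_min`), the lowest and
#' highest `trim` fractions of the remaining FST values are trimmed, and
#' the null model FST * df / FSTbar ~ chi-square(df) is fitted to the
#' surviving values by maximum likelihood, truncated to the untrimmed
#' range. df is a free continuous parameter, accommodating the
#' non-independence of loci sampled from structured populations.
#'
#' @param locus_stats tibble from [per_locus_fst()] (columns `locus`,
#'   `he`, `fst`) or any data frame with those columns.
#' @param trim fraction trimmed from each tail (default 0.05).
#' @param he_min heterozygosity cutoff (default 0.1, strict).
#' @return Object of class `outlier_fit`: `df`, `fstbar`, truncation
#'   `bounds`, counts of excluded loci, and the input table.
#' @export
fit_trimmed_chisq <- function(locus_stats, trim = 0.05, he_min = 0.1) {
  stopifnot(trim >= 0, trim < 0.25)
  ls <- tibble::as_tibble(locus_stats)
  keep_he <- ls$he > he_min
  fst <- ls$fst[keep_he]
  fst <- fst[is.finite(fst) & fst > 0]
  if (length(fst) < 50) stop("fewer than 50 usable loci after the He filter")
  srt <- sort(fst)
  ntrim <- floor(trim * length(srt))
  kept <- if (ntrim > 0) srt[(ntrim + 1):(length(srt) - ntrim)] else srt
  if (length(kept) == 0) stop("all loci trimmed")
  lo <- min(kept); hi <- max(kept)
  if (stats::var(kept) < 1e-14) {
    stop("degenerate FST distribution (no spread); chi-square df unbounded")
  }
  negll <- function(par) {
    df <- exp(par[1]); fb <- exp(par[2])
    if (!is.finite(df) || df <= 0 || fb <= 0) return(1e10)
    x <- kept * df / fb
    Z <- stats::pchisq(hi * df / fb, df) - stats::pchisq(lo * df / fb, df)
    if (!is.finite(Z) || Z <= 0) return(1e10)
    ll <- sum(stats::dchisq(x, df, log = TRUE) + log(df / fb)) - length(kept) * log(Z)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  m <- mean(kept); v <- stats::var(kept)
  starts <- list(
    c(log(max(2 * m^2 / v, 0.5)), log(m)),
    c(log(max(2 * m^2 / v, 0.5) * 3), log(m * 1.5)),
    c(log(max(2 * m^2 / v, 0.5) / 3), log(m / 1.5)),
    c(log(5), log(m))
  )
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, negll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-10)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best) || best$value >= 1e10) {
    stop("trimmed chi-square fit failed to converge from any start")
  }
  structure(list(
    df = exp(best$par[1]), fstbar = exp(best$par[2]),
    bounds = c(lo = lo, hi = hi),
    loglik = -best$value,
    n_he_excluded = sum(!keep_he),
    n_trimmed = 2 * ntrim,
    n_fit = length(kept),
    trim = trim, he_min = he_min,
    locus_stats = ls
  ), class = "outlier_fit")
}

#' Outlier p-values, q-values and flags from the fitted null
#'
#' Right-tail p-values from the fitted chi-square null are computed for
#' every locus passing the heterozygosity filter; q-values are
#' Benjamini-Hochberg adjusted, and loci with q below the FDR threshold
#' are flagged as outliers. Left-tail departures are not flagged.
#'
#' @param fit an `outlier_fit` from [fit_trimmed_chisq()].
#' @param fdr false discovery rate threshold (default 0.05).
#' @return The `outlier_fit` completed with a `loci` tibble
#'   (`locus`, `he`, `fst`, `p`, `q`, `outlier`) and `n_outliers`.
#' @export
outlier_pvalues <- function(fit, fdr = 0.05) {
  stopifnot(inherits(fit, "outlier_fit"))
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  ls <- fit$locus_stats
  tested <- ls$he > fit$he_min & is.finite(ls$fst)
  p <- rep(NA_real_, nrow(ls))
  p[tested] <- stats::pchisq(ls$fst[tested] * fit$df / fit$fstbar,
                             fit$df, lower.tail = FALSE)
  q <- rep(NA_real_, nrow(ls))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  fit$loci <- tibble::tibble(
    locus = ls$locus, he = ls$he, fst = ls$fst,
    p = p, q = q, outlier = !is.na(q) & q < fdr
  )
  fit$fdr <- fdr
  fit$n_outliers <- sum(fit$loci$outlier)
  fit
}

#' @export
print.outlier_fit <- function(x, ...) {
  cat(sprintf("<outlier_fit> chi-square null: df = %.2f, FSTbar = %.4f (fit on %d loci; %d He-excluded, %d trimmed)\n",
              x$df, x$fstbar, x$n_fit, x$n_he_excluded, x$n_trimmed))
  if (!is.null(x$n_outliers)) {
    cat(sprintf("  %d outlier loci at FDR %.2f\n", x$n_outliers, x$fdr))
  }
  invisible(x)
}

#' @export
tidy.outlier_fit <- function(x, ...) {
  if (is.null(x$loci)) stop("run outlier_pvalues() first")
  x$loci
}

#' @export
glance.outlier_fit <- function(x, ...) {
  tibble::tibble(
    df = x$df, fstbar = x$fstbar, n_fit = x$n_fit,
    n_he_excluded = x$n_he_excluded, n_trimmed = x$n_trimmed,
    n_outliers = if (is.null(x$n_outliers)) NA_integer_ else x$n_outliers
  )
}
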