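#' Per-site genetic diversity summaries
#'
#' Computes observed heterozygosity (Ho, fraction of heterozygous calls),
#' expected heterozygosity (He = 2p(1-p) from the within-site allele
#' frequency, averaged over loci) and the inbreeding coefficient
#' FIS = 1 - Ho/He, each reported both over all loci and over the loci
#' variable within the site. FIS is defined on variable loci only.
#'
#' @param g a [geno] object with at least one individual per site.
#' @return A tibble with one row per site: `site`, `n`, `ho_all`, `he_all`,
#'   `ho_var`, `he_var`, `fis`, `n_loci`, `n_var`.
#' @export
diversity_stats <- function(g) {
  site <- sites_of(g)
  purrr::map_dfr(unique(site), function(s) {
    n_ind <- sum(site == s)
    m <- g$calls[site == s, , drop = FALSE]
    called <- colSums(!is.na(m))
    usable <- called > 0          # all-missing loci skipped for this site
    m <- m[, usable, drop = FALSE]
    p <- colMeans(m, na.rm = TRUE) / 2
    he <- 2 * p * (1 - p)
    ho <- colMeans(m == 1, na.rm = TRUE)
    variable <- p > 0 & p < 1
    ho_var <- mean(ho[variable])
    he_var <- mean(he[variable])
    tibble::tibble(
      site = s, n = n_ind,
      ho_all = mean(ho), he_all = mean(he),
      ho_var = ho_var, he_var = he_var,
      fis = 1 - ho_var / he_var,
      n_loci = ncol(m), n_var = sum(variable)
    )
  })
}

# Weir & Cockerham (1984) variance components for one biallelic locus.
# n: diploid sample sizes per population; p: alt-allele frequencies;
# h: observed heterozygote fractions. Returns c(a, b, c) or NULL if the
# locus is uninformative (fewer than 2 usable populations).
wc_components <- function(n, p, h) {
  use <- n >= 2
  n <- n[use]; p <- p[use]; h <- h[use]
  r <- length(n)
  if (r < 2) return(NULL)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

locus_pop_summaries <- function(calls, site, pops) {
  lapply(pops, function(s) {
    m <- calls[site == s, , drop = FALSE]
    n <- colSums(!is.na(m))
    list(
      n = n,
      p = ifelse(n > 0, colMeans(m, na.rm = TRUE) / 2, NA_real_),
      h = ifelse(n > 0, colMeans(m == 1, na.rm = TRUE), NA_real_)
    )
  })
}

#' Pairwise multi-locus Weir-Cockerham FST between sites
#'
#' For each pair of sites, Weir & Cockerham's theta is computed per locus
#' from the among/between/within variance components (a, b, c) and
#' combined across loci as a ratio of sums, sum(a) / sum(a + b + c).
#' Missing calls are excluded per locus; negative estimates are reported
#' as computed.
#'
#' @param g a [geno] object with at least two sites.
#' @return A labeled symmetric site x site matrix with zero diagonal.
#'   Pairs sharing no usable locus are `NA` and trigger a warning.
#' @export
pairwise_fst <- function(g) {
  site <- sites_of(g)
  pops <- unique(site)
  if (length(pops) < 2) stop("need at least two sites")
  sm <- locus_pop_summaries(g$calls, site, pops)
  names(sm) <- pops
  S <- length(pops)
  out <- matrix(0, S, S, dimnames = list(pops, pops))
  for (i in seq_len(S - 1)) for (j in (i + 1):S) {
    A <- sm[[i]]; B <- sm[[j]]
    num <- 0; den <- 0; used <- 0L
    for (l in seq_along(A$n)) {
      comp <- wc_components(c(A$n[l], B$n[l]), c(A$p[l], B$p[l]), c(A$h[l], B$h[l]))
      if (is.null(comp)) next
      tot <- sum(comp)
      if (!is.finite(tot)) next
      num <- num + comp["a"]; den <- den + tot; used <- used + 1L
    }
    theta <- if (used == 0L || den == 0) NA_real_ else unname(num / den)
    if (used == 0L) warning(sprintf("sites %s and %s share no usable loci", pops[i], pops[j]))
    out[i, j] <- out[j, i] <- theta
  }
  out
}

#' Per-locus uncorrected FST and heterozygosity
#'
#' For each locus, the uncorrected fixation index is the sample-size
#' weighted among-group variance of allele frequencies divided by the
#' total variance p(1-p) at the pooled frequency, with no finite-sample
#' correction; this is the quantity whose null distribution the outlier
#' scan models. He is the pooled-sample expected heterozygosity.
#'
#' @param g a [geno] object.
#' @param grouping optional named vector mapping site -> group; by default
#'   each site is its own group.
#' @return A tibble (`locus`, `he`, `fst`, `n_groups`) for polymorphic
#'   loci; the count of monomorphic loci excluded is in attribute
#'   `n_monomorphic`.
#' @export
per_locus_fst <- function(g, grouping = NULL) {
  site <- sites_of(g)
  grp <- if (is.null(grouping)) site else unname(grouping[site])
  groups <- unique(grp)
  if (length(groups) < 2) stop("need at least two groups")
  sm <- locus_pop_summaries(g$calls, grp, groups)
  nmat <- vapply(sm, `[[`, numeric(ncol(g$calls)), "n") |> matrix(nrow = ncol(g$calls))
  pmat <- vapply(sm, `[[`, numeric(ncol(g$calls)), "p") |> matrix(nrow = ncol(g$calls))
  res <- purrr::map_dfr(seq_len(ncol(g$calls)), function(l) {
    n <- nmat[l, ]; p <- pmat[l, ]
    use <- n > 0
    n <- n[use]; p <- p[use]
    if (length(n) < 2) return(NULL)
    w <- n / sum(n)
    pbar <- sum(w * p)
    he <- 2 * pbar * (1 - pbar)
    if (pbar == 0 || pbar == 1) return(NULL)   # monomorphic: FST undefined
    fst <- sum(w * (p - pbar)^2) / (pbar * (1 - pbar))
    tibble::tibble(locus = colnames(g$calls)[l], he = he, fst = fst,
                   n_groups = length(n))
  })
  attr(res, "n_monomorphic") <- ncol(g$calls) - nrow(res)
  res
}

#' Principal component analysis of the genotype covariance matrix
#'
#' Missing calls are mean-imputed per locus, columns are centered, and
#' individual scores are taken from the eigenstructure of the resulting
#' individual covariance (computed via SVD). Variance fractions are
#' relative to the total genotypic variance.
#'
#' @param g a [geno] object with at least two individuals.
#' @param n_axes number of components to report (default up to 10).
#' @return A list of class `geno_pca`: `scores` (tibble with `individual`,
#'   `site`, `PC1..`), `var_frac`, and `degenerate` flag (TRUE when the
#'   genotypes carry no variance).
#' @export
genotype_pca <- function(g, n_axes = 10) {
  calls <- g$calls
  if (nrow(calls) < 2) stop("need at least two individuals")
  all_missing <- rownames(calls)[rowSums(!is.na(calls)) == 0]
  if (length(all_missing) > 0) {
    stop("individual(s) with no called genotypes: ", paste(all_missing, collapse = ", "))
  }
  mu <- colMeans(calls, na.rm = TRUE)
  x <- calls
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx) > 0) x[idx] <- mu[idx[, 2]]
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  total <- sum(sv$d^2)
  degenerate <- total < 1e-12
  k <- min(n_axes, ncol(sv$u), nrow(calls) - 1)
  scores <- if (degenerate) {
    matrix(0, nrow(calls), k)
  } else {
    sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  }
  colnames(scores) <- paste0("PC", seq_len(k))
  out <- list(
    scores = dplyr::bind_cols(
      tibble::tibble(individual = rownames(calls), site = unname(sites_of(g))),
      tibble::as_tibble(scores)
    ),
    var_frac = if (degenerate) rep(0, k) else (sv$d[seq_len(k)]^2) / total,
    degenerate = degenerate
  )
  class(out) <- "geno_pca"
  out
}

#' @export
print.geno_pca <- function(x, ...) {
  cat(sprintf("<geno_pca> %d individuals, %d axes", nrow(x$scores), length(x$var_frac)))
  if (x$degenerate) cat(" [degenerate: no genotypic variance]")
  cat("\n  variance fractions:", paste(sprintf("%.3f", utils::head(x$var_frac, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Evanno delta-K statistic over clustering log-probabilities
#'
#' Given replicate log-probabilities L(K) for consecutive numbers of
#' clusters K, computes DeltaK(K) = mean(|L(K+1) - 2 L(K) + L(K-1)|) / sd(L(K)),
#' with the mean over replicate-wise second differences and the sample
#' standard deviation (n-1 denominator) over replicates of L(K). Endpoints
#' are undefined; so is any K whose replicates are identical (sd = 0).
#'
#' @param lnp data frame with columns `k`, `rep`, `lnp`; at least three
#'   consecutive K values and two replicates per K.
#' @return A tibble (`k`, `delta_k`, `defined`) with attribute `best_k`,
#'   the K maximizing DeltaK among defined values.
#' @export
delta_k <- function(lnp) {
  lnp <- tibble::as_tibble(lnp)
  stopifnot(all(c("k", "rep", "lnp") %in% names(lnp)))
  ks <- sort(unique(lnp$k))
  if (length(ks) < 3 || any(diff(ks) != 1)) stop("need >= 3 consecutive K values")
  wide <- tidyr::pivot_wider(lnp, names_from = "rep", values_from = "lnp") |>
    dplyr::arrange(.data$k)
  L <- as.matrix(wide[, -1, drop = FALSE])
  if (ncol(L) < 2 || anyNA(L)) stop("need >= 2 replicates for every K")
  sds <- apply(L, 1, stats::sd)
  dk <- rep(NA_real_, length(ks))
  for (i in 2:(length(ks) - 1)) {
    if (sds[i] == 0) next
    dk[i] <- mean(abs(L[i + 1, ] - 2 * L[i, ] + L[i - 1, ])) / sds[i]
  }
  flagged <- sds == 0 & seq_along(ks) %in% 2:(length(ks) - 1)
  if (any(flagged)) {
    warning("sd(L(K)) = 0 at K = ", paste(ks[flagged], collapse = ", "), "; DeltaK undefined there")
  }
  out <- tibble::tibble(k = ks, delta_k = dk, defined = !is.na(dk))
  attr(out, "best_k") <- if (any(out$defined)) out$k[which.max(out$delta_k)] else NA_integer_
  out
}
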