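# analytic folded JSFS of a panmictic population: E[t_{i,j}] proportional
# to C(n1,i) C(n2,j) / C(n, i+j) / (i+j), folded by pooled minor allele
panmictic_folded_oracle <- function(n1, n2) {
  n <- n1 + n2
  unf <- outer(0:n1, 0:n2, function(i, j) {
    t <- i + j
    ifelse(t > 0 & t < n, choose(n1, i) * choose(n2, j) / choose(n, pmin(t, n - 1)) / pmax(t, 1), 0)
  })
  f <- matrix(0, n1 + 1, n2 + 1)
  for (i in 0:n1) for (j in 0:n2) {
    t <- i + j
    if (t > 0 && t < n) {
      if (t < n / 2) f[i + 1, j + 1] <- unf[i + 1, j + 1] + unf[n1 - i + 1, n2 - j + 1]
      else if (t == n / 2) f[i + 1, j + 1] <- unf[i + 1, j + 1]
    }
  }
  f
}

test_that("folding is mass-conserving, idempotent, and masks the redundant half", {
  set.seed(2)
  m <- matrix(rexp(9 * 7), 9, 7)
  x <- jsfs(m)
  fx <- fold_jsfs(x)
  expect_true(attr(fx, "folded"))
  # mass conserved over non-corner cells
  keep <- !attr(x, "mask")
  expect_equal(sum(unclass(fx)[!attr(fx, "mask")]), sum(m[keep]), tolerance = 1e-12)
  expect_identical(fold_jsfs(fx), fx)
  tot <- outer(0:8, 0:6, `+`)
  expect_true(all(attr(fx, "mask")[tot > 7]))
})

test_that("a fixed-different locus projects onto the complementary corner cells", {
  calls <- matrix(c(rep(2L, 4), rep(0L, 4)), ncol = 1)
  g <- toy_geno(calls, sites = rep(c("A", "B"), each = 4))
  grouping <- c(A = "pop1", B = "pop2")
  s <- folded_jsfs(g, grouping, projection = c(2, 2))
  m <- unclass(s)
  expect_equal(m[3, 1] + m[1, 3], 1, tolerance = 1e-12)
  expect_equal(sum(m) - (m[3, 1] + m[1, 3]), 0, tolerance = 1e-12)
})

test_that("hypergeometric projection equals exhaustive subsampling enumeration", {
  # 3 loci with missingness; enumerate all ways of drawing 2 alleles per pop
  calls <- cbind(c(0L, 1L, 2L, NA, 1L, 1L),
                 c(1L, 1L, 0L, 2L, 0L, NA),
                 c(2L, 2L, 1L, 0L, 0L, 1L))
  g <- toy_geno(calls, sites = rep(c("A", "B"), each = 3))
  grouping <- c(A = "pop1", B = "pop2")
  s <- folded_jsfs(g, grouping, projection = c(2, 2))
  # oracle: per locus, enumerate unordered pairs of chromosomes per group
  unf <- matrix(0, 3, 3)
  for (l in 1:3) {
    enum <- function(rows) {
      alleles <- unlist(lapply(rows, function(r) {
        v <- calls[r, l]
        if (is.na(v)) NULL else c(rep(1, v), rep(0, 2 - v))
      }))
      alleles
    }
    a1 <- enum(1:3); a2 <- enum(4:6)
    if (length(a1) < 2 || length(a2) < 2) next
    pairs1 <- utils::combn(length(a1), 2)
    pairs2 <- utils::combn(length(a2), 2)
    for (c1 in seq_len(ncol(pairs1))) for (c2 in seq_len(ncol(pairs2))) {
      i <- sum(a1[pairs1[, c1]]); j <- sum(a2[pairs2[, c2]])
      unf[i + 1, j + 1] <- unf[i + 1, j + 1] + 1 / (ncol(pairs1) * ncol(pairs2))
    }
  }
  oracle <- fold_jsfs(jsfs(unf))
  expect_equal(unclass(s), unclass(oracle), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("panmictic data give a population-symmetric folded spectrum", {
  freqs <- matrix(runif(4000, 0.05, 0.95), 4000, 2)
  freqs[, 2] <- freqs[, 1]                       # same frequency everywhere
  g <- geno_from_freqs(freqs, n_per_site = 12, seed = 6)
  s <- folded_jsfs(g, c(S1 = "pop1", S2 = "pop2"), projection = c(8, 8))
  m <- unclass(s); msk <- attr(s, "mask")
  asym <- abs(m - t(m)) / pmax(m + t(m), 1)
  expect_lt(max(asym[!msk & !t(msk)]), 0.15)
})

test_that("the SI limit Ts -> 0 reproduces the analytic panmictic folded SFS", {
  e <- expected_jsfs("SI", list(N1 = 1, N2 = 1, Ts = 1e-9), sizes = c(8, 8),
                     nreps = 100000, seed = 1)
  oracle <- panmictic_folded_oracle(8, 8)
  msk <- attr(e, "mask")
  tv <- 0.5 * sum(abs(e[!msk] / sum(e[!msk]) - oracle[!msk] / sum(oracle[!msk])))
  expect_lt(tv, 0.02)
})

test_that("migration homogenizes the spectrum and 2M reduces at P = 1", {
  shared_frac <- function(e) {
    m <- unclass(e); msk <- attr(e, "mask")
    inner <- m[2:8, 2:8]
    sum(inner) / sum(m[!msk])
  }
  base <- list(N1 = 1, N2 = 1, Ts = 2)
  e0 <- expected_jsfs("IM", c(base, m12 = 0.001, m21 = 0.001), c(8, 8), 30000, seed = 2)
  e1 <- expected_jsfs("IM", c(base, m12 = 5, m21 = 5), c(8, 8), 30000, seed = 2)
  expect_gt(shared_frac(e1), shared_frac(e0))
  p1 <- list(N1 = 1, N2 = 1, m12 = 2, m21 = 1, me12 = 9, me21 = 9, Ts = 2, P = 1)
  e2m <- expected_jsfs("IM2M", p1, c(8, 8), 40000, seed = 3)
  ehom <- expected_jsfs("IM", list(N1 = 1, N2 = 1, m12 = 2, m21 = 1, Ts = 2),
                        c(8, 8), 40000, seed = 3)
  msk <- attr(e2m, "mask")
  rel <- sum(abs(e2m[!msk] - ehom[!msk])) / sum(ehom[!msk])
  expect_lt(rel, 0.05)
})

test_that("expected spectra are reproducible and validate their parameters", {
  p <- list(N1 = 1, N2 = 1, m12 = 1, m21 = 1, Ts = 2, Tsc = 0.3)
  a <- expected_jsfs("SC", p, c(6, 6), 5000, seed = 9)
  b <- expected_jsfs("SC", p, c(6, 6), 5000, seed = 9)
  expect_identical(unclass(a), unclass(b))
  expect_error(expected_jsfs("SC", list(N1 = 1, N2 = 1, m12 = 1, m21 = 1, Ts = 1, Tsc = 2),
                             c(6, 6), 2000), "Tsc")
  expect_error(expected_jsfs("SC", list(N1 = 1, N2 = 1, Ts = 1), c(6, 6), 2000), "missing")
  expect_error(expected_jsfs("XX", p, c(6, 6), 2000))
})

test_that("the composite likelihood prefers the generating parameters", {
  true <- list(N1 = 1.5, N2 = 0.5, m12 = 1, m21 = 0.5, Ts = 2, Tsc = 0.3)
  e <- expected_jsfs("SC", true, c(8, 8), 40000, seed = 12)
  set.seed(12)
  obs <- jsfs(matrix(rpois(81, 50 * unclass(e)), 9, 9), folded = TRUE,
              mask = attr(e, "mask"))
  ll_of <- function(params) {
    ee <- expected_jsfs("SC", params, c(8, 8), 40000, seed = 13)
    msk <- attr(obs, "mask")
    o <- as.numeric(obs)[!msk]; x <- pmax(as.numeric(ee)[!msk], 1e-12)
    th <- sum(o) / sum(x)
    sum(o * log(th * x) - th * x - lgamma(o + 1))
  }
  perturbed <- true
  perturbed$N1 <- true$N1 * 2; perturbed$Ts <- true$Ts * 2; perturbed$m21 <- true$m21 * 2
  expect_gt(ll_of(true), ll_of(perturbed))
})

test_that("multi-start optimization is monotone in restarts and recovers SI over SC", {
  e <- expected_jsfs("SI", list(N1 = 1.5, N2 = 0.7, Ts = 2), c(8, 8), 20000, seed = 31)
  set.seed(31)
  obs <- jsfs(matrix(rpois(81, 60 * unclass(e)), 9, 9), folded = TRUE,
              mask = attr(e, "mask"))
  f1 <- fit_model(obs, "SI", runs = 1, seed = 5, nreps = 800, maxit = 50)
  f3 <- fit_model(obs, "SI", runs = 3, seed = 5, nreps = 800, maxit = 50)
  expect_gte(max(f3$run_values), max(f1$run_values) - 1e-9)
  # k-penalty: SI beats (or ties within 2 AIC of) the overparameterized SC
  wins <- vapply(1:3, function(r) {
    ee <- expected_jsfs("SI", list(N1 = 1.5, N2 = 0.7, Ts = 2), c(8, 8), 20000,
                        seed = 1000 + r)
    set.seed(r)
    oo <- jsfs(matrix(rpois(81, 60 * unclass(ee)), 9, 9), folded = TRUE,
               mask = attr(ee, "mask"))
    fsi <- fit_model(oo, "SI", runs = 2, seed = r, nreps = 1200, maxit = 60)
    fsc <- fit_model(oo, "SC", runs = 2, seed = r, nreps = 1200, maxit = 60)
    fsi$aic <= fsc$aic + 2
  }, logical(1))
  expect_gte(sum(wins), 2)
})

test_that("compare_models ranks all seven divergence models", {
  e <- expected_jsfs("IM", list(N1 = 1, N2 = 1, m12 = 1, m21 = 1, Ts = 1),
                     c(6, 6), 20000, seed = 8)
  set.seed(8)
  obs <- jsfs(matrix(rpois(49, 40 * unclass(e)), 7, 7), folded = TRUE,
              mask = attr(e, "mask"))
  tab <- compare_models(obs, seed = 2, runs = 1, nreps = 500, maxit = 40)
  expect_equal(nrow(tab), 7)
  expect_setequal(tab$model, c("SI", "IM", "AM", "SC", "IM2M", "AM2M", "SC2M"))
  expect_true(!is.unsorted(tab$aic))
  expect_equal(tab$delta_aic[1], 0)
  expect_true(tab$best[1])
  fits <- attr(tab, "fits")
  expect_equal(fits$SI$aic, 2 * 3 - 2 * fits$SI$loglik, tolerance = 1e-12)
  expect_equal(fits$SC2M$k, 9)
})

test_that("JSFS text serialization round-trips", {
  set.seed(4)
  x <- fold_jsfs(jsfs(matrix(rexp(35), 5, 7)))
  path <- tempfile(fileext = ".sfs")
  write_jsfs(x, path)
  y <- read_jsfs(path)
  expect_equal(unclass(y), unclass(x), tolerance = 1e-15, ignore_attr = TRUE)
  expect_identical(attr(y, "mask"), attr(x, "mask"))
  expect_true(attr(y, "folded"))
})
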