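# Small in-code fixtures shared across test files.

# geno object from an explicit call matrix; sites assigned round-robin
# unless given.
toy_geno <- function(calls, sites = NULL) {
  if (is.null(rownames(calls))) rownames(calls) <- sprintf("i%02d", seq_len(nrow(calls)))
  if (is.null(colnames(calls))) colnames(calls) <- sprintf("L%03d", seq_len(ncol(calls)))
  if (is.null(sites)) sites <- rep(c("A", "B"), length.out = nrow(calls))
  geno(calls, tibble::tibble(individual = rownames(calls), site = sites))
}

# genotypes for S sites x n diploids drawn from given per-site allele
# frequencies (matrix loci x sites)
geno_from_freqs <- function(freqs, n_per_site, seed = 1) {
  set.seed(seed)
  S <- ncol(freqs); L <- nrow(freqs)
  calls <- do.call(rbind, lapply(seq_len(S), function(s) {
    matrix(stats::rbinom(n_per_site * L, 2, rep(freqs[, s], each = n_per_site)),
           n_per_site, L)
  }))
  toy_geno(calls, sites = rep(sprintf("S%d", seq_len(S)), each = n_per_site))
}

# random symmetric "distance" matrix with iid upper-triangle entries
rand_sym <- function(S, labels = sprintf("S%d", seq_len(S))) {
  m <- matrix(0, S, S, dimnames = list(labels, labels))
  v <- stats::rnorm(S * (S - 1) / 2)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  m
}

# fold an unfolded pair vector back into a symmetric matrix, using the
# package's stated pair order (row-wise lower triangle)
fold_pairs <- function(v, labels) {
  S <- length(labels)
  m <- matrix(0, S, S, dimnames = list(labels, labels))
  idx <- 1
  for (i in 2:S) for (j in seq_len(i - 1)) {
    m[i, j] <- m[j, i] <- v[idx]
    idx <- idx + 1
  }
  m
}

# independent transcription of the Weir & Cockerham (1984) theta for one
# biallelic locus from per-population genotype counts (n_hom_ref, n_het,
# n_hom_alt), used as the direct-formula oracle
wc_theta_oracle <- function(counts) {
  n <- rowSums(counts)
  r <- nrow(counts)
  p <- (counts[, 3] + counts[, 2] / 2) / n
  h <- counts[, 2] / n
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

# plain-R Dijkstra over an explicit edge list, used as the shortest-path
# oracle for small rasters
dijkstra_oracle <- function(n, edges, weights, from) {
  dist <- rep(Inf, n)
  dist[from] <- 0
  visited <- rep(FALSE, n)
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, weights[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, weights[k]))
  }
  repeat {
    cand <- which(!visited & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    visited[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (k in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][k, 1]
        dist[v] <- min(dist[v], dist[u] + adj[[u]][k, 2])
      }
    }
  }
  dist
}
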