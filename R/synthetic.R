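#' Configuration for the synthetic seascape generator
#'
#' Defaults mirror the sampling design the analysis is built for: 8
#' coastal sites of 12 diploid individuals each, 5,000 biallelic SNPs,
#' hierarchical structure from up to three barriers with Balding-Nichols
#' drift, a site-level drift component with an isolation-by-distance
#' correlation kernel, 5% missing calls, and twelve environmental
#' variables (six mean + six variability layers) following smooth
#' spatial gradients.
#'
#' @param n_sites number of sampling sites.
#' @param n_ind diploid individuals per site.
#' @param n_loci number of biallelic SNP loci.
#' @param barriers named numeric vector of per-barrier drift effects F_b;
#'   barriers split the site chain at evenly spaced positions.
#' @param f_site site-level Balding-Nichols drift F.
#' @param ibd_scale e-folding distance (meters) of the site-level
#'   correlation kernel; `Inf` disables IBD.
#' @param missing_rate fraction of calls set missing.
#' @param env_gradient multiplier on the latitudinal/longitudinal
#'   gradients of the environmental layers (0 = noise only).
#' @param env_noise_sd log-scale noise sd of the environmental layers.
#' @param raster_dim grid dimensions c(nrows, ncols).
#' @param cellsize raster cell size in degrees.
#' @param land_fraction approximate fraction of land (0 = all water).
#' @param seed master seed driving all sub-generators.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 8, n_ind = 12, n_loci = 5000,
                       barriers = c(b1 = 0.02, b2 = 0.05, b3 = 0.03),
                       f_site = 0.02, ibd_scale = 1e6, missing_rate = 0.05,
                       env_gradient = 1, env_noise_sd = 0.1,
                       raster_dim = c(30, 44), cellsize = 0.5,
                       land_fraction = 0.25, seed = 1) {
  stopifnot(missing_rate >= 0, missing_rate <= 1, f_site >= 0, f_site < 1,
            all(barriers >= 0), all(barriers < 1), land_fraction >= 0, land_fraction < 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a seascape: raster, sites and environmental table
#'
#' Builds a coastline raster in which a peninsula separates two basins
#' (emulating a semi-enclosed sea opening into an ocean), places the
#' sites in water along the coastline, assigns per-barrier side labels
#' from position along the site chain, and generates strictly positive
#' environmental variables as smooth spatial gradients plus log-normal
#' noise.
#'
#' @param cfg a [sim_config].
#' @return List with `sites` (tibble: site, name, lat, lon, side_*),
#'   `raster` (a [sea_raster]) and `env` (tibble, site x 12 variables).
#' @export
simulate_seascape <- function(cfg) {
  set.seed(cfg$seed)
  nr <- cfg$raster_dim[1]; nc <- cfg$raster_dim[2]
  xll <- 32; yll <- 8
  water <- matrix(TRUE, nr, nc)
  if (cfg$land_fraction > 0) {
    # peninsula: a wedge descending from the northern edge through the
    # middle of the grid, leaving a strait open at its southern tip
    depth <- round(nr * (1 - cfg$land_fraction / 2))
    mid <- round(nc * 0.45)
    width <- max(2, round(nc * cfg$land_fraction / 2))
    for (r in seq_len(depth)) {
      w <- max(1, round(width * (1 - r / depth) * 2))
      cols <- max(1, mid - w):min(nc, mid + w)
      water[r, cols] <- FALSE
    }
  }
  rast <- sea_raster(water, xll, yll, cfg$cellsize)
  # sites along a smooth coastal arc around the peninsula, in water
  tt <- seq(0.05, 0.95, length.out = cfg$n_sites)
  lon <- xll + (0.12 + 0.76 * tt) * nc * cfg$cellsize
  lat <- yll + (0.25 + 0.55 * sin(pi * tt)^0.7) * nr * cfg$cellsize
  # nudge any site sitting on land southwards into water
  for (i in seq_len(cfg$n_sites)) {
    tries <- 0
    repeat {
      row <- nr - floor((lat[i] - yll) / cfg$cellsize)
      col <- floor((lon[i] - xll) / cfg$cellsize) + 1
      row <- min(max(row, 1), nr); col <- min(max(col, 1), nc)
      if (water[row, col]) break
      lat[i] <- lat[i] - cfg$cellsize
      tries <- tries + 1
      if (tries > nr) stop("could not place site ", i, " in water (too much land)")
    }
  }
  sites <- tibble::tibble(
    site = sprintf("S%02d", seq_len(cfg$n_sites)),
    name = sprintf("site_%02d", seq_len(cfg$n_sites)),
    lat = lat, lon = lon
  )
  # barriers split the site chain at evenly spaced positions
  nb <- length(cfg$barriers)
  if (nb > 0) {
    cuts <- round(seq_len(nb) * cfg$n_sites / (nb + 1))
    for (b in seq_len(nb)) {
      sites[[paste0("side_", names(cfg$barriers)[b])]] <-
        ifelse(seq_len(cfg$n_sites) <= cuts[b], "A", "B")
    }
  }
  env <- simulate_env(cfg, sites)
  list(sites = sites, raster = rast, env = env)
}

simulate_env <- function(cfg, sites) {
  base_vars <- c("sst", "salinity", "ph", "oxygen", "nitrate", "chla")
  latn <- (sites$lat - min(sites$lat)) / max(diff(range(sites$lat)), 1e-9)
  lonn <- (sites$lon - min(sites$lon)) / max(diff(range(sites$lon)), 1e-9)
  env <- tibble::tibble(site = sites$site)
  for (v in seq_along(base_vars)) {
    a <- stats::runif(1, -1, 1) * cfg$env_gradient
    b <- stats::runif(1, -1, 1) * cfg$env_gradient
    mu <- exp(1 + a * latn + b * lonn + stats::rnorm(nrow(sites), 0, cfg$env_noise_sd))
    vr <- exp(0.2 + 0.5 * (-a) * latn + 0.5 * b * lonn +
                stats::rnorm(nrow(sites), 0, cfg$env_noise_sd))
    env[[paste0(base_vars[v], "_mean")]] <- mu
    env[[paste0(base_vars[v], "_range")]] <- vr
  }
  env
}

# Balding-Nichols draw: Beta around p (vectorized) with drift F
rbn <- function(p, f) {
  if (f <= 0) return(p)
  stats::rbeta(length(p), p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate genotypes with barrier, site-drift and IBD structure
#'
#' Per locus the ancestral frequency is Uniform(0.05, 0.95); each
#' barrier contributes Balding-Nichols drift F_b accumulated along the
#' chain of barrier crossings from the reference (first) region; sites
#' then drift from their regional frequency with F_site through a
#' Gaussian-copula Balding-Nichols step whose site-site correlation
#' decays as exp(-d / ibd_scale) with geographic distance (the IBD
#' component). Genotypes are Binomial(2, site frequency) with missing
#' calls at the configured rate.
#'
#' @param cfg a [sim_config].
#' @param sites site table from [simulate_seascape()] (needs `side_*`
#'   columns when barriers are configured).
#' @param dist optional site x site distance matrix (meters) for the IBD
#'   kernel, e.g. from [least_cost_distance()]; haversine distance is
#'   used when omitted.
#' @return A [geno] object.
#' @export
simulate_genotypes <- function(cfg, sites, dist = NULL) {
  set.seed(cfg$seed + 1)
  S <- nrow(sites)
  nb <- length(cfg$barriers)
  bnames <- names(cfg$barriers)
  # per-site set of barriers crossed relative to site 1
  crossed <- lapply(seq_len(S), function(i) {
    if (nb == 0) return(character())
    bnames[vapply(bnames, function(b) {
      sites[[paste0("side_", b)]][i] != sites[[paste0("side_", b)]][1]
    }, logical(1))]
  })
  key_of <- function(set) if (length(set) == 0) "." else paste(set, collapse = "+")
  region_key <- vapply(crossed, key_of, character(1))
  if (is.null(dist)) {
    dist <- geosphere::distm(cbind(sites$lon, sites$lat))
  }
  corr <- if (is.finite(cfg$ibd_scale)) exp(-dist / cfg$ibd_scale) else diag(S)
  ch <- chol(corr + diag(1e-8, S))
  L <- cfg$n_loci
  anc <- stats::runif(L, 0.05, 0.95)
  # regional frequencies: sequential BN drift along each region's
  # crossing set, shared between regions with a common prefix
  keys <- unique(region_key)
  preg <- matrix(NA_real_, L, length(keys), dimnames = list(NULL, keys))
  freq_cache <- list("." = anc)
  for (k in keys) {
    set <- if (k == ".") character() else strsplit(k, "+", fixed = TRUE)[[1]]
    for (d in seq_along(set)) {
      kk <- key_of(set[seq_len(d)])
      if (is.null(freq_cache[[kk]])) {
        parent <- pmin(pmax(freq_cache[[key_of(set[seq_len(d - 1)])]], 1e-6), 1 - 1e-6)
        freq_cache[[kk]] <- rbn(parent, cfg$barriers[[set[d]]])
      }
    }
    preg[, k] <- freq_cache[[k]]
  }
  # site frequencies: correlated Gaussian copula into the BN Beta
  z <- matrix(stats::rnorm(L * S), L, S) %*% ch
  u <- stats::pnorm(z)
  psite <- matrix(NA_real_, L, S)
  f <- cfg$f_site
  for (s in seq_len(S)) {
    pr <- pmin(pmax(preg[, region_key[s]], 1e-3), 1 - 1e-3)
    psite[, s] <- if (f <= 0) pr else {
      # qbeta is imprecise deep in the tails for near-fixed frequencies;
      # those loci are effectively monomorphic either way
      suppressWarnings(
        pmin(pmax(stats::qbeta(u[, s], pr * (1 - f) / f, (1 - pr) * (1 - f) / f), 0), 1)
      )
    }
  }
  n_ind <- cfg$n_ind
  calls <- matrix(NA_integer_, S * n_ind, L)
  for (s in seq_len(S)) {
    rows <- (s - 1) * n_ind + seq_len(n_ind)
    calls[rows, ] <- matrix(
      stats::rbinom(n_ind * L, 2, rep(psite[, s], each = n_ind)), n_ind, L
    )
  }
  if (cfg$missing_rate > 0) {
    calls[stats::runif(length(calls)) < cfg$missing_rate] <- NA_integer_
  }
  ind <- as.vector(vapply(seq_len(S), function(s) {
    sprintf("%s_i%02d", sites$site[s], seq_len(n_ind))
  }, character(n_ind)))
  rownames(calls) <- ind
  colnames(calls) <- sprintf("L%05d", seq_len(L))
  geno(calls, tibble::tibble(individual = ind,
                             site = rep(sites$site, each = n_ind)))
}

#' Simulate a neutral (or spiked) per-locus FST panel
#'
#' Draws per-locus FST values from the chi-square null
#' FST ~ FSTbar * chi2(df) / df, optionally replacing a fraction of loci
#' with values inflated by `outlier_multiplier`, and heterozygosities
#' from Uniform(0.05, 0.5) so the He > 0.1 filter of the outlier scan is
#' exercised.
#'
#' @param df chi-square degrees of freedom (> 0).
#' @param fstbar mean neutral FST in (0, 1).
#' @param L number of loci.
#' @param outlier_fraction fraction of loci drawn from the inflated class.
#' @param outlier_multiplier FST multiplier of that class (> 1).
#' @param seed integer seed.
#' @return Tibble (`locus`, `he`, `fst`, `true_outlier`).
#' @export
simulate_neutral_fst_panel <- function(df, fstbar, L,
                                       outlier_fraction = 0,
                                       outlier_multiplier = 5, seed = 1) {
  stopifnot(df > 0, fstbar > 0, fstbar < 1)
  if (outlier_fraction > 0 && outlier_multiplier <= 1) {
    warning("outlier_multiplier <= 1: outlier class indistinguishable from the null")
  }
  set.seed(seed)
  is_out <- stats::runif(L) < outlier_fraction
  fst <- fstbar * stats::rchisq(L, df) / df
  fst[is_out] <- outlier_multiplier * fstbar * stats::rchisq(sum(is_out), df) / df
  tibble::tibble(
    locus = sprintf("L%06d", seq_len(L)),
    he = stats::runif(L, 0.05, 0.5),
    fst = fst,
    true_outlier = is_out
  )
}

#' Write the synthetic inputs in the pipeline's file formats
#'
#' Emits the VCF, population map CSV, site CSV, environmental CSV and
#' land-sea raster text that [read_genotypes()] and friends consume.
#'
#' @param sea result of [simulate_seascape()].
#' @param g a [geno] from [simulate_genotypes()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the file paths written.
#' @export
write_seascape_inputs <- function(sea, g, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    vcf = file.path(dir, "genotypes.vcf"),
    popmap = file.path(dir, "popmap.csv"),
    sites = file.path(dir, "sites.csv"),
    env = file.path(dir, "env.csv"),
    raster = file.path(dir, "landsea.asc")
  )
  write_vcf(g, paths["vcf"])
  readr::write_csv(g$pop_map, paths["popmap"])
  readr::write_csv(sea$sites, paths["sites"])
  readr::write_csv(sea$env, paths["env"])
  write_ascii_raster(sea$raster, paths["raster"])
  paths
}
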