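#' Land/sea raster in ESRI ASCII grid layout
#'
#' A `sea_raster` is a logical matrix (`TRUE` = water) with lower-left
#' corner registration: `xll`, `yll` in decimal degrees and a square
#' `cellsize` in degrees. Row 1 of the matrix is the northernmost row,
#' matching the ASCII grid convention.
#'
#' @param water logical matrix, rows north-to-south.
#' @param xll,yll lower-left corner of the grid (degrees).
#' @param cellsize cell edge in degrees (> 0).
#' @return An object of class `sea_raster`.
#' @export
sea_raster <- function(water, xll, yll, cellsize) {
  stopifnot(is.matrix(water), cellsize > 0)
  if (!any(water)) stop("raster contains no water cells")
  structure(list(water = water, xll = xll, yll = yll, cellsize = cellsize),
            class = "sea_raster")
}

#' @export
print.sea_raster <- function(x, ...) {
  cat(sprintf("<sea_raster> %d x %d cells (%.3f deg), %.1f%% water\n",
              nrow(x$water), ncol(x$water), x$cellsize, 100 * mean(x$water)))
  invisible(x)
}

#' Read / write a land-sea mask as ESRI ASCII grid text
#'
#' Grid values 1 mark water and 0 land; `nodata` cells are treated as land.
#'
#' @param path file path.
#' @return [read_ascii_raster()]: a [sea_raster]. [write_ascii_raster()]:
#'   `path`, invisibly.
#' @export
read_ascii_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- 0
  sea_raster(m == 1, hdr$xllcorner, hdr$yllcorner, hdr$cellsize)
}

#' @rdname read_ascii_raster
#' @param r a [sea_raster].
#' @export
write_ascii_raster <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(r$water)),
    paste("nrows", nrow(r$water)),
    paste("xllcorner", r$xll),
    paste("yllcorner", r$yll),
    paste("cellsize", r$cellsize),
    "NODATA_value -9999"
  ), con)
  utils::write.table(1 * r$water, con, sep = " ", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

cell_lon <- function(r, col) r$xll + (col - 0.5) * r$cellsize
cell_lat <- function(r, row) r$yll + (nrow(r$water) - row + 0.5) * r$cellsize

# Edge list of the water-cell graph: 8-connected, great-circle weights,
# diagonal steps allowed only when both orthogonal neighbours are water
# (prevents corner-cutting through land).
raster_graph <- function(r) {
  w <- r$water
  nr <- nrow(w); nc <- ncol(w)
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  add_edges <- function(r1, c1, r2, c2) {
    ok <- w[cbind(r1, c1)] & w[cbind(r2, c2)]
    if (!any(ok)) return(NULL)
    cbind(id[cbind(r1, c1)][ok], id[cbind(r2, c2)][ok])
  }
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  rr <- grid$row; cc <- grid$col
  # east
  e <- cc < nc
  edges$e <- add_edges(rr[e], cc[e], rr[e], cc[e] + 1)
  # south
  s <- rr < nr
  edges$s <- add_edges(rr[s], cc[s], rr[s] + 1, cc[s])
  # diagonals, gated on both orthogonal neighbours
  d1 <- rr < nr & cc < nc
  ok1 <- d1 & w[cbind(pmin(rr + 1, nr), cc)] & w[cbind(rr, pmin(cc + 1, nc))]
  edges$se <- add_edges(rr[ok1], cc[ok1], rr[ok1] + 1, cc[ok1] + 1)
  d2 <- rr < nr & cc > 1
  ok2 <- d2 & w[cbind(pmin(rr + 1, nr), cc)] & w[cbind(rr, pmax(cc - 1, 1))]
  edges$sw <- add_edges(rr[ok2], cc[ok2], rr[ok2] + 1, cc[ok2] - 1)
  em <- do.call(rbind, edges)
  if (is.null(em)) em <- matrix(integer(), ncol = 2)
  row_of <- function(i) ((i - 1) %% nr) + 1
  col_of <- function(i) ((i - 1) %/% nr) + 1
  wts <- geosphere::distHaversine(
    cbind(cell_lon(r, col_of(em[, 1])), cell_lat(r, row_of(em[, 1]))),
    cbind(cell_lon(r, col_of(em[, 2])), cell_lat(r, row_of(em[, 2])))
  )
  list(edges = em, weights = wts, n = nr * nc, nr = nr)
}

snap_to_water <- function(r, lon, lat, site, max_cells = 3) {
  nr <- nrow(r$water)
  col0 <- (lon - r$xll) / r$cellsize + 0.5
  row0 <- nr - (lat - r$yll) / r$cellsize + 0.5
  wet <- which(r$water, arr.ind = TRUE)
  d2 <- (wet[, 1] - row0)^2 + (wet[, 2] - col0)^2
  best <- which.min(d2)
  if (sqrt(d2[best]) > max_cells) {
    stop(sprintf("site '%s' is more than %d cells from water", site, max_cells))
  }
  (wet[best, 2] - 1) * nr + wet[best, 1]
}

#' Least-cost within-water geographic distance between sites
#'
#' Sites are snapped to the nearest water cell (within `snap_max_cells`
#' cells) and pairwise shortest-path lengths are computed over the
#' 8-connected water-cell graph with great-circle (haversine) edge
#' weights, in meters. Diagonal moves are disallowed when they would cut
#' a land corner.
#'
#' @param raster a [sea_raster].
#' @param sites data frame with columns `site`, `lon`, `lat`.
#' @param snap_max_cells snapping tolerance in cells.
#' @return Labeled symmetric site x site matrix of distances in meters;
#'   pairs in disconnected water bodies are `Inf` with a warning.
#' @export
least_cost_distance <- function(raster, sites, snap_max_cells = 3) {
  sites <- tibble::as_tibble(sites)
  stopifnot(all(c("site", "lon", "lat") %in% names(sites)))
  gr <- raster_graph(raster)
  g <- igraph::make_empty_graph(n = gr$n, directed = FALSE)
  g <- igraph::add_edges(g, t(gr$edges))
  igraph::E(g)$weight <- gr$weights
  nodes <- vapply(seq_len(nrow(sites)), function(i) {
    snap_to_water(raster, sites$lon[i], sites$lat[i], sites$site[i], snap_max_cells)
  }, numeric(1))
  D <- igraph::distances(g, v = nodes, to = nodes, algorithm = "dijkstra")
  dimnames(D) <- list(sites$site, sites$site)
  diag(D) <- 0
  if (any(is.infinite(D))) warning("some site pairs lie in disconnected water bodies (distance Inf)")
  D
}

#' PCA of environmental variables on the correlation matrix
#'
#' Variables are log-transformed and standardized to zero mean and unit
#' variance before the decomposition (i.e., a correlation-matrix PCA).
#' Variables that are not strictly positive are shifted by a small
#' offset before the log; constant variables are dropped with a warning.
#'
#' @param env data frame: first column `site`, remaining columns numeric
#'   environmental variables.
#' @return An object of class `env_pca` with elements `scores` (tibble),
#'   `loadings` (matrix), `var_frac`, `dropped`.
#' @export
env_pca <- function(env) {
  env <- tibble::as_tibble(env)
  site <- env[[1]]
  x <- as.matrix(env[, -1, drop = FALSE])
  if (nrow(x) < 3) stop("need at least three sites")
  nonpos <- apply(x, 2, function(v) any(v <= 0))
  for (j in which(nonpos)) {
    posmin <- min(x[x[, j] > 0, j], Inf)
    eps <- if (is.finite(posmin)) 1e-6 * posmin else 1e-6
    x[, j] <- x[, j] - min(x[, j]) + eps
  }
  lx <- log(x)
  sds <- apply(lx, 2, stats::sd)
  dropped <- colnames(lx)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping constant variable(s): ", paste(dropped, collapse = ", "))
    lx <- lx[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(lx, center = TRUE, scale. = TRUE)
  out <- list(
    scores = dplyr::bind_cols(tibble::tibble(site = site), tibble::as_tibble(pc$x)),
    loadings = pc$rotation,
    var_frac = pc$sdev^2 / sum(pc$sdev^2),
    dropped = dropped
  )
  class(out) <- "env_pca"
  out
}

#' @export
print.env_pca <- function(x, ...) {
  cat(sprintf("<env_pca> %d sites, %d components\n", nrow(x$scores), length(x$var_frac)))
  cat("  variance fractions:", paste(sprintf("%.3f", utils::head(x$var_frac, 5)), collapse = " "), "\n")
  invisible(x)
}

#' Pairwise environmental distance in PCA space
#'
#' Euclidean distance between site scores over the retained leading
#' components. By default the smallest leading set whose cumulative
#' variance fraction reaches `cum_var` is retained.
#'
#' @param pca an [env_pca] result.
#' @param n_components fixed number of components to retain (overrides
#'   `cum_var` when given).
#' @param cum_var cumulative-variance threshold for the default rule.
#' @return Labeled symmetric site x site distance matrix.
#' @export
env_distance <- function(pca, n_components = NULL, cum_var = 0.85) {
  k <- if (!is.null(n_components)) n_components else {
    which(cumsum(pca$var_frac) >= cum_var)[1]
  }
  if (is.na(k) || k < 1) stop("retention rule selects zero components")
  sc <- as.matrix(pca$scores[, 1 + seq_len(k), drop = FALSE])
  D <- as.matrix(stats::dist(sc))
  dimnames(D) <- list(pca$scores$site, pca$scores$site)
  attr(D, "n_components") <- k
  D
}

#' Barrier variables: pairwise counts of separating barriers
#'
#' For each non-empty subset of the named barriers (2^B - 1 subsets), a
#' site x site matrix whose entry counts how many barriers in the subset
#' separate the pair (sites on different recorded sides). Single-barrier
#' variables are 0/1; the full three-barrier variable takes levels 0-3.
#'
#' @param sites data frame with a `site` column and one `side_<barrier>`
#'   column per barrier (arbitrary side labels).
#' @param barriers character vector of barrier names, e.g. `c("b1","b2","b3")`.
#' @return Named list of labeled symmetric integer matrices; names are
#'   subset labels like `"b1"`, `"b1+b2"`.
#' @export
barrier_variables <- function(sites, barriers) {
  sites <- tibble::as_tibble(sites)
  cols <- paste0("side_", barriers)
  miss <- setdiff(cols, names(sites))
  if (length(miss) > 0) stop("missing side columns: ", paste(miss, collapse = ", "))
  for (co in cols) {
    if (anyNA(sites[[co]])) {
      stop(sprintf("site '%s' lacks a side label for barrier '%s'",
                   sites$site[which(is.na(sites[[co]]))[1]], sub("^side_", "", co)))
    }
  }
  diff_mats <- lapply(cols, function(co) {
    v <- sites[[co]]
    outer(v, v, FUN = `!=`) * 1L
  })
  names(diff_mats) <- barriers
  subsets <- unlist(lapply(seq_along(barriers), function(k) {
    utils::combn(barriers, k, simplify = FALSE)
  }), recursive = FALSE)
  out <- lapply(subsets, function(ss) {
    m <- Reduce(`+`, diff_mats[ss])
    dimnames(m) <- list(sites$site, sites$site)
    m
  })
  names(out) <- vapply(subsets, paste, character(1), collapse = "+")
  out
}
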