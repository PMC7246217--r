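#' Genotype matrix with population map
#'
#' A `geno` object holds diploid biallelic SNP calls as an integer matrix of
#' alternate-allele counts (0, 1, 2, `NA` for missing) with individuals in
#' rows and loci in columns, plus a population map assigning every
#' individual to a sampling site.
#'
#' @param calls integer matrix, individuals x loci; entries 0/1/2/NA.
#'   Must carry row and column names (individual and locus identifiers).
#' @param pop_map data frame with columns `individual` and `site` covering
#'   every row of `calls`.
#' @return An object of class `geno`.
#' @export
geno <- function(calls, pop_map) {
  stopifnot(is.matrix(calls), !is.null(rownames(calls)))
  if (is.null(colnames(calls))) {
    if (ncol(calls) > 0) stop("calls must carry locus identifiers as column names")
    colnames(calls) <- character(0)
  }
  bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
  if (length(bad) > 0) {
    stop("non-missing calls must be 0, 1 or 2; found: ", paste(utils::head(bad), collapse = ", "))
  }
  if (anyDuplicated(colnames(calls))) stop("locus identifiers must be unique")
  pop_map <- tibble::as_tibble(pop_map)
  if (!all(c("individual", "site") %in% names(pop_map))) {
    stop("pop_map needs columns 'individual' and 'site'")
  }
  missing_ind <- setdiff(rownames(calls), pop_map$individual)
  if (length(missing_ind) > 0) {
    stop("individuals absent from population map: ", paste(missing_ind, collapse = ", "))
  }
  if (anyDuplicated(pop_map$individual)) stop("each individual must map to exactly one site")
  pop_map <- pop_map[match(rownames(calls), pop_map$individual), , drop = FALSE]
  structure(list(calls = calls, pop_map = pop_map), class = "geno")
}

#' @export
print.geno <- function(x, ...) {
  cat(sprintf(
    "<geno> %d individuals x %d loci, %d sites, %.1f%% missing\n",
    nrow(x$calls), ncol(x$calls), dplyr::n_distinct(x$pop_map$site),
    100 * mean(is.na(x$calls))
  ))
  invisible(x)
}

#' @export
dim.geno <- function(x) dim(x$calls)

sites_of <- function(g) {
  stats::setNames(g$pop_map$site, g$pop_map$individual)[rownames(g$calls)]
}

#' Read genotypes from a VCF and a population map
#'
#' Expects a VCF 4.x with biallelic SNP records and a GT field; genotypes
#' are encoded as alternate-allele counts. Multi-allelic records are
#' rejected. The population map is a CSV with two columns
#' (individual, site); a header row is detected automatically.
#'
#' @param vcf_path path to a VCF (optionally gzipped).
#' @param popmap_path path to the population-map CSV.
#' @return A [geno] object.
#' @export
read_genotypes <- function(vcf_path, popmap_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi)) {
    ids <- v@fix[multi, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(v@fix[multi, "CHROM"], ":", v@fix[multi, "POS"])[is.na(ids) | ids == "."]
    stop("multi-allelic records not supported: ", paste(utils::head(ids, 5), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  calls <- gt_to_counts(gt)           # loci x individuals
  ids <- v@fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(v@fix[blank, "CHROM"], ":", v@fix[blank, "POS"])
  rownames(calls) <- ids
  calls <- t(calls)
  pop_map <- read_popmap(popmap_path)
  absent <- setdiff(rownames(calls), pop_map$individual)
  if (length(absent) > 0) {
    stop("samples absent from population map: ", paste(absent, collapse = ", "))
  }
  geno(calls, pop_map)
}

gt_to_counts <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  out <- suppressWarnings(as.integer(a1) + as.integer(a2))
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

read_popmap <- function(path) {
  first <- readr::read_csv(path, col_names = FALSE, n_max = 1,
                           show_col_types = FALSE, progress = FALSE)
  has_header <- all(tolower(unlist(first[1, 1:2])) %in% c("individual", "site", "sample", "pop", "population"))
  pm <- readr::read_csv(path, col_names = has_header, show_col_types = FALSE, progress = FALSE)
  names(pm)[1:2] <- c("individual", "site")
  tibble::as_tibble(pm[, 1:2])
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Emits one biallelic SNP record per locus with a GT-only FORMAT field,
#' suitable for round-tripping through [read_genotypes()].
#'
#' @param g a [geno] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  calls <- g$calls
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  enc <- matrix("./.", nrow = ncol(calls), ncol = nrow(calls))
  idx <- !is.na(t(calls))
  enc[idx] <- gt_codes[as.character(t(calls)[idx])]
  body <- data.frame(
    CHROM = "1", POS = seq_len(ncol(calls)), ID = colnames(calls),
    REF = "A", ALT = "T", QUAL = ".", FILTER = "PASS", INFO = ".",
    FORMAT = "GT", check.names = FALSE
  )
  body <- cbind(body, as.data.frame(enc, check.names = FALSE) |>
                  stats::setNames(rownames(calls)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=seascapr",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#", paste(names(body), collapse = "\t"))
  ), con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter loci by minor allele frequency, presence and call rate
#'
#' Retains loci whose overall minor-allele frequency strictly exceeds
#' `maf_min` and that are genotyped in at least `call_rate_min` of the
#' individuals within at least `min_pops_present` populations. Defaults
#' mirror common RAD-seq practice: MAF > 0.05, call rate 0.8 in at least
#' n - 1 populations.
#'
#' @param g a [geno] object.
#' @param maf_min minor-allele-frequency threshold (strict `>`).
#' @param call_rate_min within-population call-rate threshold (`>=`).
#' @param min_pops_present number of populations that must meet the call
#'   rate; default one fewer than the number of populations.
#' @return A [geno] with the surviving loci, order preserved. If no locus
#'   survives, a zero-column `geno` with attribute `empty = TRUE`.
#' @export
filter_loci <- function(g, maf_min = 0.05, call_rate_min = 0.8,
                        min_pops_present = NULL) {
  site <- sites_of(g)
  pops <- unique(site)
  if (is.null(min_pops_present)) min_pops_present <- max(length(pops) - 1L, 1L)
  calls <- g$calls
  p <- colMeans(calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  ok_maf <- maf > maf_min

  called <- !is.na(calls)
  pass_by_pop <- vapply(pops, function(s) {
    m <- called[site == s, , drop = FALSE]
    as.numeric(colMeans(m) >= call_rate_min)
  }, numeric(ncol(calls)))
  n_pass <- rowSums(matrix(pass_by_pop, nrow = ncol(calls)))
  keep <- ok_maf & (n_pass >= min_pops_present)
  out <- geno(calls[, keep, drop = FALSE], g$pop_map)
  if (!any(keep)) {
    warning("no loci survive filtering")
    attr(out, "empty") <- TRUE
  }
  out
}

#' Merge two genotype matrices on their shared loci
#'
#' Used to combine closely related species on the SNPs they share: the
#' result carries the locus intersection and the union of individuals,
#' with per-individual provenance recorded in the population map.
#'
#' @param g1,g2 [geno] objects with comparable locus identifiers.
#' @param sources length-2 character giving provenance labels.
#' @return A [geno]; its `pop_map` gains a `source` column.
#' @export
merge_shared_loci <- function(g1, g2, sources = c("set1", "set2")) {
  shared <- intersect(colnames(g1$calls), colnames(g2$calls))
  if (length(shared) == 0) stop("no shared loci between the two data sets")
  dup <- intersect(rownames(g1$calls), rownames(g2$calls))
  if (length(dup) > 0) stop("individual identifiers occur in both sets: ", paste(dup, collapse = ", "))
  calls <- rbind(g1$calls[, shared, drop = FALSE], g2$calls[, shared, drop = FALSE])
  pm <- dplyr::bind_rows(
    dplyr::mutate(g1$pop_map, source = sources[1]),
    dplyr::mutate(g2$pop_map, source = sources[2])
  )
  geno(calls, pm)
}
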