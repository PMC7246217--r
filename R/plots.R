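#' @export
#' @importFrom ggplot2 autoplot
ggplot2::autoplot

#' @export
autoplot.env_pca <- function(object, axes = c(1, 2), ...) {
  sc <- object$scores
  xs <- paste0("PC", axes[1]); ys <- paste0("PC", axes[2])
  ggplot2::ggplot(sc, ggplot2::aes(.data[[xs]], .data[[ys]], label = .data$site)) +
    ggplot2::geom_point(color = "steelblue", size = 2) +
    ggplot2::geom_text(nudge_y = 0.15, size = 3) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", xs, 100 * object$var_frac[axes[1]]),
      y = sprintf("%s (%.0f%%)", ys, 100 * object$var_frac[axes[2]]),
      title = "Environmental PCA of sampling sites"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.geno_pca <- function(object, axes = c(1, 2), ...) {
  xs <- paste0("PC", axes[1]); ys <- paste0("PC", axes[2])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data[[xs]], .data[[ys]], color = .data$site)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("%s (%.0f%%)", xs, 100 * object$var_frac[axes[1]]),
      y = sprintf("%s (%.0f%%)", ys, 100 * object$var_frac[axes[2]]),
      title = "Genotype PCA"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.outlier_fit <- function(object, ...) {
  if (is.null(object$loci)) stop("run outlier_pvalues() first")
  ggplot2::ggplot(object$loci, ggplot2::aes(.data$he, .data$fst, color = .data$outlier)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = object$fstbar, linetype = 2) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "heterozygosity", y = "FST",
                  title = sprintf("FST outlier scan (df = %.1f, FSTbar = %.3f)",
                                  object$df, object$fstbar)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.jsfs <- function(object, ...) {
  df <- tidyr::expand_grid(i = 0:attr(object, "n1"), j = 0:attr(object, "n2"))
  df$value <- as.numeric(unclass(object)[cbind(df$i + 1, df$j + 1)])
  df$masked <- attr(object, "mask")[cbind(df$i + 1, df$j + 1)]
  df$value[df$masked] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$i, .data$j, fill = log10(.data$value + 1e-12))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10 mass", na.value = "white") +
    ggplot2::labs(x = "minor allele count, population 1",
                  y = "minor allele count, population 2",
                  title = "Folded joint site frequency spectrum") +
    ggplot2::theme_minimal()
}

#' Heat map of a labeled site-by-site distance matrix
#'
#' @param D labeled symmetric matrix (e.g., pairwise FST).
#' @param name legend title.
#' @return A ggplot object.
#' @export
plot_distance_matrix <- function(D, name = "distance") {
  df <- tidyr::expand_grid(a = rownames(D), b = colnames(D))
  df$value <- as.numeric(D[cbind(df$a, df$b)])
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = name) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Model-ranking plot: Akaike weights of the top candidate models
#'
#' @param ranking an `mmrr_ranking` from [rank_models()].
#' @param top number of models to show.
#' @return A ggplot object.
#' @export
plot_model_weights <- function(ranking, top = 15) {
  df <- utils::head(tibble::as_tibble(ranking), top)
  df$model <- factor(df$model, levels = rev(df$model))
  ggplot2::ggplot(df, ggplot2::aes(.data$weight, .data$model)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Akaike weight", y = NULL,
                  title = "Candidate models ranked by AICc") +
    ggplot2::theme_minimal()
}
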