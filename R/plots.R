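#' Plot the RMT threshold scan
#'
#' Poisson goodness-of-fit p-value against the correlation cutoff, with the
#' rejection level and the chosen threshold marked.
#'
#' @param object An `rmt_scan`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rmt_scan <- function(object, ...) {
  df <- filter(object$scan, !is.na(.data$p_poisson))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cutoff, y = .data$p_poisson)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = object$settings$alpha,
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$r_star, colour = "red") +
    ggplot2::labs(x = "correlation cutoff",
                  y = "Poisson spacing GOF p-value",
                  title = sprintf("RMT threshold scan (r* = %.2f)",
                                  object$r_star)) +
    ggplot2::theme_minimal()
}

#' Plot HMM category counts
#'
#' @param object A `tn_hmm_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tn_hmm_fit <- function(object, ...) {
  df <- count(object$calls, call = factor(.data$call, levels = hmm_states))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$call, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "fitness category", y = "genes",
                  title = "HMM essentiality calls") +
    ggplot2::theme_minimal()
}

#' Plot the degree distribution of a cofitness network
#'
#' @param object A `cofitness_graph`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cofitness_graph <- function(object, ...) {
  df <- tibble(k = as.numeric(igraph::degree(object$graph)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::labs(x = "connectivity degree", y = "nodes",
                  title = sprintf("Cofitness degree distribution (r* = %.2f)",
                                  object$r_star)) +
    ggplot2::theme_minimal()
}

#' Fitness distributions by category
#'
#' Violin/box plot of Monte Carlo log2 fold-change fitness values grouped by
#' a category column (e.g. the HMM call), the standard view for checking the
#' ES < GA < NE < GD fitness ordering.
#'
#' @param fitness Fitness tibble from [gene_fitness()].
#' @param calls Calls tibble with `gene_id` and a category column.
#' @param category Name of the category column in `calls`.
#' @return A ggplot.
#' @export
plot_fitness_by_category <- function(fitness, calls, category = "call") {
  df <- inner_join(fitness, calls, by = "gene_id")
  df$cat <- factor(df[[category]],
                   levels = intersect(hmm_states, unique(df[[category]])))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cat, y = .data$log2fc)) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_boxplot(width = 0.15, outlier.size = 0.5) +
    ggplot2::labs(x = "fitness category", y = "fitness (log2 fold change)") +
    ggplot2::theme_minimal()
}
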