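#' Tidiers for pantnfit result objects
#'
#' `tidy()` returns the per-unit result table (gene calls, scan rows, node
#' metrics, pairwise comparisons); `glance()` returns a one-row model-level
#' summary.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name pantnfit-tidiers
NULL

#' @rdname pantnfit-tidiers
#' @export
tidy.tn_hmm_fit <- function(x, ...) x$calls

#' @rdname pantnfit-tidiers
#' @export
glance.tn_hmm_fit <- function(x, ...) {
  tab <- table(factor(x$calls$call, levels = hmm_states))
  tibble(
    n_genes = nrow(x$calls), n_sites = nrow(x$states),
    n_ES = as.integer(tab[["ES"]]), n_GA = as.integer(tab[["GA"]]),
    n_NE = as.integer(tab[["NE"]]), n_GD = as.integer(tab[["GD"]]),
    epsilon = x$params$epsilon,
    mean_NE = unname(x$params$state_means[["NE"]])
  )
}

#' @rdname pantnfit-tidiers
#' @export
tidy.tn_gumbel_fit <- function(x, ...) x$calls

#' @rdname pantnfit-tidiers
#' @export
glance.tn_gumbel_fit <- function(x, ...) {
  tab <- table(factor(x$calls$category,
                      levels = c("ES", "Uncertain", "NE", "TooShort")))
  tibble(
    n_genes = nrow(x$calls), q_hat = x$q_hat,
    n_ES = as.integer(tab[["ES"]]),
    n_Uncertain = as.integer(tab[["Uncertain"]]),
    n_NE = as.integer(tab[["NE"]]),
    n_TooShort = as.integer(tab[["TooShort"]]),
    iters = x$settings$iters
  )
}

#' @rdname pantnfit-tidiers
#' @export
tidy.rmt_scan <- function(x, ...) x$scan

#' @rdname pantnfit-tidiers
#' @export
glance.rmt_scan <- function(x, ...) {
  tibble(r_star = x$r_star, alpha = x$settings$alpha,
         min_size = x$settings$min_size,
         n_cutoffs = nrow(x$scan))
}

#' @rdname pantnfit-tidiers
#' @export
tidy.cofitness_graph <- function(x, ...) node_metrics(x)

#' @rdname pantnfit-tidiers
#' @export
glance.cofitness_graph <- function(x, ...) {
  tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    r_star = x$r_star,
    edge_density = igraph::edge_density(x$graph)
  )
}

#' @rdname pantnfit-tidiers
#' @export
tidy.tn_tukey <- function(x, ...) x$comparisons

#' @rdname pantnfit-tidiers
#' @export
glance.tn_tukey <- function(x, ...) {
  tibble(n_groups = nrow(x$letters), alpha = x$alpha,
         n_significant = sum(x$comparisons$p_adj < x$alpha))
}
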