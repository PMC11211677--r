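#' Pairwise Pearson cofitness matrix
#'
#' Pearson correlation of per-orthogroup fitness profiles across strain
#' columns, with exact symmetry enforced and unit diagonal.
#'
#' @param fm Core fitness matrix from [core_fitness_matrix()].
#' @return Symmetric numeric matrix (orthogroups x orthogroups) with
#'   dimnames from `orthogroup_id`.
#' @export
pearson_matrix <- function(fm) {
  strains <- attr(fm, "strains") %||%
    names(fm)[vapply(fm, is.numeric, logical(1))]
  if (length(strains) < 3) abort("Pearson matrix needs >= 3 strain columns.")
  vals <- as.matrix(fm[, strains])
  rownames(vals) <- fm$orthogroup_id
  if (any(apply(vals, 1, sd) == 0)) {
    abort("constant fitness row: filter upstream with core_fitness_matrix().")
  }
  m <- cor(t(vals))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Threshold a correlation matrix for spectral analysis
#'
#' Keeps entries with `r >= cutoff` (or `|r| >= cutoff` when
#' `absolute = TRUE`), zeroes the rest, restores a unit diagonal, and drops
#' rows/columns without any surviving off-diagonal entry.
#' @noRd
threshold_matrix <- function(corr, cutoff, absolute = FALSE) {
  keep <- if (absolute) abs(corr) >= cutoff else corr >= cutoff
  m <- corr
  m[!keep] <- 0
  diag(m) <- 1
  off <- (m != 0)
  diag(off) <- FALSE
  sel <- rowSums(off) > 0
  m[sel, sel, drop = FALSE]
}

#' Nearest-neighbour spacing distribution of a thresholded matrix
#'
#' Eigenvalues are computed, the spectrum is unfolded by fitting a cubic
#' smoothing spline to the empirical cumulative eigenvalue density evaluated
#' at `n_support` uniformly spaced support points, and spacings are the
#' consecutive differences of the unfolded eigenvalues, normalized to unit
#' mean.
#'
#' @param m Symmetric matrix (typically a thresholded correlation submatrix).
#' @param min_size Smallest admissible matrix size.
#' @param n_support Support points for the smoothing-spline unfolding.
#' @return Numeric vector of spacings with `mean(s) == 1`.
#' @export
nnsd <- function(m, min_size = 100, n_support = 21) {
  if (nrow(m) < min_size) {
    abort(sprintf("matrix of size %d is below the NNSD size floor (%d).",
                  nrow(m), min_size))
  }
  ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  n <- length(ev)
  sup <- seq(min(ev), max(ev), length.out = n_support)
  cum <- vapply(sup, function(x) sum(ev <= x), numeric(1))
  fit <- smooth.spline(sup, cum)
  unfolded <- predict(fit, ev)$y
  s <- diff(unfolded)
  s <- s[s >= 0]  # guard against tiny non-monotonicities of the spline
  s / mean(s)
}

#' Kolmogorov distance of a spacing sample to a reference law
#'
#' Reference laws: Poisson spacings \eqn{P(s) = e^{-s}} (independent levels)
#' and the Wigner surmise \eqn{P(s) = (\pi s/2) e^{-\pi s^2/4}} (GOE level
#' repulsion).
#'
#' @param s Spacing sample from [nnsd()].
#' @param reference `"poisson"` or `"wigner"`.
#' @return Supremum distance between the empirical CDF of `s` and the
#'   reference CDF.
#' @export
nnsd_distance <- function(s, reference = c("poisson", "wigner")) {
  reference <- match.arg(reference)
  ref_cdf <- switch(reference,
    poisson = function(x) 1 - exp(-x),
    wigner = function(x) 1 - exp(-pi * x^2 / 4)
  )
  x <- sort(s)
  n <- length(x)
  emp_hi <- seq_len(n) / n
  emp_lo <- (seq_len(n) - 1) / n
  max(abs(emp_hi - ref_cdf(x)), abs(emp_lo - ref_cdf(x)))
}

#' Chi-square goodness of fit of spacings against Poisson
#'
#' Bins of width `bin_width` on [0, 3] plus a pooled tail; expected counts
#' from \eqn{P(s) = e^{-s}}.
#' @noRd
nnsd_poisson_gof <- function(s, bin_width = 0.1, upper = 3) {
  breaks <- c(seq(0, upper, by = bin_width), Inf)
  obs <- table(cut(s, breaks = breaks, right = TRUE, include.lowest = TRUE))
  p <- exp(-breaks[-length(breaks)]) - exp(-breaks[-1])
  exp_cnt <- length(s) * p
  stat <- sum((as.numeric(obs) - exp_cnt)^2 / exp_cnt)
  df <- length(p) - 1
  list(chisq = stat, df = df,
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' RMT-based correlation-threshold scan
#'
#' For each cutoff on the grid, the correlation matrix is thresholded, the
#' nearest-neighbour spacing distribution of the surviving submatrix is
#' computed, and a chi-square goodness-of-fit against Poisson spacings is
#' evaluated. The chosen threshold `r_star` is the smallest cutoff whose
#' Poisson fit is not rejected (p > `alpha`) and whose submatrix meets the
#' size floor - the point where the spectrum has transitioned from
#' correlated (Wigner, GOE-like) to uncorrelated (Poisson) statistics.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @param grid Increasing cutoff grid.
#' @param alpha Rejection level for the Poisson fit.
#' @param min_size Submatrix size floor for the NNSD.
#' @param absolute Threshold on `|r|` instead of signed `r`.
#' @return Object of class `rmt_scan`: list with `r_star` and `scan` (tibble
#'   `cutoff`, `size`, `chisq`, `p_poisson`, `qualifies`). Supports
#'   [tidy()], [glance()], [autoplot()].
#' @export
rmt_threshold_scan <- function(corr, grid = seq(0.5, 0.99, by = 0.01),
                               alpha = 0.05, min_size = 100,
                               absolute = FALSE) {
  if (is.unsorted(grid, strictly = TRUE)) abort("`grid` must be increasing.")
  rows <- purrr::map(grid, function(cutoff) {
    m <- threshold_matrix(corr, cutoff, absolute = absolute)
    if (nrow(m) < min_size) {
      return(tibble(cutoff = cutoff, size = nrow(m), chisq = NA_real_,
                    p_poisson = NA_real_, qualifies = FALSE))
    }
    s <- nnsd(m, min_size = min_size)
    g <- nnsd_poisson_gof(s)
    tibble(cutoff = cutoff, size = nrow(m), chisq = g$chisq,
           p_poisson = g$p, qualifies = g$p > alpha)
  })
  scan <- bind_rows(rows)
  hit <- which(scan$qualifies)
  if (length(hit) == 0) {
    abort("no cutoff reaches Poisson spacing statistics; widen the grid or lower `min_size`.")
  }
  structure(
    list(r_star = scan$cutoff[hit[1]], scan = scan,
         settings = list(alpha = alpha, min_size = min_size,
                         absolute = absolute)),
    class = "rmt_scan"
  )
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("RMT threshold scan: r* = %.2f (%d cutoffs scanned)\n",
              x$r_star, nrow(x$scan)))
  invisible(x)
}

#' Build the thresholded cofitness network
#'
#' Edge between two orthogroups iff their Pearson cofitness `r >= r_star`
#' (signed by default: only strong positive cofitness). All matrix genes are
#' nodes, including isolates.
#'
#' @param corr Correlation matrix.
#' @param r_star Correlation threshold in (0, 1].
#' @param absolute Use `|r|` instead of signed `r`.
#' @return Object of class `cofitness_graph`: list with `graph` (igraph),
#'   `r_star`, `edges` (tibble `gene_a`, `gene_b`, `r`).
#' @export
build_network <- function(corr, r_star, absolute = FALSE) {
  stopifnot(r_star > 0, r_star <= 1)
  keep <- if (absolute) abs(corr) >= r_star else corr >= r_star
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble(
    gene_a = rownames(corr)[idx[, 1]],
    gene_b = colnames(corr)[idx[, 2]],
    r = corr[idx]
  )
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")],
    directed = FALSE,
    vertices = rownames(corr)
  )
  structure(list(graph = g, r_star = r_star, edges = edges),
            class = "cofitness_graph")
}

#' @export
print.cofitness_graph <- function(x, ...) {
  cat(sprintf("Cofitness network: %d nodes, %d edges (r* = %.3g)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph), x$r_star))
  invisible(x)
}

#' Per-node topology metrics
#'
#' Connectivity degree `k`; average shortest path length `aspl` (mean
#' shortest-path length to reachable nodes, excluding the node itself; NA for
#' isolates); closeness centrality `closeness = 1/aspl` (0 for isolates); and
#' the topological coefficient `topo_coeff`: the mean over nodes `m != n`
#' sharing at least one neighbour with `n` of `J(n, m) / k(n)`, where
#' `J(n, m)` is the number of shared neighbours plus 1 if `n` and `m` are
#' adjacent. `topo_coeff` is 0 for nodes of degree <= 1.
#'
#' @param x A `cofitness_graph` or an igraph object.
#' @return Tibble `gene_id`, `k`, `aspl`, `closeness`, `topo_coeff`.
#' @export
node_metrics <- function(x) {
  g <- if (inherits(x, "cofitness_graph")) x$graph else x
  n <- igraph::vcount(g)
  k <- igraph::degree(g)
  d <- igraph::distances(g)
  diag(d) <- NA
  aspl <- unname(apply(d, 1, function(row) {
    fin <- row[is.finite(row)]
    if (length(fin) == 0) NA_real_ else mean(fin)
  }))
  closeness <- ifelse(is.na(aspl), 0, 1 / aspl)
  a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  shared <- a %*% a
  jmat <- shared + a
  topo <- vapply(seq_len(n), function(i) {
    if (k[i] <= 1) return(0)
    cand <- which(shared[i, ] >= 1)
    cand <- setdiff(cand, i)
    if (length(cand) == 0) return(0)
    mean(jmat[i, cand] / k[i])
  }, numeric(1))
  tibble(
    gene_id = igraph::V(g)$name,
    k = as.numeric(k),
    aspl = aspl,
    closeness = closeness,
    topo_coeff = topo
  )
}

#' Subnetwork of the strongest cofitness edges
#'
#' Keeps the top `fraction` of candidate gene pairs ranked by correlation
#' (descending, stable pair order on ties). The candidate base is either all
#' gene pairs (default; isolated genes are dropped from the result) or only
#' the pairs already retained at `r_star`.
#'
#' @param corr Correlation matrix.
#' @param fraction Fraction of candidate pairs to keep, in (0, 1].
#' @param base `"all-pairs"` or `"retained-edges"`.
#' @param r_star Threshold (required for `base = "retained-edges"`).
#' @return A `cofitness_graph` on the genes involved in the kept pairs.
#' @export
top_fraction_subnetwork <- function(corr, fraction = 0.01,
                                    base = c("all-pairs", "retained-edges"),
                                    r_star = NULL) {
  base <- match.arg(base)
  stopifnot(fraction > 0, fraction <= 1)
  ut <- which(upper.tri(corr), arr.ind = TRUE)
  r <- corr[ut]
  if (base == "retained-edges") {
    if (is.null(r_star)) abort("`r_star` required for base = 'retained-edges'.")
    sel <- r >= r_star
    ut <- ut[sel, , drop = FALSE]
    r <- r[sel]
  }
  n_keep <- max(1L, floor(fraction * length(r)))
  ord <- order(-r)  # stable: ties keep original pair order
  kept <- head(ord, n_keep)
  edges <- tibble(
    gene_a = rownames(corr)[ut[kept, 1]],
    gene_b = colnames(corr)[ut[kept, 2]],
    r = r[kept]
  )
  nodes <- unique(c(edges$gene_a, edges$gene_b))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b")], directed = FALSE, vertices = nodes
  )
  structure(list(graph = g, r_star = min(edges$r), edges = edges),
            class = "cofitness_graph")
}

#' Module (community) assignment
#'
#' Greedy modularity maximization (deterministic given the vertex order);
#' isolates end up in singleton modules. Modules are numbered by decreasing
#' size (ties by smallest member vertex index).
#'
#' @param x A `cofitness_graph` or igraph object.
#' @return Tibble `gene_id`, `module_id`.
#' @export
detect_modules <- function(x) {
  g <- if (inherits(x, "cofitness_graph")) x$graph else x
  cm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  mem <- igraph::membership(cm)
  sizes <- table(mem)
  first_member <- vapply(names(sizes), function(m) {
    min(which(mem == as.integer(m)))
  }, numeric(1))
  ord <- order(-as.numeric(sizes), first_member)
  renum <- setNames(seq_along(ord), names(sizes)[ord])
  tibble(
    gene_id = igraph::V(g)$name,
    module_id = as.integer(renum[as.character(mem)])
  )
}

#' Export a cofitness network
#'
#' Writes the edge list as TSV (`gene_a`, `gene_b`, `r`) and optionally
#' GraphML.
#'
#' @param x A `cofitness_graph`.
#' @param edge_path Path for the edge-list TSV.
#' @param graphml_path Optional path for a GraphML export.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(x, edge_path, graphml_path = NULL) {
  readr::write_tsv(x$edges, edge_path)
  if (!is.null(graphml_path)) {
    igraph::write_graph(x$graph, graphml_path, format = "graphml")
  }
  invisible(edge_path)
}
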