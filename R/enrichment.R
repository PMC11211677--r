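#' Exact hypergeometric (Fisher) enrichment of labels in a gene set
#'
#' One-sided (greater) exact hypergeometric tail per label: the probability
#' of observing at least the seen overlap between the gene set and the
#' label's genes when drawing `|set|` genes from the background. Genes with
#' multiple labels (e.g. multi-letter COG assignments) contribute once per
#' label. Odds ratios use the Haldane 0.5 correction when a cell of the 2x2
#' table is zero. p-values are Benjamini-Hochberg adjusted across labels.
#'
#' @param gene_set Character vector of genes (must be a subset of
#'   `background`).
#' @param annotation Tibble `gene_id`, `label` (one row per gene-label pair).
#' @param background Character vector: the gene universe.
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @return Tibble `label`, `k` (hits in set), `n` (set size), `K` (hits in
#'   background), `N` (background size), `odds_ratio`, `p`, `p_adj`.
#' @export
fisher_enrichment <- function(gene_set, annotation, background,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (length(background) == 0) abort("empty background.")
  if (!all(gene_set %in% background)) {
    abort("`gene_set` must be a subset of `background`.")
  }
  if (length(gene_set) == 0) {
    return(tibble(label = character(), k = integer(), n = integer(),
                  K = integer(), N = integer(), odds_ratio = numeric(),
                  p = numeric(), p_adj = numeric()))
  }
  ann <- annotation |>
    filter(.data$gene_id %in% background) |>
    distinct(.data$gene_id, .data$label)
  N <- length(unique(background))
  n <- length(unique(gene_set))
  rows <- ann |>
    group_by(.data$label) |>
    summarise(
      K = dplyr::n_distinct(.data$gene_id),
      k = dplyr::n_distinct(intersect(.data$gene_id, gene_set))
    ) |>
    ungroup()
  p_greater <- phyper(rows$k - 1, rows$K, N - rows$K, n, lower.tail = FALSE)
  p <- if (alternative == "greater") {
    p_greater
  } else {
    # two-sided by summing probabilities <= observed (fisher.test convention)
    purrr::map2_dbl(rows$k, rows$K, function(k, K) {
      supp <- max(0, n + K - N):min(n, K)
      d <- stats::dhyper(supp, K, N - K, n)
      sum(d[d <= d[supp == k] * (1 + 1e-7)])
    })
  }
  a <- rows$k
  b <- rows$K - rows$k
  c_ <- n - rows$k
  d <- N - rows$K - n + rows$k
  need_h <- a == 0 | b == 0 | c_ == 0 | d == 0
  h <- ifelse(need_h, 0.5, 0)
  or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
  tibble(
    label = rows$label, k = rows$k, n = n, K = rows$K, N = N,
    odds_ratio = or, p = pmin(1, p), p_adj = p.adjust(pmin(1, p), "BH")
  )
}

#' Permutation Z test for subset membership of a gene category
#'
#' Observed: number of category genes carrying the target subset label. Null:
#' draw `|category|` genes uniformly without replacement from the background
#' `n_sim` times and count target-subset members (the draw count is an exact
#' hypergeometric sample). The z-score against the simulated null mean/SD is
#' converted to a two-tailed Gaussian p-value.
#'
#' @param category_genes Character vector of genes in the category.
#' @param subset_labels Tibble `gene_id`, `subset` covering the background.
#' @param target_subset Subset label tested (e.g. `"I"`).
#' @param n_sim Number of random draws.
#' @param seed RNG seed.
#' @return Tibble (one row): `observed`, `null_mean`, `null_sd`, `z`,
#'   `p_two_tailed`, `n_sim`, `seed`.
#' @export
permutation_z <- function(category_genes, subset_labels, target_subset,
                          n_sim = 5000, seed = 1L) {
  bg <- unique(subset_labels$gene_id)
  if (!all(category_genes %in% bg)) {
    abort("`subset_labels` must cover every category gene.")
  }
  target <- subset_labels$gene_id[subset_labels$subset == target_subset]
  K <- length(unique(target))
  N <- length(bg)
  m <- length(unique(category_genes))
  observed <- length(intersect(unique(category_genes), target))
  sims <- with_seed_(seed, stats::rhyper(n_sim, K, N - K, m))
  null_mean <- mean(sims)
  null_sd <- sd(sims)
  if (null_sd == 0) {
    warn("degenerate null (sd = 0); p reported as 1")
    z <- 0
    p <- 1
  } else {
    z <- (observed - null_mean) / null_sd
    p <- min(1, 2 * (1 - pnorm(abs(z))))
  }
  tibble(observed = observed, null_mean = null_mean, null_sd = null_sd,
         z = z, p_two_tailed = p, n_sim = n_sim, seed = seed)
}

#' Tukey HSD multiple comparison with compact letter display
#'
#' Studentized-range pairwise comparisons at family level `alpha` (the
#' Tukey-Kramer correction applies automatically to unbalanced groups, via
#' [stats::TukeyHSD()] on a one-way [stats::aov()] fit). The compact letter
#' display assigns letters so that groups sharing a letter are not
#' significantly different: maximal cliques of the "not significantly
#' different" graph each receive one letter, ordered by descending group
#' mean.
#'
#' @param data Data frame with a numeric value column and a grouping column.
#' @param value Name of the value column.
#' @param group Name of the grouping column.
#' @param alpha Family-wise error level.
#' @return Object of class `tn_tukey`: list with `comparisons` (tibble
#'   `group1`, `group2`, `diff`, `lwr`, `upr`, `p_adj`) and `letters`
#'   (tibble `group`, `mean`, `letters`).
#' @export
tukey_hsd <- function(data, value, group, alpha = 0.05) {
  v <- data[[value]]
  g <- factor(data[[group]])
  sizes <- table(g)
  if (length(sizes) < 2) abort("Tukey HSD needs at least 2 groups.")
  if (any(sizes < 2)) abort("every group needs at least 2 values.")
  fit <- aov(v ~ g)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  comparisons <- tibble(
    group1 = vapply(nm, `[`, character(1), 1),
    group2 = vapply(nm, `[`, character(1), 2),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"]
  )
  means <- tapply(v, g, mean)
  lv <- names(sort(means, decreasing = TRUE))
  nonsig <- matrix(TRUE, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_len(nrow(comparisons))) {
    if (comparisons$p_adj[i] < alpha) {
      nonsig[comparisons$group1[i], comparisons$group2[i]] <- FALSE
      nonsig[comparisons$group2[i], comparisons$group1[i]] <- FALSE
    }
  }
  gg <- igraph::graph_from_adjacency_matrix(nonsig, mode = "undirected",
                                            diag = FALSE)
  cliques <- igraph::max_cliques(gg)
  # order cliques by the best (highest-mean) member so 'a' marks the top group
  best <- vapply(cliques, function(cl) min(match(names(cl), lv)), numeric(1))
  cliques <- cliques[order(best)]
  lett <- setNames(rep("", length(lv)), lv)
  for (i in seq_along(cliques)) {
    members <- names(cliques[[i]])
    lett[members] <- paste0(lett[members], letters[i])
  }
  letters_tbl <- tibble(
    group = lv,
    mean = as.numeric(means[lv]),
    letters = vapply(lett[lv], function(x) {
      paste(sort(strsplit(x, "")[[1]]), collapse = "")
    }, character(1))
  )
  structure(list(comparisons = comparisons, letters = letters_tbl,
                 alpha = alpha),
            class = "tn_tukey")
}

#' @export
print.tn_tukey <- function(x, ...) {
  cat("Tukey HSD (alpha =", x$alpha, ")\n")
  print(as.data.frame(x$letters))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] (step-up BH, capped at 1).
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, elementwise >= the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}
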