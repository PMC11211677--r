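# Independent oracles used across the suite. These deliberately share no code
# with the package implementation.

hmm_state_names <- c("ES", "GA", "NE", "GD")

# exhaustive most-probable-path search over all 4^L state sequences
viterbi_brute_force <- function(counts, state_means, epsilon,
                                initial = rep(0.25, 4)) {
  L <- length(counts)
  x <- round(counts)
  le <- sapply(state_means, function(m) {
    p <- 1 / (1 + m)
    x * log1p(-p) + log(p)
  })
  le <- matrix(le, nrow = L)
  if (L == 1) return(hmm_state_names[which.max(log(initial) + le[1, ])])
  logT <- matrix(log(epsilon / 3), 4, 4)
  diag(logT) <- log(1 - epsilon)
  paths <- as.matrix(expand.grid(rep(list(1:4), L)))
  ll <- log(initial)[paths[, 1]] + le[cbind(1, paths[, 1])]
  for (i in 2:L) {
    ll <- ll + logT[cbind(paths[, i - 1], paths[, i])] + le[cbind(i, paths[, i])]
  }
  hmm_state_names[paths[which.max(ll), ]]
}

# plain breadth-first-search node metrics on an adjacency matrix
bfs_node_metrics <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  dist <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n)
    d[s] <- 0
    frontier <- s
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(adj[v, ] == 1)
        new <- nb[d[nb] == Inf]
        d[new] <- d[v] + 1
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
  }
  aspl <- numeric(n)
  closeness <- numeric(n)
  for (i in seq_len(n)) {
    dd <- dist[i, -i]
    dd <- dd[is.finite(dd)]
    if (length(dd) == 0) {
      aspl[i] <- NA_real_
      closeness[i] <- 0
    } else {
      aspl[i] <- mean(dd)
      closeness[i] <- 1 / aspl[i]
    }
  }
  topo <- numeric(n)
  for (i in seq_len(n)) {
    if (k[i] <= 1) next
    vals <- c()
    for (m in seq_len(n)) {
      if (m == i) next
      shared <- sum(adj[i, ] == 1 & adj[m, ] == 1)
      if (shared >= 1) {
        vals <- c(vals, (shared + adj[i, m]) / k[i])
      }
    }
    topo[i] <- if (length(vals) > 0) mean(vals) else 0
  }
  data.frame(k = k, aspl = aspl, closeness = closeness, topo_coeff = topo)
}

# exact enrichment p by enumerating every size-n subset of the universe
fisher_enumeration_oracle <- function(universe, label_genes, gene_set) {
  n <- length(gene_set)
  obs <- length(intersect(gene_set, label_genes))
  sets <- combn(universe, n, simplify = FALSE)
  hits <- vapply(sets, function(s) length(intersect(s, label_genes)), numeric(1))
  mean(hits >= obs)
}

# longest success run per row, streaming
empirical_max_run <- function(n, q, reps) {
  cur <- integer(reps)
  mx <- integer(reps)
  for (j in seq_len(n)) {
    z <- runif(reps) < q
    cur <- (cur + 1L) * z
    mx <- pmax(mx, cur)
  }
  c(mean = mean(mx), sd = sd(mx))
}

# tiny single-replicon track + gene index built by hand (no sequences needed)
make_toy_experiment <- function(counts_by_gene, spacing = 16L,
                                replicon = "toy") {
  n_ta <- lengths(counts_by_gene)
  pos <- (seq_len(sum(n_ta)) - 1L) * spacing
  gene_of <- rep(seq_along(counts_by_gene), n_ta)
  track <- tibble::tibble(
    replicon_id = replicon, library_id = "toy",
    pos = pos, count = unlist(counts_by_gene, use.names = FALSE)
  )
  gene_index <- tibble::tibble(
    gene_id = sprintf("g%03d", seq_along(counts_by_gene)),
    replicon_id = replicon,
    ta_sites = split(pos, factor(gene_of, levels = seq_along(counts_by_gene))),
    n_ta = as.integer(n_ta),
    no_data = n_ta == 0L
  )
  list(track = track, gene_index = gene_index)
}

# small cached pangenome simulation shared by slower tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(
        n_strains = 4, n_core = 120, n_accessory_shared = 30, n_specific = 10,
        gene_length_mean = 500, ta_per_gene_mean = 30, seed = 11
      )
      cache <<- simulate_pangenome(cfg)
    }
    cache
  }
})

strain_gene_table <- function(sim, strain) {
  g <- sim$genes[sim$genes$strain_id == strain, ]
  tibble::tibble(gene_id = g$gene_id, replicon_id = g$replicon_id,
                 start = g$start, end = g$end, strand = g$strand, cog = g$cog)
}
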