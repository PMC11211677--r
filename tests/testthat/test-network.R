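test_that("Pearson cofitness matrix matches the covariance formula", {
  fm <- tibble::tibble(
    orthogroup_id = c("a", "b", "c"),
    s1 = c(1, 2, 0.3), s2 = c(2, 4, -0.1), s3 = c(3, 6, 0.8),
    s4 = c(4, 8, 0.2), s5 = c(5, 10, -0.5)
  )
  attr(fm, "strains") <- paste0("s", 1:5)
  m <- pearson_matrix(fm)
  expect_equal(m["a", "b"], 1)
  expect_identical(m, t(m))
  expect_equal(diag(m), setNames(rep(1, 3), c("a", "b", "c")))
  neg <- fm
  neg$s1 <- -fm$s1; neg$s2 <- -fm$s2; neg$s3 <- -fm$s3
  neg$s4 <- -fm$s4; neg$s5 <- -fm$s5
  # row a vs its own negation (put negated a in row c)
  fm2 <- fm
  fm2[3, -1] <- -fm[1, -1]
  attr(fm2, "strains") <- paste0("s", 1:5)
  expect_equal(pearson_matrix(fm2)["a", "c"], -1)
  # independent rows: direct formula oracle
  set.seed(41)
  x <- rnorm(5); y <- rnorm(5)
  fm3 <- fm
  fm3[1, -1] <- as.list(x); fm3[2, -1] <- as.list(y)
  attr(fm3, "strains") <- paste0("s", 1:5)
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_matrix(fm3)["a", "b"], r_direct, tolerance = 1e-12)
  expect_lt(abs(pearson_matrix(fm3)["a", "b"]), 1)
  fm2col <- fm[, 1:3]
  attr(fm2col, "strains") <- c("s1", "s2")
  expect_error(pearson_matrix(fm2col), ">= 3")
})

test_that("NNSD has unit mean and separates GOE from Poisson spectra", {
  set.seed(42)
  n <- 300
  a <- matrix(rnorm(n * n), n)
  goe <- (a + t(a)) / 2
  s <- nnsd(goe)
  expect_equal(mean(s), 1, tolerance = 1e-6)
  d_w <- nnsd_distance(s, "wigner")
  d_p <- nnsd_distance(s, "poisson")
  expect_lt(d_w, d_p)
  expect_gte(d_p - d_w, 0.1)
  # independent diagonal blocks superpose to Poisson-like spacings
  bs <- 30
  blocks <- matrix(0, n, n)
  for (b in seq_len(n / bs)) {
    i <- ((b - 1) * bs + 1):(b * bs)
    x <- matrix(rnorm(bs * bs), bs)
    blocks[i, i] <- (x + t(x)) / 2
  }
  sb <- nnsd(blocks)
  expect_lt(nnsd_distance(sb, "poisson"), nnsd_distance(sb, "wigner"))
  expect_error(nnsd(goe[1:20, 1:20]), "size floor")
})

test_that("threshold scan finds the separating band of a planted two-block matrix", {
  set.seed(43)
  p <- 200
  g <- rep(1:2, each = p / 2)
  lat <- matrix(rnorm(2 * 20), 2)
  x <- lat[g, ] + matrix(rnorm(p * 20), p) * 0.35
  corr <- cor(t(x))
  within <- mean(corr[g[row(corr)] == g[col(corr)] & upper.tri(corr)])
  between <- mean(corr[g[row(corr)] != g[col(corr)] & upper.tri(corr)])
  sc <- rmt_threshold_scan(corr, grid = seq(0.30, 0.99, 0.01), min_size = 80)
  expect_gt(sc$r_star, between)
  expect_lt(sc$r_star, within)
  expect_s3_class(tidy(sc), "tbl_df")
  expect_equal(glance(sc)$r_star, sc$r_star)
  # when exactly one cutoff qualifies, it is returned
  one <- sc$scan$cutoff[sc$scan$qualifies][1]
  sc1 <- rmt_threshold_scan(corr, grid = c(0.30, one), min_size = 80)
  expect_equal(sc1$r_star, one)
  expect_error(rmt_threshold_scan(corr, grid = c(0.9, 0.5)), "increasing")
})

test_that("network edges are the upper-triangle pairs at or above r*", {
  corr <- matrix(c(1, 0.95, 0.20,
                   0.95, 1, 0.92,
                   0.20, 0.92, 1), 3, 3,
                 dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  net <- build_network(corr, 0.91)
  edges <- net$edges
  expect_equal(nrow(edges), 2)
  expect_setequal(paste(edges$gene_a, edges$gene_b),
                  c("g1 g2", "g2 g3"))
  expect_equal(igraph::vcount(net$graph), 3)
  expect_equal(nrow(build_network(corr, 1)$edges), 0)
  # monotone nesting of edge sets
  e_lo <- build_network(corr, 0.5)$edges
  e_hi <- build_network(corr, 0.93)$edges
  expect_true(all(paste(e_hi$gene_a, e_hi$gene_b) %in%
                    paste(e_lo$gene_a, e_lo$gene_b)))
  expect_equal(nrow(e_lo), sum(corr[upper.tri(corr)] >= 0.5))
})

test_that("node metrics match hand-computed values on canonical graphs", {
  tri <- matrix(1, 3, 3) - diag(3)
  rownames(tri) <- colnames(tri) <- c("a", "b", "c")
  g <- igraph::graph_from_adjacency_matrix(tri, mode = "undirected")
  m <- node_metrics(g)
  expect_equal(m$k, rep(2, 3))
  expect_equal(m$aspl, rep(1, 3))
  expect_equal(m$closeness, rep(1, 3))
  expect_equal(m$topo_coeff, rep(1, 3))
  # star K_{1,3}
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  rownames(star) <- colnames(star) <- c("hub", "l1", "l2", "l3")
  ms <- node_metrics(igraph::graph_from_adjacency_matrix(star, "undirected"))
  expect_equal(ms$k, c(3, 1, 1, 1))
  # leaf distances are 1 (hub) and 2, 2 (other leaves): aspl = 5/3
  expect_equal(ms$aspl, c(1, 5 / 3, 5 / 3, 5 / 3))
  expect_equal(ms$closeness, c(1, 0.6, 0.6, 0.6))
  expect_equal(ms$topo_coeff[1], 0)  # hub shares no neighbours (leaves k=1 -> 0)
})

test_that("node metrics equal a BFS oracle on random graphs", {
  set.seed(44)
  for (i in 1:20) {
    n <- 30
    adj <- matrix(0L, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.08)
    adj <- adj + t(adj)
    rownames(adj) <- colnames(adj) <- sprintf("n%02d", 1:n)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    got <- node_metrics(g)
    want <- bfs_node_metrics(adj)
    expect_equal(got$k, want$k)
    expect_equal(got$aspl, want$aspl)
    expect_equal(got$closeness, want$closeness)
    expect_equal(got$topo_coeff, want$topo_coeff)
  }
})

test_that("top-fraction subnetwork ranks pairs by correlation", {
  set.seed(45)
  p <- 6
  x <- matrix(rnorm(p * 8), p)
  corr <- cor(t(x))
  rownames(corr) <- colnames(corr) <- letters[1:p]
  # 15 pairs; fraction 0.2 keeps top 3
  sub <- top_fraction_subnetwork(corr, fraction = 0.2)
  expect_equal(nrow(sub$edges), 3)
  r_all <- sort(corr[upper.tri(corr)], decreasing = TRUE)
  expect_equal(sort(sub$edges$r, decreasing = TRUE), r_all[1:3])
  expect_lte(igraph::vcount(sub$graph), 2 * nrow(sub$edges))
  # fraction 1 on retained edges reproduces the thresholded network
  full <- top_fraction_subnetwork(corr, fraction = 1,
                                  base = "retained-edges", r_star = 0.2)
  net <- build_network(corr, 0.2)
  expect_equal(nrow(full$edges), nrow(net$edges))
})

test_that("module detection recovers disjoint cliques and partitions nodes", {
  adj <- matrix(0, 7, 7)
  adj[1:3, 1:3] <- 1
  adj[4:6, 4:6] <- 1
  diag(adj) <- 0
  rownames(adj) <- colnames(adj) <- letters[1:7]
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  mod <- detect_modules(g)
  expect_equal(length(unique(mod$module_id)), 3)  # 2 cliques + 1 isolate
  expect_equal(length(unique(mod$module_id[1:3])), 1)
  expect_equal(length(unique(mod$module_id[4:6])), 1)
  expect_false(mod$module_id[1] == mod$module_id[4])
  expect_equal(sum(table(mod$module_id)), 7)
  empty <- igraph::make_empty_graph(5, directed = FALSE)
  igraph::V(empty)$name <- letters[1:5]
  expect_equal(sort(detect_modules(empty)$module_id), 1:5)
})

test_that("network export writes edge list and GraphML", {
  corr <- matrix(c(1, 0.95, 0.95, 1), 2, 2,
                 dimnames = list(c("x", "y"), c("x", "y")))
  net <- build_network(corr, 0.9)
  edge_f <- withr::local_tempfile(fileext = ".tsv")
  gml_f <- withr::local_tempfile(fileext = ".graphml")
  write_network(net, edge_f, gml_f)
  e <- readr::read_tsv(edge_f, show_col_types = FALSE)
  expect_equal(nrow(e), 1)
  expect_true(file.size(gml_f) > 0)
})
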