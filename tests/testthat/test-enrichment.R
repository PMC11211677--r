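test_that("Fisher enrichment equals exhaustive enumeration on tiny universes", {
  universe <- c("g1", "g2", "g3", "g4")
  ann <- tibble::tibble(gene_id = c("g1", "g2"), label = "L")
  res <- fisher_enrichment(c("g1", "g2"), ann, universe)
  expect_equal(res$p, 1 / 6)
  expect_equal(res$k, 2)
  # overlap 0 gives p = 1
  res0 <- fisher_enrichment(c("g3", "g4"), ann, universe)
  expect_equal(res0$p, 1)
  expect_equal(nrow(fisher_enrichment(character(0), ann, universe)), 0)
  expect_error(fisher_enrichment("zz", ann, universe), "subset")
  expect_error(fisher_enrichment("g1", ann, character(0)), "empty")
})

test_that("Fisher matches enumeration and fisher.test on random small cases", {
  set.seed(51)
  for (i in 1:15) {
    N <- sample(6:12, 1)
    universe <- sprintf("u%02d", 1:N)
    K <- sample(2:(N - 1), 1)
    label_genes <- sample(universe, K)
    n <- sample(2:(N - 1), 1)
    gene_set <- sample(universe, n)
    ann <- tibble::tibble(gene_id = label_genes, label = "L")
    got <- fisher_enrichment(gene_set, ann, universe)$p
    want <- fisher_enumeration_oracle(universe, label_genes, gene_set)
    expect_equal(got, want, tolerance = 1e-12)
    # cross-check against the standard exact test
    k <- length(intersect(gene_set, label_genes))
    ft <- fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                      alternative = "greater")$p.value
    expect_equal(got, ft, tolerance = 1e-9)
  }
})

test_that("multi-label genes count once per label; odds ratios use Haldane", {
  universe <- sprintf("g%d", 1:10)
  ann <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    label = c("J", "M", "J", "M")
  )
  res <- fisher_enrichment(c("g1", "g2"), ann, universe)
  expect_equal(res$k[res$label == "J"], 2)
  expect_equal(res$k[res$label == "M"], 1)
  expect_true(all(is.finite(res$odds_ratio)))
})

test_that("permutation Z matches the binomial-scale expectation", {
  bg <- sprintf("g%04d", 1:1000)
  labels <- tibble::tibble(
    gene_id = bg,
    subset = rep(c("I", "II"), each = 500)
  )
  res <- permutation_z(bg[1:100], labels, "I", n_sim = 5000, seed = 3)
  expect_gt(res$z, 8)
  expect_lt(res$p_two_tailed, 1e-15)
  res2 <- permutation_z(bg[1:100], labels, "I", n_sim = 5000, seed = 3)
  expect_identical(res$z, res2$z)
  # calibration: random categories rarely reach |z| > 3
  set.seed(52)
  zs <- replicate(100, {
    permutation_z(sample(bg, 80), labels, "I", n_sim = 400,
                  seed = sample.int(1e6, 1))$z
  })
  expect_gte(mean(abs(zs) < 3), 0.97)
})

test_that("permutation Z approximates the exact hypergeometric tail", {
  bg <- sprintf("g%04d", 1:400)
  labels <- tibble::tibble(gene_id = bg,
                           subset = rep(c("I", "II"), c(120, 280)))
  set.seed(53)
  for (i in 1:5) {
    cat_genes <- sample(bg, 60)
    res <- permutation_z(cat_genes, labels, "I", n_sim = 5000, seed = i)
    k <- res$observed
    # the Gaussian z-p approximates the exact two-sided MID-p (half the
    # point mass P(X = k) assigned to each tail)
    pmass <- dhyper(k, 120, 280, 60)
    p_hi <- phyper(k, 120, 280, 60, lower.tail = FALSE) + pmass / 2
    p_lo <- phyper(k - 1, 120, 280, 60) + pmass / 2
    p_exact <- min(1, 2 * min(p_hi, p_lo))
    expect_lt(abs(res$p_two_tailed - p_exact), 0.02)
  }
})

test_that("a planted threefold-enriched label is detected by both tests", {
  set.seed(54)
  hits <- 0L
  n_rep <- 40
  for (i in 1:n_rep) {
    bg <- sprintf("g%04d", 1:600)
    lab_genes <- sample(bg, 120)
    ann <- tibble::tibble(gene_id = lab_genes, label = "L")
    subs <- tibble::tibble(gene_id = bg,
                           subset = ifelse(bg %in% lab_genes, "I", "II"))
    # gene set draws label members at 3x the background rate
    w <- ifelse(bg %in% lab_genes, 3, 1)
    gene_set <- sample(bg, 80, prob = w)
    pf <- fisher_enrichment(gene_set, ann, bg)$p
    pz <- permutation_z(gene_set, subs, "I", n_sim = 400, seed = i)$p_two_tailed
    if (pf < 0.05 && pz < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("Tukey HSD separates distinct groups and letters agree", {
  same <- data.frame(v = rep(c(1, 2, 3), 3),
                     g = rep(c("a", "b", "c"), each = 3))
  tk <- tukey_hsd(same, "v", "g")
  expect_true(all(tk$comparisons$p_adj > 0.999))
  expect_equal(length(unique(tk$letters$letters)), 1)
  set.seed(55)
  two <- data.frame(v = c(rnorm(20, 0, 0.1), rnorm(20, 10, 0.1)),
                    g = rep(c("lo", "hi"), each = 20))
  tk2 <- tukey_hsd(two, "v", "g")
  expect_lt(tk2$comparisons$p_adj, 0.001)
  expect_false(tk2$letters$letters[1] == tk2$letters$letters[2])
  # with two groups Tukey reduces to the equal-variance two-sample comparison
  tt <- t.test(v ~ g, data = two, var.equal = TRUE)$p.value
  expect_equal(tk2$comparisons$p_adj, tt, tolerance = 1e-6)
  expect_error(tukey_hsd(two[1:21, ], "v", "g"), "at least 2 values")
  expect_s3_class(tidy(tk2), "tbl_df")
  expect_equal(glance(tk2)$n_groups, 2)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- c(0.001, 0.2, 0.04, 0.9)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})
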