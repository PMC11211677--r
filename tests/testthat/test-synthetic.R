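test_that("config validation rejects impossible settings", {
  expect_error(sim_config(density_target = 1.2))
  expect_error(sim_config(category_probs = c(ES = 0.5, GA = 0.2,
                                             GD = 0.2, NE = 0.2)))
  expect_error(sim_config(gene_length_mean = 100, ta_per_gene_mean = 40),
               "infeasible")
})

test_that("pangenome structure matches the configured architecture", {
  sim <- small_sim()
  cfg <- sim$cfg
  span <- dplyr::count(dplyr::distinct(sim$orthogroups, orthogroup_id,
                                       strain_id), orthogroup_id)
  expect_equal(sum(span$n == cfg$n_strains) >= cfg$n_core, TRUE)
  expect_equal(sum(span$n == 1), cfg$n_strains * cfg$n_specific)
  # core orthogroups are single-copy everywhere
  copies <- dplyr::count(sim$orthogroups, orthogroup_id, strain_id)
  expect_true(all(copies$n == 1))
  # subset truth labels agree with the span definition
  expect_true(all(sim$truth$subset %in% c("I", "II", "III")))
  # gene n_ta matches the planted TA count exactly (untrimmed)
  ta <- ta_index(sim$genomes[["S1"]])
  gi <- build_gene_ta_index(strain_gene_table(sim, "S1"), ta,
                            trim_fraction = 0)
  expect_true(all(gi$n_ta >= 1))
  expect_equal(mean(gi$n_ta), cfg$ta_per_gene_mean, tolerance = 0.1)
})

test_that("rewiring is absent at rewire_prob 0 and matches expectation at 0.3", {
  cfg0 <- sim_config(n_strains = 3, n_core = 60, n_accessory_shared = 10,
                     n_specific = 5, gene_length_mean = 400,
                     ta_per_gene_mean = 20, rewire_prob = 0, seed = 2)
  sim0 <- simulate_pangenome(cfg0)
  core_og <- sprintf("OG%05d", 1:60)
  discord0 <- sim0$truth |>
    dplyr::filter(orthogroup_id %in% core_og) |>
    dplyr::group_by(orthogroup_id) |>
    dplyr::summarise(d = dplyr::n_distinct(category) > 1)
  expect_false(any(discord0$d))
  cfg3 <- sim_config(n_strains = 5, n_core = 300, n_accessory_shared = 10,
                     n_specific = 5, gene_length_mean = 400,
                     ta_per_gene_mean = 20, rewire_prob = 0.3, seed = 1)
  sim3 <- simulate_pangenome(cfg3)
  core_og3 <- sprintf("OG%05d", 1:300)
  discord <- sim3$truth |>
    dplyr::filter(orthogroup_id %in% core_og3) |>
    dplyr::group_by(orthogroup_id) |>
    dplyr::summarise(d = dplyr::n_distinct(category) > 1)
  # analytic expectation: per strain a gene of base category c switches with
  # probability rewire_prob * (1 - p_c); discordance if any strain switches
  p <- cfg3$category_probs
  exp_frac <- sum(p * (1 - (1 - 0.3 * (1 - p))^5))
  se <- sqrt(exp_frac * (1 - exp_frac) / 300)
  expect_lt(abs(mean(discord$d) - exp_frac), 4 * se)
})

test_that("library simulation hits the density target and leaks ES rarely", {
  sim <- small_sim()
  tr <- simulate_library(sim, "S2", 1)
  expect_equal(mean(tr$count > 0), sim$cfg$density_target, tolerance = 0.02)
  ta <- ta_index(sim$genomes[["S2"]])
  st <- pantnfit:::site_states(sim, "S2", ta)
  es_hit <- mean(tr$count[st == "ES"] > 0)
  ne_hit <- mean(tr$count[st == "NE"] > 0)
  expect_lt(es_hit, 0.2)
  expect_gt(ne_hit, 0.8)
  expect_gt(ne_hit / max(es_hit, 1e-3), 5)
  # same seed, same track; different library index, different track
  tr_b <- simulate_library(sim, "S2", 1)
  expect_identical(tr$count, tr_b$count)
  tr2 <- simulate_library(sim, "S2", 2)
  expect_false(identical(tr$count, tr2$count))
  expect_error(simulate_library(sim, "S2", 1, density_target = 0.999),
               "unreachable")
  expect_error(simulate_library(sim, "nope", 1), "unknown strain")
})

test_that("fixture bundles are complete and byte-reproducible", {
  cfg <- sim_config(n_strains = 2, n_core = 25, n_accessory_shared = 0,
                    n_specific = 3, gene_length_mean = 400,
                    ta_per_gene_mean = 20, n_libraries = 2, seed = 6)
  sim <- simulate_pangenome(cfg)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture_bundle(sim, d1)
  write_fixture_bundle(sim, d2)
  rel <- c("genomes/S1.fasta", "annotations/S1_genes.tsv",
           "annotations/S1.gff3", "tracks/S1_lib1.wig", "tracks/S2_lib2.wig",
           "orthogroups.tsv", "cog.tsv", "truth.tsv", "config.yaml")
  for (f in rel) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # the GFF3 round-trips through the annotation reader
  g <- read_genes(file.path(d1, "annotations", "S1.gff3"))
  g_tsv <- read_genes(file.path(d1, "annotations", "S1_genes.tsv"))
  expect_setequal(g$gene_id, g_tsv$gene_id)
  expect_equal(dplyr::arrange(g[, c("gene_id", "start", "end")], gene_id),
               dplyr::arrange(g_tsv[, c("gene_id", "start", "end")], gene_id))
})
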