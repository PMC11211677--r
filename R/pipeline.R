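#' Default pipeline configuration
#' @noRd
default_pipeline_config <- function() {
  list(
    input_dir = NULL,
    strains = NULL,              # default: every genome in input_dir/genomes
    n_strains_total = NULL,      # default: number of strains found
    n_libraries = NULL,          # default: every wig found per strain
    trim_fraction = 0.05,
    loess_span = 0.1,
    ttr_trim = 0.05,
    ttr_target_mean = 100,
    hmm_epsilon = 1e-3,
    gumbel_z_es = 0.99,
    gumbel_z_ne = 0.05,
    gumbel_min_ta = 4,
    gumbel_iters = 2000,
    n_pseudo = 2000,
    pseudocount = 0.5,
    rmt_grid_min = 0.5,
    rmt_grid_max = 0.99,
    rmt_grid_step = 0.01,
    rmt_alpha = 0.05,
    rmt_min_size = 100,
    top_fraction = 0.01,
    multi_copy = "min",
    seed = 1
  )
}

#' Run the full pangenomic Tn-seq analysis
#'
#' Stages, in order, for each strain of a fixture-bundle-style input
#' directory (see [write_fixture_bundle()] for the layout): read genome and
#' annotations, read the per-library wig tracks, combine and normalize
#' (LOESS then TTR), call essentiality by HMM, Gumbel, and Monte Carlo
#' fitness; then assemble the core fitness matrix over all strains, choose
#' the RMT correlation threshold, build the cofitness network with node
#' metrics and modules, and compute subset/enrichment summaries. Unknown
#' config keys raise an error before any computation; a missing input file
#' raises an error naming it.
#'
#' @param config Named list overriding the defaults; `input_dir` is
#'   required. May also be a path to a YAML file.
#' @param outdir Optional directory; when given, per-stage TSV outputs are
#'   written there.
#' @return List of class `tn_pipeline`: `config`, `qc`, `hmm`, `gumbel`,
#'   `fitness` (per strain), `fitness_matrix`, `rmt`, `network`, `metrics`,
#'   `modules`, `subsets`, `summary`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  defaults <- default_pipeline_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$input_dir)) abort("config must set `input_dir`.")
  if (!dir.exists(cfg$input_dir)) {
    abort(paste0("input directory not found: ", cfg$input_dir))
  }
  fastas <- list.files(file.path(cfg$input_dir, "genomes"),
                       pattern = "\\.fasta$", full.names = TRUE)
  strains <- cfg$strains %||% sub("\\.fasta$", "", basename(fastas))
  if (length(strains) == 0) abort("no genomes found under input_dir/genomes.")
  n_strains_total <- cfg$n_strains_total %||% length(strains)

  qc <- list(); hmm <- list(); gumbel <- list(); fitness <- list()
  gene_tables <- list()
  for (s in strains) {
    fa <- file.path(cfg$input_dir, "genomes", paste0(s, ".fasta"))
    ann <- file.path(cfg$input_dir, "annotations", paste0(s, "_genes.tsv"))
    for (f in c(fa, ann)) {
      if (!file.exists(f)) abort(paste0("missing input file: ", f))
    }
    ta <- ta_index(fa)
    genes <- build_gene_ta_index(read_genes(ann), ta,
                                 trim_fraction = cfg$trim_fraction)
    gene_tables[[s]] <- genes
    wigs <- list.files(file.path(cfg$input_dir, "tracks"),
                       pattern = paste0("^", s, "_lib\\d+\\.wig$"),
                       full.names = TRUE)
    if (!is.null(cfg$n_libraries)) {
      expect <- file.path(cfg$input_dir, "tracks",
                          sprintf("%s_lib%d.wig", s, seq_len(cfg$n_libraries)))
      miss <- expect[!file.exists(expect)]
      if (length(miss) > 0) {
        abort(paste0("missing library track(s): ",
                     paste(basename(miss), collapse = ", ")))
      }
      wigs <- expect
    }
    if (length(wigs) == 0) abort(paste0("no library tracks found for ", s))
    tracks <- purrr::map(wigs, read_track, ta = ta)
    qc[[s]] <- library_qc(bind_rows(tracks))
    comb <- prepare_track(tracks, span = cfg$loess_span, trim = cfg$ttr_trim,
                          target_mean = cfg$ttr_target_mean,
                          library_id = paste0(s, "_combined"))
    hmm[[s]] <- fit_essentiality_hmm(comb, genes, epsilon = cfg$hmm_epsilon)
    gumbel[[s]] <- fit_essentiality_gumbel(
      comb, genes, z_es = cfg$gumbel_z_es, z_ne = cfg$gumbel_z_ne,
      min_ta = cfg$gumbel_min_ta, iters = cfg$gumbel_iters,
      seed = cfg$seed + 101
    )
    fitness[[s]] <- gene_fitness(comb, genes, n_pseudo = cfg$n_pseudo,
                                 pseudocount = cfg$pseudocount,
                                 seed = cfg$seed + 211)
  }

  og_path <- file.path(cfg$input_dir, "orthogroups.tsv")
  if (!file.exists(og_path)) abort(paste0("missing input file: ", og_path))
  orthogroups <- read_orthogroups(og_path)
  subsets <- assign_subsets(orthogroups, n_strains_total)
  fm <- core_fitness_matrix(orthogroups, fitness, test_strains = strains,
                            multi_copy = cfg$multi_copy)
  corr <- pearson_matrix(fm)
  rmt <- rmt_threshold_scan(
    corr, grid = seq(cfg$rmt_grid_min, cfg$rmt_grid_max,
                     by = cfg$rmt_grid_step),
    alpha = cfg$rmt_alpha, min_size = cfg$rmt_min_size
  )
  network <- build_network(corr, rmt$r_star)
  metrics <- node_metrics(network)
  modules <- detect_modules(network)

  hmm_calls <- bind_rows(purrr::map(hmm, "calls"), .id = "strain_id")
  summary <- category_subset_summary(
    hmm_calls, subsets,
    bind_rows(fitness, .id = "strain_id"),
    seed = cfg$seed + 307
  )

  result <- structure(
    list(config = cfg, qc = bind_rows(qc, .id = "strain_id"),
         hmm = hmm, gumbel = gumbel, fitness = fitness,
         gene_tables = gene_tables,
         fitness_matrix = fm, rmt = rmt, network = network,
         metrics = metrics, modules = modules, subsets = subsets,
         summary = summary),
    class = "tn_pipeline"
  )
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(result$qc, file.path(outdir, "library_qc.tsv"))
    readr::write_tsv(hmm_calls, file.path(outdir, "hmm_calls.tsv"))
    readr::write_tsv(bind_rows(purrr::map(gumbel, "calls"),
                               .id = "strain_id"),
                     file.path(outdir, "gumbel_calls.tsv"))
    readr::write_tsv(bind_rows(fitness, .id = "strain_id"),
                     file.path(outdir, "fitness.tsv"))
    readr::write_tsv(as_tibble(fm), file.path(outdir, "fitness_matrix.tsv"))
    readr::write_tsv(rmt$scan, file.path(outdir, "rmt_scan.tsv"))
    readr::write_tsv(metrics, file.path(outdir, "node_metrics.tsv"))
    readr::write_tsv(modules, file.path(outdir, "modules.tsv"))
    write_network(network, file.path(outdir, "edges.tsv"),
                  file.path(outdir, "network.graphml"))
    readr::write_tsv(summary$table, file.path(outdir, "category_subset.tsv"))
  }
  result
}

#' @export
print.tn_pipeline <- function(x, ...) {
  cat("Pangenomic Tn-seq pipeline result\n")
  cat("  strains:", paste(names(x$hmm), collapse = ", "), "\n")
  cat(sprintf("  fitness matrix: %d orthogroups x %d strains\n",
              nrow(x$fitness_matrix), length(attr(x$fitness_matrix, "strains"))))
  cat(sprintf("  network: r* = %.2f, %d edges\n", x$rmt$r_star,
              igraph::ecount(x$network$graph)))
  invisible(x)
}

#' Method concordance across callers and libraries
#'
#' Compares ES gene sets between methods per strain and library: ES counts,
#' pairwise agreement (Jaccard index of the ES sets), and the per-method SD
#' of ES counts across libraries within each strain (the library-robustness
#' statistic).
#'
#' @param calls Long tibble with columns `strain_id`, `library_id`,
#'   `method`, `gene_id`, `es` (logical).
#' @return List of tibbles: `counts` (per strain x library x method),
#'   `agreement` (pairwise Jaccard per strain x library), `dispersion`
#'   (per strain x method SD of ES counts across libraries).
#' @export
method_concordance <- function(calls) {
  stopifnot(all(c("strain_id", "library_id", "method", "gene_id", "es")
                %in% names(calls)))
  universes <- calls |>
    group_by(.data$strain_id, .data$library_id, .data$method) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene_id), .groups = "drop")
  if (length(unique(universes$n_genes)) > 1) {
    abort("methods were run on different gene universes.")
  }
  counts <- calls |>
    group_by(.data$strain_id, .data$library_id, .data$method) |>
    summarise(n_es = sum(.data$es), .groups = "drop")
  sets <- calls |>
    filter(.data$es) |>
    group_by(.data$strain_id, .data$library_id, .data$method) |>
    summarise(genes = list(unique(.data$gene_id)), .groups = "drop")
  pairs_of <- function(df) {
    ms <- sort(unique(df$method))
    if (length(ms) < 2) return(tibble())
    cmb <- utils::combn(ms, 2, simplify = FALSE)
    purrr::map(cmb, function(p) {
      a <- df$genes[df$method == p[1]][[1]] %||% character(0)
      b <- df$genes[df$method == p[2]][[1]] %||% character(0)
      u <- union(a, b)
      tibble(method_a = p[1], method_b = p[2],
             jaccard = if (length(u) == 0) 1 else
               length(intersect(a, b)) / length(u))
    }) |> bind_rows()
  }
  agreement <- sets |>
    group_by(.data$strain_id, .data$library_id) |>
    dplyr::group_modify(~ pairs_of(.x)) |>
    ungroup()
  dispersion <- counts |>
    group_by(.data$strain_id, .data$method) |>
    summarise(sd_es = sd(.data$n_es), mean_es = mean(.data$n_es),
              n_libraries = n(), .groups = "drop")
  list(counts = counts, agreement = agreement, dispersion = dispersion)
}

#' Category-by-subset summary with enrichment statistics
#'
#' Per fitness category and conservation subset: gene counts and mean Monte
#' Carlo fitness; Tukey HSD letters separating category fitness
#' distributions; and, per category, Fisher and permutation-Z enrichment of
#' subset I membership against the full background.
#'
#' @param hmm_calls Long tibble of HMM calls with `strain_id`, `gene_id`,
#'   `call`.
#' @param subsets Tibble `gene_id`, `subset` from [assign_subsets()].
#' @param fitness Long tibble of fitness records with `strain_id`, `gene_id`,
#'   `log2fc`.
#' @param target_subset Subset tested for enrichment.
#' @param n_sim Permutation draws for the Z test.
#' @param seed RNG seed.
#' @return List: `table` (category x subset counts + mean fitness),
#'   `tukey` (a `tn_tukey` on fitness by category), `enrichment` (per
#'   category: Fisher p and Z-test results).
#' @export
category_subset_summary <- function(hmm_calls, subsets, fitness,
                                    target_subset = "I", n_sim = 5000,
                                    seed = 1L) {
  merged <- hmm_calls |>
    inner_join(subsets, by = "gene_id") |>
    left_join(select(fitness, "strain_id", "gene_id", "log2fc"),
              by = c("strain_id", "gene_id"))
  tab <- merged |>
    group_by(category = .data$call, subset = .data$subset) |>
    summarise(n = n(), mean_fitness = mean(.data$log2fc, na.rm = TRUE),
              .groups = "drop")
  tk <- tukey_hsd(
    filter(merged, !is.na(.data$log2fc)),
    value = "log2fc", group = "call"
  )
  bg_labels <- distinct(merged, .data$gene_id, .data$subset) |>
    rename(subset = "subset")
  enr <- purrr::map(sort(unique(merged$call)), function(cat) {
    set <- unique(merged$gene_id[merged$call == cat])
    fis <- fisher_enrichment(
      set,
      tibble(gene_id = bg_labels$gene_id, label = as.character(bg_labels$subset)),
      bg_labels$gene_id
    )
    z <- permutation_z(set, bg_labels, target_subset,
                       n_sim = n_sim, seed = seed)
    mutate(z, category = cat,
           fisher_p = fis$p[fis$label == target_subset] %||% NA_real_)
  }) |> bind_rows()
  list(table = tab, tukey = tk, enrichment = enr)
}
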