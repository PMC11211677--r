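#' Configuration for the synthetic pangenome generator
#'
#' Defaults emulate the study design the package targets: five sibling
#' strains with multipartite genomes, a shared single-copy core, partially
#' shared accessory genes and strain-specific genes, three independent
#' mariner mutant libraries per strain with high insertion density, and a
#' strain-dependent category switch ("rewiring") for a fraction of core
#' genes.
#'
#' @param n_strains Number of strains.
#' @param n_core Single-copy core orthogroups (present in every strain).
#' @param n_accessory_shared Orthogroups present in 2..(n_strains-1) strains.
#' @param n_specific Strain-specific genes per strain.
#' @param gene_length_mean Gene length in bp.
#' @param ta_per_gene_mean Mean TA sites per gene (Poisson).
#' @param intergenic_length Spacer length between genes in bp.
#' @param category_probs Base fitness-category probabilities for core genes
#'   (ES, GA, GD, NE).
#' @param category_probs_accessory Same for accessory/specific genes
#'   (NE-dominated, as accessory genes are rarely required for growth).
#' @param rewire_prob Per-strain probability that a core gene's category is
#'   independently redrawn (the planted fuzzy essential zone).
#' @param state_insertion_prob Relative per-site insertion weights by
#'   category; ES is the non-disruptive leak rate.
#' @param state_mean_count Mean read count at an inserted site by category.
#'   Count effects are stronger than insertion-probability effects because
#'   competitive outgrowth acts multiplicatively on mutant abundance: GA
#'   mutants are depleted about fivefold, GD mutants enriched about fivefold
#'   relative to NE.
#' @param es_severity_sd SD (log scale) of the per-strain selection-severity
#'   multiplier applied to the ES leak weight and the ES escaper count mean;
#'   a shared strain effect that makes essential-gene fitness profiles
#'   correlate across strains (the planted co-essentiality signal).
#' @param n_libraries Independent libraries per strain.
#' @param density_target Genome-wide insertion density per library.
#' @param seed Master seed.
#' @return A validated config list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 5,
                       n_core = 500,
                       n_accessory_shared = 120,
                       n_specific = 40,
                       gene_length_mean = 900,
                       ta_per_gene_mean = 55,
                       intergenic_length = 100,
                       category_probs = c(ES = 0.08, GA = 0.06,
                                          GD = 0.04, NE = 0.82),
                       category_probs_accessory = c(ES = 0.02, GA = 0.03,
                                                    GD = 0.02, NE = 0.93),
                       rewire_prob = 0.1,
                       state_insertion_prob = c(ES = 0.005, GA = 0.4,
                                                NE = 1, GD = 1.8),
                       state_mean_count = c(ES = 5, GA = 10,
                                            NE = 50, GD = 250),
                       es_severity_sd = 1.5,
                       n_libraries = 3,
                       density_target = 0.85,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    abs(sum(cfg$category_probs) - 1) < 1e-9,
    abs(sum(cfg$category_probs_accessory) - 1) < 1e-9,
    all(cfg$category_probs >= 0), cfg$rewire_prob >= 0, cfg$rewire_prob <= 1,
    cfg$density_target > 0, cfg$density_target < 1,
    cfg$n_strains >= 2, cfg$ta_per_gene_mean >= 1
  )
  if (2.5 * cfg$ta_per_gene_mean > cfg$gene_length_mean / 2) {
    abort("infeasible gene length / TA-site combination.")
  }
  structure(cfg, class = "sim_config")
}

#' CG spacer (never forms a TA)
#' @noRd
cg_spacer <- function(l) {
  if (l <= 0) return("")
  substr(strrep("CG", ceiling(l / 2)), 1, l)
}

#' Gene sequence with exactly k TA sites
#' @noRd
gene_sequence <- function(k, length_bp) {
  if (k == 0) return(cg_spacer(length_bp))
  spacer_total <- length_bp - 2 * k
  base <- spacer_total %/% (k + 1)
  lens <- rep(base, k + 1)
  lens[k + 1] <- lens[k + 1] + spacer_total - sum(lens)
  paste0(paste0(vapply(lens[1:k], cg_spacer, character(1)), "TA",
                collapse = ""), cg_spacer(lens[k + 1]))
}

#' Simulate a multi-strain pangenome with planted fitness categories
#'
#' Core orthogroups are single-copy in every strain; shared accessory
#' orthogroups span 2..(n_strains - 1) strains; specific genes one strain.
#' Each core orthogroup gets a base category drawn from `category_probs`,
#' and, independently per strain with probability `rewire_prob`, a redrawn
#' category. Gene sequences carry a Poisson number of TA sites on a CG
#' background (composition realism is out of scope; the TA-site geometry is
#' what downstream analysis consumes). Each strain's genome is split over
#' two replicons (chromosome + plasmid) to exercise multipartite handling.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_pangenome`: `cfg`, `genomes` (named list of
#'   named sequence vectors per strain), `genes` (long tibble with
#'   coordinates, COG, orthogroup, per-strain planted `category`),
#'   `orthogroups` (long tibble), `truth` (genes plus subset labels),
#'   `strain_severity` (named ES-leak multipliers).
#' @export
simulate_pangenome <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed_(cfg$seed, {
    strains <- paste0("S", seq_len(cfg$n_strains))
    cogs <- c("J", "K", "L", "D", "M", "H", "F", "U", "C", "G", "P", "T",
              "N", "S")
    n_og <- cfg$n_core + cfg$n_accessory_shared + cfg$n_strains * cfg$n_specific
    og_ids <- sprintf("OG%05d", seq_len(n_og))
    og_class <- c(
      rep("core", cfg$n_core),
      rep("accessory", cfg$n_accessory_shared),
      rep("specific", cfg$n_strains * cfg$n_specific)
    )
    og_strains <- vector("list", n_og)
    for (i in seq_len(n_og)) {
      og_strains[[i]] <- switch(og_class[i],
        core = strains,
        accessory = sort(sample(strains,
                                sample(2:(cfg$n_strains - 1), 1))),
        specific = strains[((i - cfg$n_core - cfg$n_accessory_shared - 1) %%
                              cfg$n_strains) + 1]
      )
    }
    og_cog <- ifelse(runif(n_og) < 0.8, sample(cogs, n_og, replace = TRUE),
                     NA_character_)
    base_cat <- character(n_og)
    base_cat[og_class == "core"] <- sample(
      names(cfg$category_probs), cfg$n_core, replace = TRUE,
      prob = cfg$category_probs
    )
    base_cat[og_class != "core"] <- sample(
      names(cfg$category_probs_accessory), sum(og_class != "core"),
      replace = TRUE, prob = cfg$category_probs_accessory
    )
    # clamped: stringency varies between strains within a bounded range, so
    # essential genes never masquerade as nonessential in a leaky strain
    strain_severity <- setNames(
      pmin(pmax(exp(rnorm(cfg$n_strains, 0, cfg$es_severity_sd)), 1 / 6), 6),
      strains
    )

    # per-strain gene tables + genomes
    genes_list <- list()
    genomes <- list()
    for (s in strains) {
      og_here <- which(vapply(og_strains, function(x) s %in% x, logical(1)))
      og_here <- sample(og_here)  # shuffle gene order along the genome
      n_g <- length(og_here)
      k_ta <- pmax(1L, rpois(n_g, cfg$ta_per_gene_mean))
      category <- vapply(og_here, function(i) {
        if (og_class[i] == "core" && runif(1) < cfg$rewire_prob) {
          sample(names(cfg$category_probs), 1, prob = cfg$category_probs)
        } else {
          base_cat[i]
        }
      }, character(1))
      # split genes over two replicons (~70/30)
      n_chr <- ceiling(0.7 * n_g)
      repl <- c(rep(paste0(s, ".chr"), n_chr),
                rep(paste0(s, ".pA"), n_g - n_chr))
      seqs <- vapply(k_ta, gene_sequence, character(1),
                     length_bp = cfg$gene_length_mean)
      inter_k <- pmax(0L, rpois(n_g, cfg$intergenic_length / 16))
      inters <- vapply(inter_k, function(k) {
        gene_sequence(k, max(cfg$intergenic_length, 2 * k + 4))
      }, character(1))
      tbl <- tibble(
        strain_id = s,
        gene_id = sprintf("%s_g%04d", s, seq_len(n_g)),
        orthogroup_id = og_ids[og_here],
        replicon_id = repl,
        cog = og_cog[og_here],
        category = category,
        strand = sample(c("+", "-"), n_g, replace = TRUE),
        gene_seq = seqs,
        inter_seq = inters
      )
      # lay genes sequentially per replicon: spacer, gene, spacer, gene, ...
      tbl <- tbl |>
        group_by(.data$replicon_id) |>
        mutate(
          gene_len = nchar(.data$gene_seq),
          inter_len = nchar(.data$inter_seq),
          start = cumsum(.data$inter_len) +
            dplyr::lag(cumsum(.data$gene_len), default = 0) + 1,
          end = .data$start + .data$gene_len - 1
        ) |>
        ungroup()
      genome <- vapply(split(tbl, tbl$replicon_id), function(t) {
        paste0(paste0(t$inter_seq, t$gene_seq, collapse = ""), cg_spacer(50))
      }, character(1))
      genomes[[s]] <- genome
      genes_list[[s]] <- select(tbl, -"gene_seq", -"inter_seq",
                                -"gene_len", -"inter_len")
    }
    genes <- bind_rows(genes_list)
    orthogroups <- genes |>
      select(orthogroup_id = "orthogroup_id", strain_id = "strain_id",
             gene_id = "gene_id")
    span <- orthogroups |>
      group_by(.data$orthogroup_id) |>
      summarise(n_strains = dplyr::n_distinct(.data$strain_id))
    truth <- genes |>
      left_join(span, by = "orthogroup_id") |>
      mutate(subset = dplyr::case_when(
        .data$n_strains == cfg$n_strains ~ "I",
        .data$n_strains == 1 ~ "III",
        TRUE ~ "II"
      )) |>
      select("strain_id", "gene_id", "orthogroup_id", "category",
             "subset", "cog")
    structure(
      list(cfg = cfg, genomes = genomes, genes = genes,
           orthogroups = orthogroups, truth = truth,
           strain_severity = strain_severity),
      class = "sim_pangenome"
    )
  })
}

#' Simulate one mariner mutant library for a strain
#'
#' Insertion is modelled as independent Poisson transposition events: site
#' `i` with relative weight `w_i` (by the category of the gene containing it;
#' intergenic sites behave as NE) is inserted with probability
#' `1 - exp(-lambda * w_i)`, with the global pressure `lambda` solved so the
#' expected genome-wide density equals `density_target`. The ES leak weight
#' is additionally multiplied by the strain's severity factor. Read counts at
#' inserted sites are `1 + Geometric` with the category's mean.
#'
#' @param sim A `sim_pangenome`.
#' @param strain_id Strain to simulate.
#' @param library_index Library number (only used for the default seed and
#'   the `library_id` label).
#' @param density_target Target insertion density (defaults to the config).
#' @param seed RNG seed (defaults to a stream derived from the master seed,
#'   strain, and library index).
#' @return Insertion track tibble aligned with `ta_index(sim$genomes[[strain_id]])`.
#' @export
simulate_library <- function(sim, strain_id, library_index = 1,
                             density_target = NULL, seed = NULL) {
  cfg <- sim$cfg
  density_target <- density_target %||% cfg$density_target
  if (density_target >= 0.995 || density_target <= 0) {
    abort("`density_target` unreachable.")
  }
  strain_i <- match(strain_id, names(sim$genomes))
  if (is.na(strain_i)) abort(paste0("unknown strain: ", strain_id))
  seed <- seed %||%
    ((cfg$seed * 10000L + strain_i * 100L + library_index) %% .Machine$integer.max)
  ta <- ta_index(sim$genomes[[strain_id]])
  state <- site_states(sim, strain_id, ta)
  sev <- sim$strain_severity[[strain_id]]
  w <- unname(cfg$state_insertion_prob[state])
  w[state == "ES"] <- w[state == "ES"] * sev
  f <- function(lam) mean(1 - exp(-lam * w)) - density_target
  lam <- stats::uniroot(f, c(1e-9, 1e7), tol = 1e-10)$root
  p_site <- 1 - exp(-lam * w)
  means <- unname(cfg$state_mean_count[state])
  # selection stringency scales escaper abundance as well as frequency
  means[state == "ES"] <- pmax(1.01, means[state == "ES"] * sev)
  with_seed_(seed, {
    ins <- runif(length(w)) < p_site
    counts <- numeric(length(w))
    counts[ins] <- 1 + rgeom(sum(ins), prob = 1 / means[ins])
    tibble(
      replicon_id = ta$replicon_id,
      library_id = sprintf("%s_lib%d", strain_id, library_index),
      pos = ta$pos,
      count = counts
    )
  })
}

#' Planted category of each TA site (intergenic = NE)
#' @noRd
site_states <- function(sim, strain_id, ta) {
  genes <- filter(sim$genes, .data$strain_id == !!strain_id)
  state <- rep("NE", nrow(ta))
  for (rep_id in unique(ta$replicon_id)) {
    sel <- ta$replicon_id == rep_id
    g <- genes[genes$replicon_id == rep_id, ]
    if (nrow(g) == 0) next
    pos <- ta$pos[sel]
    # genes are non-overlapping by construction: interval lookup
    idx <- findInterval(pos + 1, g$start)
    hit <- idx >= 1 & (pos + 2) <= g$end[pmax(idx, 1)]
    st <- rep("NE", length(pos))
    st[hit] <- g$category[idx[hit]]
    state[sel] <- st
  }
  state
}

#' Write a complete, self-describing fixture bundle
#'
#' Emits exactly the formats the analysis consumes: FASTA genomes, GFF3 +
#' TSV annotations, variableStep wig tracks (one per strain and library),
#' the orthogroups TSV, a COG table, the truth table (TSV), and the config
#' (YAML). Regenerating with the same seed is byte-identical.
#'
#' @param sim A `sim_pangenome`.
#' @param outdir Output directory (created if needed).
#' @param n_libraries Libraries per strain (defaults to the config).
#' @return `outdir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, outdir, n_libraries = NULL) {
  cfg <- sim$cfg
  n_libraries <- n_libraries %||% cfg$n_libraries
  for (d in c("", "genomes", "annotations", "tracks")) {
    dir.create(file.path(outdir, d), recursive = TRUE, showWarnings = FALSE)
  }
  strains <- names(sim$genomes)
  for (s in strains) {
    dna <- Biostrings::DNAStringSet(sim$genomes[[s]])
    Biostrings::writeXStringSet(dna, file.path(outdir, "genomes",
                                               paste0(s, ".fasta")))
    g <- filter(sim$genes, .data$strain_id == s)
    readr::write_tsv(
      tibble(gene_id = g$gene_id, replicon = g$replicon_id,
             start = g$start, end = g$end, strand = g$strand, cog = g$cog),
      file.path(outdir, "annotations", paste0(s, "_genes.tsv"))
    )
    gff <- GenomicRanges::GRanges(
      g$replicon_id,
      IRanges::IRanges(g$start, g$end),
      strand = g$strand,
      type = "gene", ID = g$gene_id, locus_tag = g$gene_id
    )
    rtracklayer::export(gff, file.path(outdir, "annotations",
                                       paste0(s, ".gff3")), format = "gff3")
    for (l in seq_len(n_libraries)) {
      tr <- simulate_library(sim, s, library_index = l)
      write_track(tr, file.path(outdir, "tracks",
                                sprintf("%s_lib%d.wig", s, l)))
    }
  }
  wide <- sim$orthogroups |>
    group_by(.data$orthogroup_id, .data$strain_id) |>
    summarise(genes = paste(.data$gene_id, collapse = ", "),
              .groups = "drop") |>
    tidyr::pivot_wider(names_from = "strain_id", values_from = "genes",
                       values_fill = "")
  names(wide)[1] <- "Orthogroup"
  readr::write_tsv(wide, file.path(outdir, "orthogroups.tsv"))
  readr::write_tsv(
    distinct(select(sim$genes, "gene_id", "cog")),
    file.path(outdir, "cog.tsv")
  )
  readr::write_tsv(sim$truth, file.path(outdir, "truth.tsv"))
  cfg_out <- unclass(cfg)
  yaml::write_yaml(cfg_out, file.path(outdir, "config.yaml"))
  invisible(outdir)
}

#' Planted-depletion Tn-seq experiment (single replicon)
#'
#' Builds an insertion track and matching gene index with known per-gene
#' depletion factors `d`: a gene's sites keep their baseline insertions with
#' probability `d` (so `d = 0` genes are fully depleted and `d = 1` genes
#' untouched), with baseline counts geometric around `lambda`. Used to
#' validate the Monte Carlo fitness estimator against a known truth.
#'
#' @param n_genes Genes (equal shares get each depletion factor).
#' @param ta_per_gene TA sites per gene.
#' @param lambda Mean read count at inserted sites.
#' @param depletion Depletion factors cycled over genes.
#' @param density Baseline insertion probability per site.
#' @param seed RNG seed.
#' @return List: `track`, `gene_index`, `truth` (tibble `gene_id`, `d`).
#' @export
simulate_depletion_experiment <- function(n_genes = 500, ta_per_gene = 20,
                                          lambda = 100,
                                          depletion = c(1, 0.5, 0.25, 0.1, 0),
                                          density = 0.85, seed = 1L) {
  with_seed_(seed, {
    d_gene <- rep_len(depletion, n_genes)
    n_sites <- n_genes * ta_per_gene
    pos <- (seq_len(n_sites) - 1L) * 16L
    gene_of_site <- rep(seq_len(n_genes), each = ta_per_gene)
    ins <- runif(n_sites) < density * d_gene[gene_of_site]
    counts <- numeric(n_sites)
    counts[ins] <- 1 + rgeom(sum(ins), prob = 1 / lambda)
    track <- tibble(replicon_id = "sim", library_id = "depletion",
                    pos = pos, count = counts)
    gene_index <- tibble(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      replicon_id = "sim",
      ta_sites = split(pos, gene_of_site),
      n_ta = ta_per_gene,
      no_data = FALSE
    )
    list(track = track, gene_index = gene_index,
         truth = tibble(gene_id = gene_index$gene_id, d = d_gene))
  })
}
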