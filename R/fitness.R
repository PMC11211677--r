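#' Generate one "Expected" pseudodataset
#'
#' The multiset of nonzero counts of the observed track is placed at a
#' uniformly random subset of distinct TA sites of the same cardinality; all
#' other sites get 0. Total reads, the count multiset, and the number of
#' unique insertions are preserved exactly, so the pseudodataset ensemble is
#' the natural null for per-gene insertion abundance.
#'
#' @param track Observed insertion track.
#' @return A track tibble with permuted counts.
#' @export
make_pseudodataset <- function(track) {
  nz <- track$count[track$count > 0]
  if (length(nz) == 0) abort("track has no insertions.")
  v <- numeric(nrow(track))
  v[sample.int(nrow(track), length(nz))] <- nz
  out <- track
  out$count <- v
  out
}

#' Monte Carlo pseudodataset fitness (log2 fold change)
#'
#' For each gene, observed insertion abundance (sum of normalized counts over
#' its trimmed TA sites) is compared against its distribution across
#' `n_pseudo` pseudodatasets ([make_pseudodataset()]). The fitness value is
#' \deqn{\log_2\frac{\mathrm{observed} + c}{\mathrm{expected\ mean} + c}}
#' with pseudocount `c`. Significance is the two-sided empirical tail
#' probability with add-one correction, Benjamini-Hochberg adjusted across
#' genes; a gene is flagged essential when `log2fc < -1` and adjusted
#' p < 0.05.
#'
#' @param track Normalized combined insertion track for one strain.
#' @param gene_index Gene table from [build_gene_ta_index()].
#' @param n_pseudo Number of pseudodatasets (>= 100).
#' @param pseudocount Pseudocount `c` added to both numerator and denominator.
#' @param seed RNG seed; the ensemble is reproducible given the seed.
#' @return Tibble: `gene_id`, `n_ta`, `observed`, `expected_mean`,
#'   `expected_sd`, `log2fc`, `p_raw`, `p_adj`, `es_flag`, `no_data`. Genes
#'   without TA sites carry `no_data = TRUE` and are excluded from the BH
#'   adjustment.
#' @export
gene_fitness <- function(track, gene_index, n_pseudo = 2000, pseudocount = 0.5,
                         seed = 1L) {
  stopifnot(n_pseudo >= 100)
  track_key <- paste(track$replicon_id, track$pos)
  idx_list <- purrr::map2(
    gene_index$replicon_id, gene_index$ta_sites,
    function(rep, sites) match(paste(rep, sites), track_key)
  )
  gene_of_site <- factor(
    rep(seq_along(idx_list), lengths(idx_list)),
    levels = seq_along(idx_list)
  )
  site_idx <- unlist(idx_list, use.names = FALSE)
  sum_by_gene <- function(v) {
    s <- numeric(length(idx_list))
    if (length(site_idx) > 0) {
      agg <- rowsum(v[site_idx], gene_of_site)
      s[as.integer(rownames(agg))] <- agg[, 1]
    }
    s
  }
  observed <- sum_by_gene(track$count)
  nz <- track$count[track$count > 0]
  if (length(nz) == 0) abort("track has no insertions.")
  n_sites <- nrow(track)
  pseudo <- with_seed_(seed, {
    m <- matrix(0, length(idx_list), n_pseudo)
    v <- numeric(n_sites)
    for (j in seq_len(n_pseudo)) {
      v[] <- 0
      v[sample.int(n_sites, length(nz))] <- nz
      m[, j] <- sum_by_gene(v)
    }
    m
  })
  expected_mean <- rowMeans(pseudo)
  expected_sd <- apply(pseudo, 1, sd)
  log2fc <- log2((observed + pseudocount) / (expected_mean + pseudocount))
  n_le <- rowSums(pseudo <= observed)
  n_ge <- rowSums(pseudo >= observed)
  p_raw <- pmin(1, 2 * pmin((1 + n_le) / (1 + n_pseudo),
                            (1 + n_ge) / (1 + n_pseudo)))
  no_data <- gene_index$n_ta == 0L
  p_adj <- rep(NA_real_, length(p_raw))
  p_adj[!no_data] <- p.adjust(p_raw[!no_data], method = "BH")
  tibble(
    gene_id = gene_index$gene_id,
    n_ta = gene_index$n_ta,
    observed = observed,
    expected_mean = expected_mean,
    expected_sd = expected_sd,
    log2fc = log2fc,
    p_raw = ifelse(no_data, NA_real_, p_raw),
    p_adj = p_adj,
    es_flag = !no_data & log2fc < -1 & p_adj < 0.05,
    no_data = no_data
  )
}

#' Per-gene fitness dispersion across strains
#'
#' Sample standard deviation (n-1 denominator) of each orthogroup's fitness
#' values across the strain columns of a core fitness matrix.
#'
#' @param fm Core fitness matrix from [core_fitness_matrix()] (or any tibble
#'   with an `orthogroup_id` column plus one numeric column per strain).
#' @param strains Strain column names; defaults to the matrix's `strains`
#'   attribute or all numeric columns.
#' @return Tibble `orthogroup_id`, `sd_fitness`.
#' @export
fitness_dispersion <- function(fm, strains = NULL) {
  strains <- strains %||% attr(fm, "strains") %||%
    names(fm)[vapply(fm, is.numeric, logical(1))]
  strains <- intersect(strains, names(fm))
  if (length(strains) < 2) abort("fitness dispersion needs >= 2 strains.")
  vals <- as.matrix(fm[, strains])
  if (anyNA(vals)) abort("fitness matrix has missing cells.")
  tibble(
    orthogroup_id = fm$orthogroup_id,
    sd_fitness = apply(vals, 1, sd)
  )
}
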