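#' Read an orthogroups table
#'
#' Expects the tab-separated dialect produced by orthology inference tools:
#' a header row with an orthogroup-id column followed by one column per
#' strain, and rows holding comma-separated gene lists (empty cell = strain
#' absent from that orthogroup).
#'
#' @param path Path to the orthogroups TSV.
#' @return Long tibble `orthogroup_id`, `strain_id`, `gene_id` (one row per
#'   gene). A gene appearing in more than one orthogroup is an error.
#' @export
read_orthogroups <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(
    .default = readr::col_character()
  ))
  if (ncol(raw) < 2) abort("orthogroups table needs an id column plus strains.")
  names(raw)[1] <- "orthogroup_id"
  out <- raw |>
    tidyr::pivot_longer(-"orthogroup_id", names_to = "strain_id",
                        values_to = "genes") |>
    filter(!is.na(.data$genes), .data$genes != "") |>
    mutate(gene_id = strsplit(.data$genes, ",\\s*")) |>
    select(-"genes") |>
    tidyr::unnest("gene_id") |>
    filter(.data$gene_id != "")
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0) {
    abort(paste0("gene(s) present in more than one orthogroup: ",
                 paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Conservation-subset labels from an orthology map
#'
#' Subset I: the gene's orthogroup spans all `n_strains_total` strains of the
#' reference pangenome; subset III: the orthogroup is strain-specific (spans
#' exactly one strain); subset II: everything in between (2 to
#' `n_strains_total - 1` strains). `n_strains_total` is a declared property
#' of the reference strain set, not inferred from the table, so subsets can
#' be defined against a larger pangenome than the assayed strains.
#'
#' @param orthogroups Long orthogroup tibble from [read_orthogroups()].
#' @param n_strains_total Number of strains in the reference pangenome.
#' @param all_genes Optional character vector of the full annotated gene
#'   universe; genes absent from the orthology map are labelled III with a
#'   warning (treated strain-specific).
#' @return Tibble `gene_id`, `subset` (factor I/II/III).
#' @export
assign_subsets <- function(orthogroups, n_strains_total, all_genes = NULL) {
  span <- orthogroups |>
    group_by(.data$orthogroup_id) |>
    summarise(n_strains = dplyr::n_distinct(.data$strain_id))
  if (any(span$n_strains > n_strains_total)) {
    abort("orthogroup spans more strains than `n_strains_total`.")
  }
  lab <- orthogroups |>
    left_join(span, by = "orthogroup_id") |>
    mutate(subset = dplyr::case_when(
      .data$n_strains == n_strains_total ~ "I",
      .data$n_strains == 1 ~ "III",
      TRUE ~ "II"
    )) |>
    select("gene_id", "subset")
  if (!is.null(all_genes)) {
    missing <- setdiff(all_genes, lab$gene_id)
    if (length(missing) > 0) {
      warn(sprintf(
        "%d gene(s) absent from the orthology map labelled III", length(missing)
      ))
      lab <- bind_rows(lab, tibble(gene_id = missing, subset = "III"))
    }
  }
  mutate(lab, subset = factor(.data$subset, levels = c("I", "II", "III")))
}

#' Assemble the cross-strain core fitness matrix
#'
#' Rows are orthogroups with at least one member gene in every test strain;
#' columns are the test strains; values are Monte Carlo log2 fold-change
#' fitness values. When a strain carries several copies of an orthogroup the
#' representative is configurable: the copy with the lowest fitness (`"min"`,
#' default: the most fitness-relevant copy), the mean across copies
#' (`"mean"`), or single-copy orthogroups only (`"single"`). Rows with zero
#' variance across strains make Pearson correlation undefined and are
#' rejected with an error naming the orthogroups.
#'
#' @param orthogroups Long orthogroup tibble.
#' @param fitness Named list of per-strain fitness tibbles (from
#'   [gene_fitness()]), names = strain ids, or one long tibble with a
#'   `strain_id` column.
#' @param test_strains Strains to include as columns.
#' @param multi_copy `"min"`, `"mean"`, or `"single"`.
#' @return Wide tibble `orthogroup_id` + one numeric column per test strain,
#'   with attribute `strains`.
#' @export
core_fitness_matrix <- function(orthogroups, fitness,
                                test_strains = NULL,
                                multi_copy = c("min", "mean", "single")) {
  multi_copy <- match.arg(multi_copy)
  if (is.list(fitness) && !is.data.frame(fitness)) {
    fitness <- bind_rows(fitness, .id = "strain_id")
  }
  test_strains <- test_strains %||% unique(fitness$strain_id)
  og <- filter(orthogroups, .data$strain_id %in% test_strains)
  fit <- fitness |>
    filter(.data$strain_id %in% test_strains) |>
    select("strain_id", "gene_id", "log2fc")
  member <- inner_join(og, fit, by = c("strain_id", "gene_id"))
  lost <- dplyr::anti_join(og, fit, by = c("strain_id", "gene_id"))
  if (nrow(lost) > 0) {
    abort(paste0("missing fitness for member gene(s), e.g. ",
                 paste(head(lost$gene_id, 5), collapse = ", ")))
  }
  if (multi_copy == "single") {
    multi <- member |>
      count(.data$orthogroup_id, .data$strain_id) |>
      filter(.data$n > 1)
    member <- filter(member, !.data$orthogroup_id %in% multi$orthogroup_id)
  }
  per_cell <- member |>
    group_by(.data$orthogroup_id, .data$strain_id) |>
    summarise(log2fc = if (multi_copy == "mean") mean(.data$log2fc)
              else min(.data$log2fc), .groups = "drop")
  wide <- tidyr::pivot_wider(per_cell, names_from = "strain_id",
                             values_from = "log2fc")
  keep <- complete.cases(wide[, test_strains])
  wide <- wide[keep, c("orthogroup_id", test_strains)]
  vals <- as.matrix(wide[, test_strains])
  const <- apply(vals, 1, function(x) max(x) - min(x) == 0)
  if (any(const)) {
    abort(paste0(
      "orthogroup(s) with identical fitness values across strains ",
      "(correlation undefined): ",
      paste(wide$orthogroup_id[const], collapse = ", ")
    ))
  }
  structure(wide, strains = test_strains)
}
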