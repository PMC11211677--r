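#' Locate TA dinucleotide sites in a DNA sequence
#'
#' The Himar1 mariner transposon inserts exclusively at TA dinucleotides, so
#' every downstream quantity (insertion density, per-gene counts, essentiality
#' calls) is defined over the ordered set of TA sites. A site is identified by
#' the 0-based coordinate of its T. Overlapping occurrences ("TATA") all count.
#'
#' @param sequence A single DNA string over A/C/G/T/N (case-insensitive), or a
#'   [Biostrings::DNAString].
#' @return Integer vector of 0-based positions `p` with
#'   `sequence[p..p+1] == "TA"`, strictly increasing. Empty sequence gives an
#'   empty vector. `N` never matches.
#' @examples
#' find_ta_sites("GATTACA")  # 3
#' find_ta_sites("TATATA")   # 0 2 4
#' @export
find_ta_sites <- function(sequence) {
  if (inherits(sequence, "DNAString") || inherits(sequence, "DNAStringSet")) {
    sequence <- as.character(sequence)
  }
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq_up <- toupper(sequence)
  if (nchar(seq_up) == 0) return(integer(0))
  if (grepl("[^ACGTN]", seq_up)) {
    abort("`sequence` contains characters other than A, C, G, T, N.")
  }
  # stringr drops overlapping matches; scan the character vector directly
  ch <- strsplit(seq_up, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 2) return(integer(0))
  which(ch[-n] == "T" & ch[-1] == "A") - 1L
}

#' Build a TA-site index for a (multi-replicon) genome
#'
#' Sinorhizobium and many other bacteria carry multipartite genomes; every
#' structure in this package is therefore keyed by `replicon_id` and
#' genome-level summaries aggregate replicons.
#'
#' @param genome A named character vector of sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file (read with
#'   [Biostrings::readDNAStringSet()]).
#' @return A tibble with one row per TA site: `replicon_id`, `pos` (0-based
#'   coordinate of the T), `replicon_length`.
#' @export
ta_index <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(genome, "DNAStringSet")) {
    lens <- Biostrings::width(genome)
    seqs <- as.character(genome)
  } else {
    stopifnot(is.character(genome))
    seqs <- genome
    lens <- nchar(genome)
  }
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  if (is.null(names(seqs))) names(seqs) <- ids
  # FASTA headers may carry descriptions after the first token
  ids <- sub("\\s.*$", "", ids)
  purrr::map2(ids, seq_along(seqs), function(id, i) {
    tibble(
      replicon_id = id,
      pos = find_ta_sites(seqs[[i]]),
      replicon_length = lens[[i]]
    )
  }) |>
    bind_rows()
}

#' Read gene annotations into the package's gene table
#'
#' Accepts GFF3 (via [rtracklayer::readGFF()]) or a tabular TSV with columns
#' `gene_id`, `replicon`/`replicon_id`, `start`, `end`, `strand`, and
#' optionally `cog`. Coordinates are 1-based inclusive (GFF3 convention).
#'
#' @param path Path to a GFF3 (`.gff`, `.gff3`) or TSV file.
#' @param feature_type For GFF3, which feature type to keep (`"gene"` or
#'   `"CDS"`).
#' @return Tibble with columns `gene_id`, `replicon_id`, `start`, `end`,
#'   `strand`, `cog`.
#' @export
read_genes <- function(path, feature_type = "gene") {
  stopifnot(file.exists(path))
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    g <- rtracklayer::readGFF(path)
    g <- as.data.frame(g)
    g <- g[g$type %in% feature_type, , drop = FALSE]
    id <- if (!is.null(g$locus_tag)) ifelse(is.na(g$locus_tag), g$ID, g$locus_tag) else g$ID
    out <- tibble(
      gene_id = as.character(id),
      replicon_id = as.character(g$seqid),
      start = as.integer(g$start),
      end = as.integer(g$end),
      strand = as.character(g$strand),
      cog = if (!is.null(g$cog)) as.character(g$cog) else NA_character_
    )
  } else {
    out <- readr::read_tsv(path, show_col_types = FALSE)
    nm <- names(out)
    if ("replicon" %in% nm && !"replicon_id" %in% nm) {
      out <- rename(out, replicon_id = "replicon")
    }
    if (!"cog" %in% names(out)) out$cog <- NA_character_
    out <- select(
      out, "gene_id", "replicon_id", "start", "end", "strand", "cog"
    )
    out <- mutate(out,
      gene_id = as.character(.data$gene_id),
      replicon_id = as.character(.data$replicon_id),
      start = as.integer(.data$start), end = as.integer(.data$end)
    )
  }
  if (any(out$start > out$end)) {
    abort("gene annotation with start > end encountered.")
  }
  out
}

#' Assign trimmed TA sites to genes
#'
#' Insertions at the extreme 5' and 3' ends of a gene are often tolerated
#' (non-disruptive), so a fraction of each end of the gene span is excluded
#' before TA sites are assigned. The trim length is `floor(trim_fraction *
#' gene_length)` bases from each end, computed on the genomic span regardless
#' of strand (mariner insertion disrupts both strands). A gene shorter than
#' `1/trim_fraction` bases loses no bases. A TA site inside two overlapping
#' genes is assigned to both.
#'
#' @param genes Gene table as returned by [read_genes()].
#' @param ta TA-site index from [ta_index()].
#' @param trim_fraction Fraction of each gene end to exclude, in `[0, 0.5)`.
#' @return `genes` with list-column `ta_sites` (0-based TA positions inside
#'   the trimmed span, genomic order), `n_ta`, and logical `no_data`
#'   (`n_ta == 0`).
#' @export
build_gene_ta_index <- function(genes, ta, trim_fraction = 0.05) {
  stopifnot(is.data.frame(genes), is.data.frame(ta))
  if (!(trim_fraction >= 0 && trim_fraction < 0.5)) {
    abort("`trim_fraction` must be in [0, 0.5).")
  }
  if (any(genes$start > genes$end)) abort("gene with start > end.")
  unknown <- setdiff(unique(genes$replicon_id), unique(ta$replicon_id))
  if (length(unknown) > 0) {
    abort(paste0("replicon_id not in TA index: ", paste(unknown, collapse = ", ")))
  }
  ta_by_rep <- split(ta$pos, ta$replicon_id)
  len_by_rep <- vapply(split(ta$replicon_length, ta$replicon_id), `[`, numeric(1), 1)
  bad <- genes$end > len_by_rep[genes$replicon_id]
  if (any(bad)) {
    abort(paste0("gene coordinates beyond replicon length: ",
                 paste(genes$gene_id[bad], collapse = ", ")))
  }
  sites <- purrr::pmap(
    list(genes$replicon_id, genes$start, genes$end),
    function(rep, s, e) {
      gl <- e - s + 1L
      trim <- floor(trim_fraction * gl)
      # inner 1-based span [s+trim, e-trim]; a TA site (0-based T at p)
      # lies inside iff p+1 >= s+trim and p+2 <= e-trim
      p <- ta_by_rep[[rep]]
      p[p + 1L >= s + trim & p + 2L <= e - trim]
    }
  )
  genes$ta_sites <- sites
  genes$n_ta <- lengths(sites)
  genes$no_data <- genes$n_ta == 0L
  as_tibble(genes)
}

#' Fraction of TA sites carrying at least one insertion
#'
#' Insertion density is the standard library-quality proxy for mariner
#' Tn-seq; libraries below 50% are flagged with a QC warning.
#'
#' @param track Insertion track tibble (see [track_from_positions()]).
#' @param qc_threshold Density below which a warning is emitted.
#' @return A single proportion.
#' @export
insertion_density <- function(track, qc_threshold = 0.5) {
  stopifnot(is.data.frame(track))
  if (nrow(track) == 0) abort("empty track.")
  d <- mean(track$count > 0)
  if (d < qc_threshold) {
    warn(sprintf(
      "insertion density %.3f is below the good-library threshold (%.2f)",
      d, qc_threshold
    ))
  }
  d
}

#' Write a TA-site index as BED
#'
#' 0-based half-open 2-bp features, one per TA site.
#'
#' @param ta TA index tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ta_bed <- function(ta, path) {
  readr::write_tsv(
    tibble(chrom = ta$replicon_id, start = ta$pos, end = ta$pos + 2L),
    path,
    col_names = FALSE
  )
  invisible(path)
}
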