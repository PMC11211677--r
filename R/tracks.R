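#' Build an insertion track from mapped insertion coordinates
#'
#' An insertion track is a tibble with one row per TA site of the genome
#' (columns `replicon_id`, `library_id`, `pos`, `count`), aligned 1:1 with the
#' TA index. Reads mapped to coordinates that are not TA sites are discarded
#' and reported in a warning.
#'
#' @param coords Tibble of mapped insertions with columns `replicon_id`,
#'   `pos` (0-based coordinate of the insertion-site T) and `reads`
#'   (multiplicity; defaults to 1 per row if absent).
#' @param ta TA index from [ta_index()].
#' @param library_id Label stored in the track.
#' @return Insertion track tibble.
#' @export
track_from_positions <- function(coords, ta, library_id = "lib1") {
  stopifnot(is.data.frame(ta))
  if (is.data.frame(coords) && !"reads" %in% names(coords)) coords$reads <- 1
  track <- tibble(
    replicon_id = ta$replicon_id,
    library_id = library_id,
    pos = ta$pos,
    count = 0
  )
  if (nrow(coords) == 0) return(track)
  lens <- vapply(split(ta$replicon_length, ta$replicon_id), `[`, numeric(1), 1)
  if (any(!coords$replicon_id %in% names(lens))) {
    abort("coordinates on a replicon absent from the TA index.")
  }
  if (any(coords$pos < 0 | coords$pos >= lens[coords$replicon_id])) {
    abort("insertion coordinate outside replicon bounds.")
  }
  key <- paste(coords$replicon_id, coords$pos)
  ta_key <- paste(ta$replicon_id, ta$pos)
  hit <- key %in% ta_key
  if (any(!hit)) {
    warn(sprintf(
      "%d read group(s) (%g reads) at non-TA coordinates discarded",
      sum(!hit), sum(coords$reads[!hit])
    ))
  }
  agg <- rowsum(coords$reads[hit], key[hit])
  idx <- match(rownames(agg), ta_key)
  track$count[idx] <- agg[, 1]
  track
}

#' Read a variableStep wig file as an insertion track
#'
#' Positions in wig files are 1-based; the track stores the 0-based T
#' coordinate. Positions not present in the TA index are discarded with a
#' warning; TA sites absent from the file get count 0. Duplicate position
#' lines are summed (with a warning).
#'
#' @param path Path to a variableStep wig file.
#' @param ta TA index.
#' @param library_id Label; defaults to the file name.
#' @return Insertion track tibble.
#' @export
read_track <- function(path, ta, library_id = NULL) {
  stopifnot(file.exists(path))
  library_id <- library_id %||% sub("\\.wig$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^(track|variableStep|fixedStep|#)", lines) &
                  nzchar(trimws(lines))]
  if (length(body) == 0) {
    has_header <- any(grepl("^(variableStep|fixedStep)", lines))
    if (!has_header) abort("malformed wig file: no step header found.")
    return(track_from_positions(tibble(replicon_id = character(),
                                       pos = integer(), reads = numeric()),
                                ta, library_id = library_id))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = "wig"),
    error = function(e) abort(paste0("malformed wig file: ", conditionMessage(e)))
  )
  df <- as.data.frame(gr)
  if (nrow(df) > 0 && any(df$width != 1)) {
    # spans collapse to their start coordinate
    df$end <- df$start
  }
  coords <- tibble(
    replicon_id = as.character(df$seqnames),
    pos = as.integer(df$start) - 1L,
    reads = as.numeric(df$score)
  )
  if (anyDuplicated(paste(coords$replicon_id, coords$pos))) {
    warn("duplicate wig positions summed")
  }
  track_from_positions(coords, ta, library_id = library_id)
}

#' Write an insertion track as variableStep wig
#'
#' Only TA sites with nonzero counts are written (wig convention).
#'
#' @param track Insertion track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track <- function(track, path) {
  nz <- track[track$count > 0, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    nz$replicon_id,
    IRanges::IRanges(start = nz$pos + 1L, width = 1L),
    score = nz$count
  )
  rtracklayer::export(gr, path, format = "wig")
  invisible(path)
}

#' Combine independent libraries by raw-count summation
#'
#' Summation before normalization preserves count semantics and is what
#' downstream density statistics require; the combined density is at least the
#' maximum of the individual densities.
#'
#' @param tracks A single long track tibble containing several `library_id`
#'   values, or a list of track tibbles over the same TA universe.
#' @param library_id Label for the combined track.
#' @return Insertion track tibble.
#' @export
combine_libraries <- function(tracks, library_id = "combined") {
  if (is.data.frame(tracks)) tracks <- split(tracks, tracks$library_id)
  if (length(tracks) == 0) abort("no tracks to combine.")
  ref <- tracks[[1]][order(tracks[[1]]$replicon_id, tracks[[1]]$pos), ]
  out <- tibble(
    replicon_id = ref$replicon_id,
    library_id = library_id,
    pos = ref$pos,
    count = ref$count
  )
  if (length(tracks) > 1) {
    for (t in tracks[-1]) {
      t <- t[order(t$replicon_id, t$pos), ]
      if (nrow(t) != nrow(out) ||
          !all(t$replicon_id == out$replicon_id & t$pos == out$pos)) {
        abort("tracks are defined over different TA universes.")
      }
      out$count <- out$count + t$count
    }
  }
  out
}

#' Trimmed-total-reads (TTR) normalization
#'
#' For each library, the mean of nonzero counts is computed after discarding
#' the top and bottom `trim` fraction of the sorted nonzero counts; all counts
#' are then rescaled so that this trimmed mean equals `target_mean`. Zeros
#' remain exactly zero, so insertion density is unchanged. The operation is
#' idempotent and scale-invariant.
#'
#' @param track Insertion track (single library, or long tibble normalized per
#'   `library_id`).
#' @param trim Fraction trimmed from each tail of the nonzero counts.
#' @param target_mean Trimmed mean after rescaling.
#' @return Track tibble with rescaled counts.
#' @export
ttr_normalize <- function(track, trim = 0.05, target_mean = 100) {
  stopifnot(is.data.frame(track))
  parts <- split(track, track$library_id)
  out <- purrr::map(parts, function(t) {
    nz <- sort(t$count[t$count > 0])
    if (length(nz) == 0) abort("all-zero track cannot be TTR-normalized.")
    k <- floor(trim * length(nz))
    kept <- if (k > 0) nz[(k + 1):(length(nz) - k)] else nz
    t$count <- t$count * (target_mean / mean(kept))
    t
  })
  res <- bind_rows(out)
  res[order(match(paste(res$library_id, res$replicon_id, res$pos),
                  paste(track$library_id, track$replicon_id, track$pos))), ]
}

#' Correct positional bias by LOESS smoothing
#'
#' Replication-associated trends (origin-to-terminus copy-number gradients)
#' bias raw counts along the chromosome. A locally weighted degree-1
#' regression with tricube weights ([stats::lowess()]) of counts on genomic
#' position is fitted per replicon, and each count is multiplied by
#' `global_mean / fitted`, with fitted values floored at a small positive
#' epsilon. Zero counts stay exactly zero.
#'
#' @param track Insertion track (single library).
#' @param span LOESS span (fraction of sites in each local window).
#' @return Corrected track tibble.
#' @export
loess_correct <- function(track, span = 0.1) {
  stopifnot(is.data.frame(track))
  if (nrow(track) < 50) abort("loess_correct needs at least 50 TA sites.")
  gmean <- mean(track$count)
  parts <- split(track, track$replicon_id)
  out <- purrr::map(parts, function(t) {
    t <- t[order(t$pos), ]
    fit <- lowess(t$pos, t$count, f = span)
    fitted <- fit$y[match(t$pos, fit$x)]
    eps <- 1e-9 * max(gmean, 1)
    if (all(fitted <= 0)) abort("degenerate LOESS fit: all fitted values <= 0.")
    fitted <- pmax(fitted, eps)
    t$count <- t$count * (gmean / fitted)
    t
  })
  res <- bind_rows(out)
  res[order(match(paste(res$replicon_id, res$pos),
                  paste(track$replicon_id, track$pos))), ]
}

#' Per-library QC summary
#'
#' @param track Long track tibble (any number of libraries).
#' @return Tibble: `library_id`, `total_reads`, `unique_insertions`,
#'   `n_sites`, `density`, `qc_pass` (density > 0.5).
#' @export
library_qc <- function(track) {
  track |>
    group_by(.data$library_id) |>
    summarise(
      total_reads = sum(.data$count),
      unique_insertions = sum(.data$count > 0),
      n_sites = n(),
      density = mean(.data$count > 0),
      qc_pass = .data$density > 0.5
    ) |>
    ungroup()
}

#' Combine, smooth, and depth-normalize a strain's libraries
#'
#' Fixed order: combine raw counts, LOESS positional correction, TTR
#' normalization.
#'
#' @inheritParams combine_libraries
#' @inheritParams ttr_normalize
#' @inheritParams loess_correct
#' @return Normalized combined track.
#' @export
prepare_track <- function(tracks, span = 0.1, trim = 0.05, target_mean = 100,
                          library_id = "combined") {
  combine_libraries(tracks, library_id = library_id) |>
    loess_correct(span = span) |>
    ttr_normalize(trim = trim, target_mean = target_mean)
}
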