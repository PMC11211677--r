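#' @keywords internal
hmm_states <- c("ES", "GA", "NE", "GD")

#' Default HMM parameters calibrated from a track
#'
#' Four fitness states over ordered TA-site counts: ES (essential, near-zero
#' counts apart from rare non-disruptive insertions), GA (growth advantage:
#' disrupting the gene is costly, mutants depleted), NE (nonessential), and GD
#' (growth disadvantage: mutants enriched). Emissions are geometric with
#' state-specific means pinned to the genome-wide mean of nonzero counts
#' \eqn{\bar\lambda}: ES \eqn{0.01\bar\lambda} (clamped to at least 0.5),
#' GA \eqn{0.1\bar\lambda}, NE \eqn{\bar\lambda}, GD \eqn{5\bar\lambda}.
#'
#' @param track Insertion track (normalized combined track recommended).
#' @param epsilon Per-site probability of leaving a state (split evenly among
#'   the other three states). Must lie in (0, 0.25).
#' @return List with `state_means` (named, increasing ES < GA < NE < GD),
#'   `epsilon`, `initial` (uniform).
#' @export
estimate_hmm_params <- function(track, epsilon = 1e-3) {
  stopifnot(is.data.frame(track))
  if (!(epsilon > 0 && epsilon < 0.25)) abort("`epsilon` must be in (0, 0.25).")
  nz <- track$count[track$count > 0]
  if (length(nz) == 0) abort("all-zero track: cannot calibrate HMM parameters.")
  lam <- mean(nz)
  means <- c(
    ES = max(0.01 * lam, 0.5),
    GA = 0.1 * lam,
    NE = lam,
    GD = 5 * lam
  )
  if (any(diff(means) <= 0)) {
    abort("state means are not strictly increasing; track mean too small.")
  }
  list(
    state_means = means,
    epsilon = epsilon,
    initial = setNames(rep(0.25, 4), hmm_states)
  )
}

#' Geometric emission log-probabilities for integer counts
#' @noRd
hmm_log_emission <- function(counts, state_means) {
  # geometric on {0,1,2,...} with success prob p = 1/(1+mean);
  # counts rounded to nearest integer (ties to even) after normalization
  x <- round(counts)
  vapply(state_means, function(m) {
    p <- 1 / (1 + m)
    x * log1p(-p) + log(p)
  }, numeric(length(x)))
}

#' Most probable state path by Viterbi decoding
#'
#' Transition matrix: stay with probability `1 - epsilon`, move to each other
#' state with probability `epsilon / 3`. Decoding is per replicon in genomic
#' order (replicons are independent chains), in log space, and deterministic.
#'
#' @param track Insertion track.
#' @param params HMM parameters from [estimate_hmm_params()].
#' @return Tibble `replicon_id`, `pos`, `count`, `state` aligned with the
#'   track (sorted by replicon and position).
#' @export
viterbi_states <- function(track, params) {
  stopifnot(is.data.frame(track))
  logT <- matrix(log(params$epsilon / 3), 4, 4)
  diag(logT) <- log(1 - params$epsilon)
  parts <- split(track, track$replicon_id)
  out <- purrr::map(parts, function(t) {
    t <- t[order(t$pos), ]
    le <- hmm_log_emission(t$count, params$state_means)  # n x 4
    n <- nrow(t)
    delta <- log(params$initial) + le[1, ]
    back <- matrix(0L, n, 4)
    if (n > 1) {
      for (i in 2:n) {
        cand <- delta + logT            # 4x4: [from, to]
        back[i, ] <- max.col(t(cand), ties.method = "first")
        delta <- cand[cbind(back[i, ], 1:4)] + le[i, ]
      }
    }
    path <- integer(n)
    path[n] <- which.max(delta)
    if (n > 1) for (i in n:2) path[i - 1] <- back[i, path[i]]
    t$state <- hmm_states[path]
    t
  })
  bind_rows(out)
}

#' Per-gene fitness category from a decoded state path
#'
#' A gene's category is the most frequent state among its trimmed TA sites;
#' ties are broken by extremeness priority ES > GA > GD > NE (states further
#' from the nonessential baseline win). Genes without TA sites are reported NE
#' with `no_data = TRUE`.
#'
#' @param states State path from [viterbi_states()].
#' @param gene_index Gene table with `ta_sites` from [build_gene_ta_index()].
#' @return Tibble: `gene_id`, `n_ta`, per-state site counts (`n_ES` ...),
#'   `call`, `no_data`.
#' @export
call_genes_hmm <- function(states, gene_index) {
  prio <- c(ES = 1, GA = 2, GD = 3, NE = 4)
  st_by_rep <- split(states, states$replicon_id)
  key <- purrr::map(st_by_rep, function(s) setNames(s$state, s$pos))
  rows <- purrr::pmap(
    list(gene_index$gene_id, gene_index$replicon_id, gene_index$ta_sites),
    function(gid, rep, sites) {
      st <- key[[rep]][as.character(sites)]
      cnt <- c(
        n_ES = sum(st == "ES"), n_GA = sum(st == "GA"),
        n_NE = sum(st == "NE"), n_GD = sum(st == "GD")
      )
      if (length(sites) == 0) {
        call <- "NE"
      } else {
        tab <- table(factor(st, levels = hmm_states))
        best <- names(tab)[tab == max(tab)]
        call <- best[which.min(prio[best])]
      }
      tibble(
        gene_id = gid, n_ta = length(sites),
        n_ES = cnt[["n_ES"]], n_GA = cnt[["n_GA"]],
        n_NE = cnt[["n_NE"]], n_GD = cnt[["n_GD"]],
        call = call, no_data = length(sites) == 0
      )
    }
  )
  bind_rows(rows)
}

#' Fit the four-state essentiality HMM and call genes
#'
#' Convenience wrapper: calibrates parameters, decodes the state path, and
#' produces gene-level calls.
#'
#' @inheritParams estimate_hmm_params
#' @inheritParams call_genes_hmm
#' @param params Optional pre-computed parameters (otherwise calibrated from
#'   the track).
#' @return An object of class `tn_hmm_fit`: list with `params`, `states`,
#'   `calls`. Supports [tidy()], [glance()], [autoplot()].
#' @export
fit_essentiality_hmm <- function(track, gene_index, params = NULL,
                                 epsilon = 1e-3) {
  params <- params %||% estimate_hmm_params(track, epsilon = epsilon)
  states <- viterbi_states(track, params)
  calls <- call_genes_hmm(states, gene_index)
  structure(
    list(params = params, states = states, calls = calls),
    class = "tn_hmm_fit"
  )
}

#' @export
print.tn_hmm_fit <- function(x, ...) {
  cat("Four-state Tn-seq essentiality HMM fit\n")
  cat("  state means:",
      paste(sprintf("%s=%.3g", names(x$params$state_means),
                    x$params$state_means), collapse = ", "), "\n")
  cat("  sites:", nrow(x$states), " genes:", nrow(x$calls), "\n")
  print(table(x$calls$call))
  invisible(x)
}
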