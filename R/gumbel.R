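#' Longest run of insertion-free TA sites
#'
#' @param counts Numeric vector of per-TA-site counts over a gene's trimmed
#'   sites, in genomic order.
#' @return Length of the longest consecutive stretch of zero counts (0 for an
#'   empty vector).
#' @export
longest_zero_run <- function(counts) {
  if (length(counts) == 0) return(0L)
  r <- rle(counts == 0)
  z <- r$lengths[r$values]
  if (length(z) == 0) 0L else as.integer(max(z))
}

#' Extreme-value null for the longest zero run
#'
#' Under a nonessential gene, each TA site is insertion-free independently
#' with probability `q`; the longest zero run over `n` sites follows (for
#' moderate `n`) a Gumbel law with mean
#' \deqn{\mu = \log_{1/q}(n(1-q)) + \gamma/\ln(1/q) - 1/2}
#' and variance \eqn{\sigma^2 = \pi^2 / (6 \ln^2(1/q)) + 1/12}
#' (\eqn{\gamma} the Euler-Mascheroni constant; the -1/2 and +1/12 terms are
#' the standard continuity corrections for the discrete run length).
#'
#' @param n Number of TA sites (>= 2).
#' @param q Genome-wide probability that a site carries no insertion,
#'   strictly inside (0, 1).
#' @return Named numeric vector `c(mu = ..., sigma = ...)`.
#' @export
gumbel_null_params <- function(n, q) {
  if (!(q > 0 && q < 1)) abort("`q` must be strictly inside (0, 1).")
  stopifnot(n >= 2)
  gamma_em <- 0.57721566490153286
  linv <- log(1 / q)
  mu <- log(n * (1 - q)) / linv + gamma_em / linv - 0.5
  sigma <- sqrt(pi^2 / (6 * linv^2) + 1 / 12)
  c(mu = mu, sigma = sigma)
}

#' Gumbel density parameterized by mean and SD
#' @noRd
dgumbel_mean_sd <- function(x, mu, sigma, log = FALSE) {
  gamma_em <- 0.57721566490153286
  b <- sigma * sqrt(6) / pi
  a <- mu - gamma_em * b
  z <- (x - a) / b
  ld <- -log(b) - z - exp(-z)
  if (log) ld else exp(ld)
}

#' Saturating alternative density for an essential gene
#'
#' Triangular density rising linearly on `[n/2, n]` and zero below: an
#' essential gene's insertion-free run should span most of the gene.
#' @noRd
des_triangular <- function(r, n, log = FALSE) {
  a <- n / 2
  d <- ifelse(r > a & r <= n, 2 * (r - a) / (n - a)^2, 0)
  if (log) log(d) else d
}

#' Bayesian essentiality calls from longest insertion-free runs
#'
#' For each gene the longest run \eqn{r_i} of zero-count TA sites among its
#' \eqn{n_i} trimmed sites is scored under a two-component mixture: a Gumbel
#' extreme-value null (nonessential; see [gumbel_null_params()]) versus a
#' saturating triangular alternative concentrated on runs spanning more than
#' half the gene. A Gibbs sampler alternates the per-gene essentiality
#' indicators \eqn{z_i} and the mixture weight (Beta(1,1) prior); the
#' reported `zbar` is the posterior mean of \eqn{z_i} over the post-burn-in
#' half of the sweeps. Genome-wide non-insertion probability `q` is estimated
#' as one minus the insertion density of the supplied track.
#'
#' @param track Normalized combined insertion track (genome-wide).
#' @param gene_index Gene table from [build_gene_ta_index()].
#' @param z_es Posterior probability at or above which a gene is called ES.
#' @param z_ne Posterior probability at or below which a gene is called NE.
#' @param min_ta Genes with fewer trimmed TA sites are called `TooShort`.
#' @param iters Total Gibbs sweeps (first half discarded as burn-in).
#' @param seed RNG seed (the sampler is bit-reproducible given the seed).
#' @return Object of class `tn_gumbel_fit`: list with `calls` (tibble
#'   `gene_id`, `n_ta`, `r`, `zbar`, `category` in ES / Uncertain / NE /
#'   TooShort), `q_hat`, and the settings used.
#' @export
fit_essentiality_gumbel <- function(track, gene_index, z_es = 0.99,
                                    z_ne = 0.05, min_ta = 4L,
                                    iters = 10000L, seed = 1L) {
  dens <- mean(track$count > 0)
  if (dens <= 0 || dens >= 1) {
    abort("insertion density of 0 or 1: non-insertion probability degenerate.")
  }
  q_hat <- 1 - dens
  cnt_by_rep <- split(track, track$replicon_id)
  cnt_key <- purrr::map(cnt_by_rep, function(t) setNames(t$count, t$pos))
  r <- purrr::map2_int(
    gene_index$replicon_id, gene_index$ta_sites,
    function(rep, sites) longest_zero_run(cnt_key[[rep]][as.character(sites)])
  )
  n_ta <- gene_index$n_ta
  eligible <- n_ta >= min_ta
  zbar <- rep(NA_real_, length(r))
  if (any(eligible)) {
    ni <- n_ta[eligible]
    ri <- r[eligible]
    pars <- vapply(ni, gumbel_null_params, numeric(2), q = q_hat)
    log_f_ne <- dgumbel_mean_sd(ri, pars["mu", ], pars["sigma", ], log = TRUE)
    log_f_es <- des_triangular(ri, ni, log = TRUE)
    zbar[eligible] <- with_seed_(seed, {
      m <- length(ri)
      w <- 0.5
      z <- rep(0L, m)
      burn <- floor(iters / 2)
      acc <- numeric(m)
      kept <- 0L
      for (it in seq_len(iters)) {
        lo <- log((1 - w) / w) + log_f_ne - log_f_es
        p <- ifelse(is.infinite(log_f_es) & log_f_es < 0, 0, 1 / (1 + exp(lo)))
        p[is.infinite(log_f_ne) & log_f_ne < 0 & !is.infinite(log_f_es)] <- 1
        z <- as.integer(runif(m) < p)
        w <- rbeta(1, 1 + sum(z), 1 + m - sum(z))
        if (it > burn) {
          acc <- acc + z
          kept <- kept + 1L
        }
      }
      acc / kept
    })
  }
  category <- dplyr::case_when(
    !eligible ~ "TooShort",
    zbar >= z_es ~ "ES",
    zbar <= z_ne ~ "NE",
    TRUE ~ "Uncertain"
  )
  calls <- tibble(
    gene_id = gene_index$gene_id, n_ta = n_ta, r = r,
    zbar = zbar, category = category
  )
  structure(
    list(calls = calls, q_hat = q_hat,
         settings = list(z_es = z_es, z_ne = z_ne, min_ta = min_ta,
                         iters = iters, seed = seed)),
    class = "tn_gumbel_fit"
  )
}

#' @export
print.tn_gumbel_fit <- function(x, ...) {
  cat("Gumbel longest-run Bayesian essentiality fit\n")
  cat(sprintf("  q_hat (non-insertion probability): %.4f\n", x$q_hat))
  print(table(x$calls$category))
  invisible(x)
}

#' Evaluate an expression with a temporary RNG seed
#' @noRd
with_seed_ <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
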