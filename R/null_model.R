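## RNG scoping: run `expr` under a private, seeded RNG stream and restore
## the caller's generator state afterwards.
.with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

## Deterministic per-drug seed so screening order never changes a drug's
## statistics: polynomial rolling hash of the drug id folded with the
## master seed, kept inside 32-bit integer range.
.drug_seed <- function(seed, drug_id) {
  h <- 0
  for (b in utf8ToInt(drug_id)) h <- (h * 131 + b) %% 2147483629
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

#' Permutation null distribution of ES and TCS for one drug
#'
#' Gene labels of the ranked list are permuted while the rank-ordering
#' (and hence the weight vector) stays fixed; equivalently, the gamma hit
#' positions are redrawn uniformly without replacement from the p ranks,
#' and ES/TCS are recomputed on the fixed weights. The same seed always
#' yields the identical ensemble.
#'
#' @inheritParams running_sum
#' @param n_perm number of permutations, default 1000.
#' @param seed integer RNG seed for this drug's stream.
#' @return list with numeric vectors `es` and `tcs`, each of length
#'   `n_perm`, all values in [0, 1].
#' @export
permute_null <- function(rl, hv, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(rl, "ranked_list"), inherits(hv, "hit_vector"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (hv$gamma < 1L) stop("permutation null undefined for gamma = 0")
  if (n_perm < 100L)
    warning("n_perm < 100: empirical p-value resolution is coarse")
  p <- rl$p
  g <- hv$gamma
  l_min <- which.min(abs(rl$rank_stat))
  if (g == p) {
    # every permutation reproduces the same (full) hit set
    sc <- suppressWarnings(enrichment_scores(rl, hv))
    return(list(es = rep(sc$es, n_perm), tcs = rep(sc$tcs, n_perm)))
  }
  w <- rl$weights
  es <- numeric(n_perm)
  lmax <- integer(n_perm)
  .with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sort.int(sample.int(p, g))
      sc <- .score_hit_positions(idx, w, p)
      es[b] <- sc[1L]
      lmax[b] <- sc[2L]
    }
  })
  list(es = es, tcs = abs(lmax - l_min) / (p - 1))
}

#' Normalized scores and empirical p-values
#'
#' The normalization factor is the mean of the drug's permutation-null
#' scores; the normalized score is the true score divided by it. The
#' empirical p-value is the proportion of permuted scores strictly greater
#' than the true score (so 0 is representable and rendered as "< 1/n_perm"
#' in text output).
#'
#' @param es,tcs observed scores for the drug.
#' @param es_nulls,tcs_nulls permutation-null score vectors from
#'   [permute_null()].
#' @return list with `nes`, `ntcs`, `es_p`, `tcs_p`.
#' @export
normalize_and_test <- function(es, tcs, es_nulls, tcs_nulls) {
  stopifnot(length(es_nulls) >= 1L, length(tcs_nulls) >= 1L)
  norm1 <- function(x, nulls) {
    m <- mean(nulls)
    if (!is.finite(m) || m <= 0) {
      warning("null mean is not positive; normalized score undefined")
      return(NA_real_)
    }
    x / m
  }
  list(
    nes = norm1(es, es_nulls),
    ntcs = norm1(tcs, tcs_nulls),
    es_p = mean(es_nulls > es),
    tcs_p = mean(tcs_nulls > tcs)
  )
}

#' Pooled-null false discovery rate (GSEA-style)
#'
#' For each drug with normalized score s, q(s) is the fraction of pooled
#' permuted normalized scores >= s divided by the fraction of observed
#' normalized scores >= s, clipped to [0, 1]. A monotone step-up pass then
#' makes the reported q non-increasing in score: each drug receives the
#' minimum raw q among drugs with a score no larger than its own.
#'
#' @param observed numeric vector of per-drug normalized scores.
#' @param pooled_nulls numeric vector pooling every drug's normalized null
#'   scores (each drug's nulls divided by that drug's null mean before
#'   pooling, for cross-drug comparability).
#' @param monotone apply the step-up pass (default TRUE).
#' @return numeric vector of q-values in [0, 1], aligned with `observed`.
#' @export
pooled_fdr <- function(observed, pooled_nulls, monotone = TRUE) {
  n <- length(observed)
  if (n == 0L) return(numeric(0))
  stopifnot(length(pooled_nulls) >= 1L)
  q <- vapply(observed, function(s) {
    num <- mean(pooled_nulls >= s)
    den <- mean(observed >= s)   # s itself is observed, so den > 0
    min(1, num / den)
  }, numeric(1))
  if (monotone && n > 1L) {
    o <- order(observed, decreasing = TRUE)
    qs <- q[o]
    qs <- rev(cummin(rev(qs)))   # q_i <- min over drugs with score <= s_i
    q[o] <- qs
  }
  q
}

#' Render an empirical p-value the way screen reports print it
#'
#' A stored p of 0 (the true score beat every permutation) is shown as
#' `"< 1/n_perm"`, e.g. `"<0.001"` at 1000 permutations.
#'
#' @param p numeric p-values.
#' @param n_perm number of permutations behind them.
#' @return character vector.
#' @export
format_empirical_p <- function(p, n_perm) {
  floor_txt <- paste0("<", format(1 / n_perm, scientific = FALSE, trim = TRUE))
  out <- format(p, digits = 3, scientific = FALSE, trim = TRUE)
  out[!is.na(p) & p == 0] <- floor_txt
  out[is.na(p)] <- NA_character_
  out
}
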