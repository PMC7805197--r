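#' Build the significance-ranked gene list
#'
#' Merges a DE table into the rank-ordered list the running-sum statistic
#' walks over. The ranking statistic T is, by default, -log10(significance)
#' carrying the sign of the effect; genes are sorted by |T| descending, so
#' rank 1 is the most significant gene and the least significant gene sits
#' at rank p. Ties in |T| are broken by lexicographic gene identifier for
#' deterministic output.
#'
#' @param de a [de_table()].
#' @param omega non-negative weight exponent of the running sum. `omega = 0`
#'   gives the classic unweighted Kolmogorov-Smirnov-style statistic;
#'   the default 1 weights each gene by |T|.
#' @param rank_stat_kind `"neglog10_significance"` (default) or
#'   `"signed_stat"`, in which case T is the signed effect column itself.
#' @return an object of class `ranked_list`: a list with elements
#'   `genes`, `weights` (|T|^omega), `disease_dirs` (sign of effect),
#'   `rank_stat` (signed T), `omega` and `p`.
#' @export
build_ranked_list <- function(de, omega = 1,
                              rank_stat_kind = c("neglog10_significance",
                                                 "signed_stat")) {
  stopifnot(inherits(de, "de_table"))
  rank_stat_kind <- match.arg(rank_stat_kind)
  if (!is.numeric(omega) || length(omega) != 1L || omega < 0)
    stop("omega must be a single non-negative number")
  tstat <- switch(rank_stat_kind,
    neglog10_significance = sign(de$effect) * -log10(de$significance),
    signed_stat = de$effect)
  abs_t <- abs(tstat)
  # radix sort: locale-independent lexicographic tie-break on gene id
  o <- order(-abs_t, de$gene, method = "radix")
  if (diff(range(abs_t)) == 0)
    warning("all ranking statistics are identical; ranking is tie-dominated")
  structure(list(
    genes = de$gene[o],
    weights = abs_t[o]^omega,
    disease_dirs = sign(de$effect[o]),
    rank_stat = tstat[o],
    omega = omega,
    p = length(o)
  ), class = "ranked_list")
}

#' Directional hit indicator for one drug
#'
#' A gene at rank j is a hit when it belongs to the drug's signature AND
#' the drug-induced direction opposes (antagonist mode, the signature
#' reversion principle) or matches (agonist mode) the disease-contrast
#' direction of that gene. Signature genes absent from the ranked list are
#' ignored; signature genes present with a non-matching sign remain in the
#' list as misses. A disease direction of 0 never matches.
#'
#' @param rl a [build_ranked_list()] result.
#' @param proto a [proto_matrix()].
#' @param drug_id drug identifier present in `proto`.
#' @param mode `"antagonist"` (default) or `"agonist"`.
#' @return an object of class `hit_vector`: list with `hit_flags`
#'   (logical, length p), `gamma` (number of hits), `mode`, `drug_id`.
#' @export
directional_hits <- function(rl, proto, drug_id,
                             mode = c("antagonist", "agonist")) {
  stopifnot(inherits(rl, "ranked_list"), inherits(proto, "proto_matrix"))
  mode <- match.arg(mode)
  sub <- proto[proto$drug == drug_id, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("drug '", drug_id, "' not present in the proto-matrix")
  idx <- match(rl$genes, sub$gene)
  drug_dir <- ifelse(is.na(idx), 0, sub$direction[idx])
  want <- if (mode == "antagonist") -rl$disease_dirs else rl$disease_dirs
  hit <- drug_dir != 0 & rl$disease_dirs != 0 & drug_dir == want
  structure(list(hit_flags = hit, gamma = sum(hit),
                 mode = mode, drug_id = drug_id),
            class = "hit_vector")
}

#' Running-sum statistic over the ranked list
#'
#' v(l) is the weighted fraction of hit genes at ranks <= l minus the
#' fraction of miss genes at ranks <= l:
#' \deqn{v(l) = \frac{\sum_{j \le l,\,hit} |T_{(j)}|^{\omega}}
#'                   {\sum_{j\,hit} |T_{(j)}|^{\omega}}
#'            - \frac{\#\{j \le l,\,miss\}}{p - \gamma}.}
#' Both fractions reach 1 at l = p, so v(p) = 0 for every valid input.
#'
#' @param rl a ranked list.
#' @param hv a hit vector with `gamma >= 1`.
#' @return numeric vector v(1..p).
#' @export
running_sum <- function(rl, hv) {
  stopifnot(inherits(rl, "ranked_list"), inherits(hv, "hit_vector"))
  p <- rl$p
  if (hv$gamma < 1L) stop("running sum undefined for gamma = 0")
  hit <- hv$hit_flags
  hw <- cumsum(rl$weights * hit)
  total <- hw[p]
  if (total > 0) {
    hit_frac <- hw / total
  } else {
    warning("all hit weights are zero; using unweighted hit fraction")
    hit_frac <- cumsum(hit) / hv$gamma
  }
  if (hv$gamma == p) {
    warning("every gene is a hit; returning the hit fraction alone")
    return(hit_frac)
  }
  hit_frac - cumsum(!hit) / (p - hv$gamma)
}

## Fast running-sum extrema from hit positions only.
##
## Between hits v is linear with negative slope, so max |v| is attained at a
## hit rank, the rank just before a hit, or at p (where v = 0 exactly).
## Cumulative sums are taken in the same index order as running_sum(), so the
## candidate values are bitwise identical to the full-vector path.
## Returns c(es, l_max).
.score_hit_positions <- function(idx, weights, p) {
  g <- length(idx)
  if (g == p) {  # degenerate: v is the hit fraction, max at l = p
    return(c(1, p))
  }
  ch <- cumsum(weights[idx])
  total <- ch[g]
  hf <- if (total > 0) ch / total else seq_len(g) / g
  i <- seq_len(g)
  denom <- p - g
  v_hit <- hf - (idx - i) / denom
  v_pre <- c(0, hf[-g]) - (idx - i) / denom  # at rank idx-1: same miss count
  cand_l <- c(idx, idx - 1L, p)
  cand_v <- c(v_hit, v_pre, 0)
  keep <- cand_l >= 1L
  cand_l <- cand_l[keep]
  cand_v <- abs(cand_v[keep])
  es <- max(cand_v)
  c(es, min(cand_l[cand_v == es]))
}

#' Enrichment score and target compatibility score for one drug
#'
#' The enrichment score is the maximum absolute deviation of the running
#' sum, ES = max_l |v(l)|, attained at rank `l_max` (smallest such rank on
#' ties). The target compatibility score measures how far the enrichment
#' peak sits from the point of minimal |T| (rank `l_min`, which is p under
#' the descending sort): `tcs_raw = |l_max - l_min|`, reported on [0, 1]
#' as `tcs = tcs_raw / (p - 1)` so maximal separation maps to 1.
#' The leading-edge (driver) genes are the hit genes at ranks <= `l_max`;
#' when the extreme deviation is negative (hits depleted from the top of
#' the list) the drivers are instead the hit genes at ranks > `l_max`, the
#' usual GSEA convention, so the set is never empty while `gamma >= 1`.
#'
#' @inheritParams running_sum
#' @return an object of class `enrichment_scores`: list with `es`, `l_max`,
#'   `l_min`, `tcs_raw`, `tcs`, `leading_edge` (gene ids in rank order).
#' @export
enrichment_scores <- function(rl, hv) {
  v <- running_sum(rl, hv)
  p <- rl$p
  av <- abs(v)
  es <- max(av)
  l_max <- which.max(av)            # first index attaining the max
  l_min <- which.min(abs(rl$rank_stat))
  tcs_raw <- abs(l_max - l_min)
  le <- if (v[l_max] >= 0) hv$hit_flags & seq_len(p) <= l_max
        else hv$hit_flags & seq_len(p) > l_max
  structure(list(
    es = es,
    l_max = l_max,
    l_min = l_min,
    tcs_raw = tcs_raw,
    tcs = tcs_raw / (p - 1),
    leading_edge = rl$genes[le]
  ), class = "enrichment_scores")
}
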