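# Independent oracles: literal loop transcriptions of the running-sum
# definition, kept free of any vectorized code from the package.

# v(l) by explicit double loop over ranks.
oracle_v <- function(abs_t, hit, omega) {
  p <- length(abs_t)
  g <- sum(hit)
  denom <- 0
  for (j in seq_len(p)) if (hit[j]) denom <- denom + abs_t[j]^omega
  v <- numeric(p)
  for (l in seq_len(p)) {
    hs <- 0
    ms <- 0
    for (j in seq_len(l)) {
      if (hit[j]) hs <- hs + abs_t[j]^omega else ms <- ms + 1
    }
    v[l] <- hs / denom - ms / (p - g)
  }
  v
}

# ES, l_max, l_min, TCS from the double-loop running sum.
oracle_scores <- function(abs_t, hit, omega) {
  p <- length(abs_t)
  v <- oracle_v(abs_t, hit, omega)
  es <- max(abs(v))
  l_max <- which(abs(v) == es)[1]
  l_min <- which(abs_t == min(abs_t))[1]
  tcs_raw <- abs(l_max - l_min)
  list(es = es, l_max = l_max, l_min = l_min,
       tcs_raw = tcs_raw, tcs = tcs_raw / (p - 1), v = v)
}

# Exact null mean of ES over every placement of g hits among p ranks.
oracle_exhaustive_null_mean <- function(abs_t, g, omega) {
  p <- length(abs_t)
  placements <- utils::combn(p, g)
  es <- apply(placements, 2, function(idx) {
    hit <- seq_len(p) %in% idx
    oracle_scores(abs_t, hit, omega)$es
  })
  mean(es)
}

# Construct core objects directly, bypassing the IO layer, for property tests.
make_ranked_list <- function(abs_t, dirs = rep(1, length(abs_t)), omega = 1,
                             genes = sprintf("g%04d", seq_along(abs_t))) {
  stopifnot(!is.unsorted(rev(abs_t)))
  structure(list(genes = genes, weights = abs_t^omega, disease_dirs = dirs,
                 rank_stat = abs_t * dirs, omega = omega, p = length(abs_t)),
            class = "ranked_list")
}

make_hits <- function(p, idx, mode = "antagonist") {
  structure(list(hit_flags = seq_len(p) %in% idx, gamma = length(idx),
                 mode = mode, drug_id = "drug"),
            class = "hit_vector")
}

# Random scored instance: descending positive |T| plus random hit ranks.
random_instance <- function(p, gamma, omega) {
  abs_t <- sort(rexp(p, rate = 0.5) + 1e-3, decreasing = TRUE)
  idx <- sort(sample.int(p, gamma))
  list(rl = make_ranked_list(abs_t, omega = omega),
       hv = make_hits(p, idx), abs_t = abs_t, idx = idx, omega = omega)
}
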