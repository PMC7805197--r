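#' Screen a disease DE profile against a drug proto-matrix
#'
#' The full pipeline: build the significance-ranked list, form per-drug
#' directional hit vectors, compute ES/TCS, permute each drug's null
#' ensemble, normalize and test, and pool the normalized nulls across all
#' screened drugs into GSEA-style FDR q-values for NES and NTCS
#' separately. Drugs with no directional hits appear in the report with NA
#' statistics and `n_hits = 0`.
#'
#' Per-drug permutation streams are seeded from a hash of (seed, drug id),
#' so each drug's statistics are invariant to the screening order and to
#' the presence of other drugs.
#'
#' @param de a [de_table()]: the disease-vs-control contrast.
#' @param proto a [proto_matrix()] of drug signatures.
#' @param mode `"antagonist"` (default; signature-reversion screening) or
#'   `"agonist"` (positively correlated identification).
#' @param omega running-sum weight exponent, default 1.
#' @param n_perm permutations per drug, default 1000.
#' @param seed master RNG seed, default 1.
#' @param fdr_alpha threshold for the `es_pass` / `tcs_pass` flag columns,
#'   default 0.05.
#' @param sort_key report order: `"es_p"` (default), `"tcs_p"`, `"nes"`,
#'   `"ntcs"`. P-value keys sort ascending with ties broken by the
#'   corresponding normalized score descending; score keys sort descending.
#' @param rank_stat_kind passed to [build_ranked_list()].
#' @return a `dpgsea_report`: a data frame with one row per drug and
#'   columns `drug`, `n_hits`, `es`, `nes`, `es_p`, `es_fdr`, `es_pass`,
#'   `tcs`, `ntcs`, `tcs_p`, `tcs_fdr`, `tcs_pass`, `leading_edge_size`,
#'   `leading_edge_genes` (list column). Attributes record `mode`,
#'   `omega`, `n_perm` and `seed`.
#' @export
screen <- function(de, proto, mode = c("antagonist", "agonist"),
                   omega = 1, n_perm = 1000L, seed = 1L,
                   fdr_alpha = 0.05, sort_key = c("es_p", "tcs_p", "nes", "ntcs"),
                   rank_stat_kind = "neglog10_significance") {
  stopifnot(inherits(de, "de_table"), inherits(proto, "proto_matrix"))
  mode <- match.arg(mode)
  sort_key <- match.arg(sort_key)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must be in (0, 1)")
  drugs <- proto_drugs(proto)
  if (length(drugs) == 0L) {
    warning("proto-matrix contains no drugs; returning an empty report")
    return(.empty_report(mode, omega, n_perm, seed))
  }
  rl <- build_ranked_list(de, omega = omega, rank_stat_kind = rank_stat_kind)
  if (!any(proto$gene %in% rl$genes)) {
    stop("no genes shared between the DE table and the proto-matrix ",
         "(identifier namespace mismatch?). DE examples: ",
         paste(utils::head(rl$genes, 3L), collapse = ", "),
         "; proto examples: ",
         paste(utils::head(unique(proto$gene), 3L), collapse = ", "))
  }
  n <- length(drugs)
  es <- nes <- es_p <- tcs <- ntcs <- tcs_p <- rep(NA_real_, n)
  n_hits <- integer(n)
  le <- vector("list", n)
  null_nes <- vector("list", n)   # per-drug normalized null scores
  null_ntcs <- vector("list", n)
  for (k in seq_len(n)) {
    hv <- directional_hits(rl, proto, drugs[k], mode = mode)
    n_hits[k] <- hv$gamma
    le[[k]] <- character(0)
    if (hv$gamma == 0L) next
    sc <- enrichment_scores(rl, hv)
    nulls <- permute_null(rl, hv, n_perm = n_perm,
                          seed = .drug_seed(seed, drugs[k]))
    st <- normalize_and_test(sc$es, sc$tcs, nulls$es, nulls$tcs)
    es[k] <- sc$es; tcs[k] <- sc$tcs
    nes[k] <- st$nes; ntcs[k] <- st$ntcs
    es_p[k] <- st$es_p; tcs_p[k] <- st$tcs_p
    le[[k]] <- sc$leading_edge
    m_es <- mean(nulls$es); m_tcs <- mean(nulls$tcs)
    null_nes[[k]] <- if (m_es > 0) nulls$es / m_es else numeric(0)
    null_ntcs[[k]] <- if (m_tcs > 0) nulls$tcs / m_tcs else numeric(0)
  }
  scored <- which(n_hits > 0L & !is.na(nes))
  es_fdr <- tcs_fdr <- rep(NA_real_, n)
  if (length(scored)) {
    pooled_es <- unlist(null_nes[scored], use.names = FALSE)
    pooled_tcs <- unlist(null_ntcs[scored], use.names = FALSE)
    es_fdr[scored] <- pooled_fdr(nes[scored], pooled_es)
    tcs_fdr[scored] <- pooled_fdr(ntcs[scored], pooled_tcs)
  }
  report <- data.frame(
    drug = drugs, n_hits = n_hits,
    es = es, nes = nes, es_p = es_p, es_fdr = es_fdr,
    es_pass = !is.na(es_fdr) & es_fdr <= fdr_alpha,
    tcs = tcs, ntcs = ntcs, tcs_p = tcs_p, tcs_fdr = tcs_fdr,
    tcs_pass = !is.na(tcs_fdr) & tcs_fdr <= fdr_alpha,
    leading_edge_size = lengths(le),
    stringsAsFactors = FALSE)
  report$leading_edge_genes <- le
  o <- switch(sort_key,
    es_p = order(report$es_p, -xtfrm(report$nes), report$drug,
                 method = "radix", na.last = TRUE),
    tcs_p = order(report$tcs_p, -xtfrm(report$ntcs), report$drug,
                  method = "radix", na.last = TRUE),
    nes = order(-xtfrm(report$nes), report$drug, method = "radix",
                na.last = TRUE),
    ntcs = order(-xtfrm(report$ntcs), report$drug, method = "radix",
                 na.last = TRUE))
  report <- report[o, , drop = FALSE]
  rownames(report) <- NULL
  attr(report, "mode") <- mode
  attr(report, "omega") <- omega
  attr(report, "n_perm") <- n_perm
  attr(report, "seed") <- seed
  attr(report, "proto_label") <- attr(proto, "label")
  class(report) <- c("dpgsea_report", "data.frame")
  report
}

.empty_report <- function(mode, omega, n_perm, seed) {
  report <- data.frame(
    drug = character(0), n_hits = integer(0),
    es = numeric(0), nes = numeric(0), es_p = numeric(0),
    es_fdr = numeric(0), es_pass = logical(0),
    tcs = numeric(0), ntcs = numeric(0), tcs_p = numeric(0),
    tcs_fdr = numeric(0), tcs_pass = logical(0),
    leading_edge_size = integer(0), stringsAsFactors = FALSE)
  report$leading_edge_genes <- list()
  attr(report, "mode") <- mode
  attr(report, "omega") <- omega
  attr(report, "n_perm") <- n_perm
  attr(report, "seed") <- seed
  class(report) <- c("dpgsea_report", "data.frame")
  report
}

#' @export
print.dpgsea_report <- function(x, n = 10L, ...) {
  cat(sprintf("dpGSEA screen report: %d drug(s), mode = %s, omega = %g, n_perm = %d\n",
              nrow(x), attr(x, "mode"), attr(x, "omega"), attr(x, "n_perm")))
  if (nrow(x) == 0L) return(invisible(x))
  shown <- utils::head(as.data.frame(x), n)
  np <- attr(x, "n_perm")
  shown$es_p <- format_empirical_p(shown$es_p, np)
  shown$tcs_p <- format_empirical_p(shown$tcs_p, np)
  shown$leading_edge_genes <- vapply(shown$leading_edge_genes, function(g) {
    if (length(g) > 4L) paste0(paste(g[1:4], collapse = ","), ",...")
    else paste(g, collapse = ",")
  }, character(1))
  num <- vapply(shown, is.numeric, logical(1))
  shown[num] <- lapply(shown[num], signif, digits = 4)
  print(shown, row.names = FALSE)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more row(s)\n")
  invisible(x)
}
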