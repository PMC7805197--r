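#' Simulate a disease DE table and drug proto-matrix with known truth
#'
#' Generates the inputs of a drug screen with controlled signal so power
#' and error rates are measurable without external data. Background genes
#' carry uniform(0,1) significances and standard-normal effects, emulating
#' a null DE contrast. Each spiked drug receives a signature of
#' `signature_size` genes; a fraction `concordance` of them are made
#' directional hits for antagonist matching (disease effect sign set
#' opposite the drug direction) and their significances are drawn as
#' 10^-(Exponential(mean = spike_strength) + 1), concentrating them in the
#' significant head of the ranked list at stochastic positions. The
#' remaining signature genes keep background-like values. Null drugs get
#' signatures drawn uniformly from all genes.
#'
#' @param n_genes number of genes in the DE table (default 2000).
#' @param n_drugs number of drugs in the proto-matrix.
#' @param n_spiked how many of them carry true signal (default 1; 0 gives
#'   an all-null screen).
#' @param signature_size genes per drug signature (default 20).
#' @param concordance fraction of a spiked signature set up as antagonist
#'   hits, in [0, 1] (default 1).
#' @param spike_strength mean of -log10(significance) above 1 for spiked
#'   genes (default 3).
#' @param disjoint force spiked signatures to be disjoint gene sets
#'   (default FALSE; signatures may overlap as in real proto-matrices).
#' @param seed integer RNG seed.
#' @return list with elements `de` (a [de_table()]), `proto`
#'   (a [proto_matrix()]), and `truth` (named character vector mapping
#'   drug id to `"spiked"` or `"null"`).
#' @export
simulate_screen_inputs <- function(n_genes = 2000L, n_drugs = 10L,
                                   n_spiked = 1L, signature_size = 20L,
                                   concordance = 1, spike_strength = 3,
                                   disjoint = FALSE, seed = 1L) {
  stopifnot(signature_size <= n_genes, concordance >= 0, concordance <= 1,
            n_spiked <= n_drugs, spike_strength > 0)
  if (disjoint && n_spiked * signature_size > n_genes)
    stop("disjoint signatures need n_spiked * signature_size <= n_genes")
  .with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    effect <- stats::rnorm(n_genes)
    sig <- stats::runif(n_genes)
    drug_ids <- sprintf("drug%02d", seq_len(n_drugs))
    spiked <- seq_len(n_drugs) <= n_spiked
    pool <- seq_len(n_genes)   # for disjoint spiked signatures
    rows <- vector("list", n_drugs)
    for (k in seq_len(n_drugs)) {
      if (spiked[k] && disjoint) {
        pick <- sample(pool, signature_size)
        pool <- setdiff(pool, pick)
      } else {
        pick <- sample.int(n_genes, signature_size)
      }
      dir <- sample(c(-1, 1), signature_size, replace = TRUE)
      if (spiked[k]) {
        n_conc <- round(concordance * signature_size)
        conc <- seq_len(signature_size) <= n_conc
        gi <- pick[conc]
        effect[gi] <- -dir[conc] * abs(stats::rnorm(length(gi)))
        sig[gi] <- 10^-(stats::rexp(length(gi), rate = 1 / spike_strength) + 1)
      }
      rows[[k]] <- data.frame(drug = drug_ids[k], gene = genes[pick],
                              direction = dir, rank = seq_len(signature_size),
                              stringsAsFactors = FALSE)
    }
    all <- do.call(rbind, rows)
    truth <- stats::setNames(ifelse(spiked, "spiked", "null"), drug_ids)
    list(
      de = de_table(genes, effect, sig),
      proto = proto_matrix(all$drug, all$gene, all$direction, all$rank,
                           label = "simulated"),
      truth = truth
    )
  })
}
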