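#' Running-sum plot for one drug
#'
#' Draws the running sum v(l) along the ranked list, with hit positions as
#' a rug, the enrichment-score peak marked, and the leading-edge region
#' shaded. Requires ggplot2.
#'
#' @inheritParams running_sum
#' @param title plot title; defaults to the drug id.
#' @return a ggplot object.
#' @export
plot_running_sum <- function(rl, hv, title = hv$drug_id) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_running_sum requires the ggplot2 package")
  v <- running_sum(rl, hv)
  sc <- enrichment_scores(rl, hv)
  df <- data.frame(rank = seq_len(rl$p), v = v)
  hits <- data.frame(rank = which(hv$hit_flags))
  ggplot2::ggplot(df, ggplot2::aes(x = rank, y = v)) +
    ggplot2::annotate("rect", xmin = 0.5, xmax = sc$l_max + 0.5,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "orange") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_step(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = sc$l_max, linetype = "dotted",
                        colour = "firebrick") +
    ggplot2::geom_rug(data = hits, ggplot2::aes(x = rank),
                      inherit.aes = FALSE, sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(title = title,
                  subtitle = sprintf("ES = %.3f at rank %d; TCS = %.3f",
                                     sc$es, sc$l_max, sc$tcs),
                  x = "rank in significance-ordered list", y = "running sum v(l)") +
    ggplot2::theme_minimal()
}
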