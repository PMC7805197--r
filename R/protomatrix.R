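#' Build a proto-matrix from per-drug DE tables
#'
#' Each drug's signature is the top `top_n` genes of its drug-vs-vehicle
#' DE table, ranked by absolute fold-change (`rank_by = "fc"`) or by
#' significance (`rank_by = "sig"`), with the drug-induced direction taken
#' from the sign of the effect. Signatures built at a smaller `top_n` are
#' prefixes of those built at a larger one under the same ranking.
#'
#' @param collection named list of [de_table()] objects, one per drug
#'   (names are drug identifiers, typically drug + cell line).
#' @param rank_by `"sig"` (significance ascending) or `"fc"`
#'   (|effect| descending). Ties are broken by the other criterion, then by
#'   gene identifier.
#' @param top_n signature size; drugs with fewer genes keep all their genes
#'   with a warning, or are dropped when `strict = TRUE`.
#' @param strict drop (rather than keep short) drugs with fewer than
#'   `top_n` usable genes.
#' @param max_p optional significance ceiling applied before ranking.
#' @return a [proto_matrix()] labeled `"<FC|Sig> Rank <top_n>"`.
#' @export
build_proto_matrix <- function(collection, rank_by = c("sig", "fc"),
                               top_n = 10L, strict = FALSE, max_p = NULL) {
  rank_by <- match.arg(rank_by)
  top_n <- as.integer(top_n)
  if (is.na(top_n) || top_n < 1L) stop("top_n must be a positive integer")
  if (is.null(names(collection)) || any(!nzchar(names(collection))))
    stop("collection must be a named list of DE tables (names = drug ids)")
  rows <- vector("list", length(collection))
  for (k in seq_along(collection)) {
    id <- names(collection)[k]
    de <- collection[[k]]
    stopifnot(inherits(de, "de_table"))
    if (!is.null(max_p)) de <- de[de$significance <= max_p, , drop = FALSE]
    zero <- de$effect == 0
    if (any(zero)) {
      warning("drug '", id, "': dropped ", sum(zero),
              " gene(s) with effect 0 (direction undefined)")
      de <- de[!zero, , drop = FALSE]
    }
    o <- switch(rank_by,
      fc = order(-abs(de$effect), de$significance, de$gene, method = "radix"),
      sig = order(de$significance, -abs(de$effect), de$gene, method = "radix"))
    if (nrow(de) < top_n) {
      if (strict) {
        warning("drug '", id, "' has fewer than ", top_n,
                " usable genes; dropped (strict)")
        next
      }
      warning("drug '", id, "' has only ", nrow(de), " usable genes; ",
              "keeping all of them")
    }
    keep <- utils::head(o, top_n)
    if (!length(keep)) next
    rows[[k]] <- data.frame(
      drug = id,
      gene = de$gene[keep],
      direction = sign(de$effect[keep]),
      rank = seq_along(keep),
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  label <- sprintf("%s Rank %d", if (rank_by == "fc") "FC" else "Sig", top_n)
  if (!length(rows)) {
    return(proto_matrix(character(0), character(0), numeric(0), integer(0),
                        label = label))
  }
  all <- do.call(rbind, rows)
  proto_matrix(all$drug, all$gene, all$direction, all$rank, label = label)
}
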