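#' Normalize gene identifiers
#'
#' Case-folds to upper case and strips surrounding whitespace so that
#' identifiers coming from different exports ("brca1 ", "BRCA1") merge.
#' The transformation is idempotent.
#'
#' @param x character vector of gene identifiers.
#' @return normalized character vector.
#' @export
normalize_gene_ids <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Construct a differential-expression table
#'
#' Validates and normalizes a per-gene DE result: one signed effect
#' (log2 fold-change or signed moderated statistic) and one significance
#' value (a p-value in (0, 1]) per gene.
#'
#' @param gene character vector of gene identifiers.
#' @param effect numeric vector of signed effects; must be finite.
#' @param significance numeric vector in (0, 1]. Values of 0 or below
#'   (underflow from an upstream DE tool) are clamped to `sig_floor` with a
#'   warning so log transforms stay defined.
#' @param sig_floor smallest representable significance, default `1e-300`.
#' @return a `data.frame` of class `de_table` with columns
#'   `gene`, `effect`, `significance`. Duplicate gene identifiers (after
#'   normalization) are collapsed to the row with the smallest significance,
#'   with a warning giving the number of rows dropped.
#' @export
de_table <- function(gene, effect, significance, sig_floor = 1e-300) {
  gene <- normalize_gene_ids(gene)
  effect <- as.numeric(effect)
  significance <- as.numeric(significance)
  n <- length(gene)
  if (length(effect) != n || length(significance) != n)
    stop("gene, effect and significance must have equal length")
  if (anyNA(gene) || any(gene == ""))
    stop("missing or empty gene identifiers")
  bad <- which(!is.finite(effect))
  if (length(bad))
    stop("non-finite effect at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  bad <- which(!is.finite(significance))
  if (length(bad))
    stop("non-finite significance at row(s): ", paste(utils::head(bad, 5L), collapse = ", "))
  if (any(significance > 1))
    stop("significance values must lie in (0, 1]")
  low <- significance <= 0
  if (any(low)) {
    warning(sum(low), " significance value(s) <= 0 clamped to ", sig_floor)
    significance[low] <- sig_floor
  }
  df <- data.frame(gene = gene, effect = effect, significance = significance,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene)) {
    o <- order(df$significance, df$gene)
    df <- df[o, , drop = FALSE]
    dup <- duplicated(df$gene)
    warning("collapsed ", sum(dup), " duplicate gene row(s) to the most significant entry")
    df <- df[!dup, , drop = FALSE]
    df <- df[order(match(df$gene, gene)), , drop = FALSE]
  }
  if (nrow(df) < 2L)
    stop("a DE table needs at least 2 distinct genes")
  rownames(df) <- NULL
  class(df) <- c("de_table", "data.frame")
  df
}

#' Read a differential-expression table from delimited text
#'
#' @param path path to a delimited text file with a header row.
#' @param columns named character vector mapping the logical columns
#'   `gene`, `effect`, `significance` to column names in the file.
#' @param sep field delimiter, default tab.
#' @param sig_floor passed to [de_table()].
#' @return a validated [de_table()].
#' @export
read_de_table <- function(path,
                          columns = c(gene = "gene", effect = "effect",
                                      significance = "significance"),
                          sep = "\t", sig_floor = 1e-300) {
  if (!file.exists(path)) stop("file not found: ", path)
  needed <- c("gene", "effect", "significance")
  if (!all(needed %in% names(columns)))
    stop("column map must name gene, effect and significance")
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (col in columns[needed]) {
    if (!col %in% names(raw))
      stop("required column '", col, "' not found in ", path)
  }
  eff <- suppressWarnings(as.numeric(raw[[columns[["effect"]]]]))
  sig <- suppressWarnings(as.numeric(raw[[columns[["significance"]]]]))
  bad <- which(is.na(eff) & !is.na(raw[[columns[["effect"]]]]))
  if (length(bad))
    stop("non-numeric effect value at line ", bad[1L] + 1L, " of ", path)
  bad <- which(is.na(sig) & !is.na(raw[[columns[["significance"]]]]))
  if (length(bad))
    stop("non-numeric significance value at line ", bad[1L] + 1L, " of ", path)
  de_table(raw[[columns[["gene"]]]], eff, sig, sig_floor = sig_floor)
}

## Accepted spellings for drug-induced regulation direction.
.parse_direction <- function(x) {
  tok <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(tok))
  out[tok %in% c("up", "+1", "1")] <- 1
  out[tok %in% c("down", "-1", "−1")] <- -1
  if (anyNA(out)) {
    bad <- unique(tok[is.na(out)])
    stop("unknown direction token(s): ", paste(sQuote(bad), collapse = ", "),
         " (accepted: up, down, +1, -1)")
  }
  out
}

#' Construct a proto-matrix
#'
#' A proto-matrix is a drug-defined gene-set prior: per drug (usually a
#' drug + cell-line combination), the top-ranked perturbation-responsive
#' genes together with the direction (+1 up / -1 down) the drug drives them.
#'
#' @param drug character vector of drug identifiers, e.g. `"paclitaxel_HT29"`.
#' @param gene character vector of gene identifiers.
#' @param direction drug-induced regulation: `up`/`down`, `+1`/`-1` or
#'   numeric +1/-1 (case-insensitive).
#' @param rank positive integer position of the gene within the drug's
#'   signature.
#' @param label free-text description of how the signatures were derived,
#'   e.g. `"Sig Rank 20"`.
#' @return a `data.frame` of class `proto_matrix` with columns
#'   `drug`, `gene`, `direction`, `rank` and a `"label"` attribute.
#' @export
proto_matrix <- function(drug, gene, direction, rank, label = "") {
  drug <- trimws(as.character(drug))
  gene <- normalize_gene_ids(gene)
  if (is.character(direction) || is.factor(direction)) {
    direction <- .parse_direction(direction)
  } else {
    direction <- as.numeric(direction)
    if (!all(direction %in% c(-1, 1)))
      stop("numeric direction must be +1 or -1")
  }
  rank <- as.integer(rank)
  n <- length(drug)
  if (length(gene) != n || length(direction) != n || length(rank) != n)
    stop("drug, gene, direction and rank must have equal length")
  if (n && any(is.na(rank) | rank < 1L))
    stop("rank must be a positive integer")
  key <- paste(drug, gene, sep = "\r")
  if (anyDuplicated(key)) {
    off <- unique(key[duplicated(key)])
    stop("duplicate (drug, gene) pair(s): ",
         paste(utils::head(gsub("\r", "/", off), 5L), collapse = ", "))
  }
  df <- data.frame(drug = drug, gene = gene, direction = direction,
                   rank = rank, stringsAsFactors = FALSE)
  attr(df, "label") <- label
  class(df) <- c("proto_matrix", "data.frame")
  df
}

#' Read a proto-matrix from delimited text
#'
#' Expects a header with columns `drug`, `gene`, `direction`, `rank`.
#' A header-only file yields a proto-matrix with zero drugs.
#'
#' @param path path to a delimited text file.
#' @param sep field delimiter, default tab.
#' @param label optional label; defaults to the file name.
#' @return a validated [proto_matrix()].
#' @export
read_proto_matrix <- function(path, sep = "\t", label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  for (col in c("drug", "gene", "direction", "rank")) {
    if (!col %in% names(raw))
      stop("required column '", col, "' not found in ", path)
  }
  if (is.null(label)) label <- basename(path)
  proto_matrix(raw$drug, raw$gene, raw$direction,
               suppressWarnings(as.integer(raw$rank)), label = label)
}

#' Drugs present in a proto-matrix
#' @param proto a [proto_matrix()].
#' @return character vector of distinct drug identifiers, in file order.
#' @export
proto_drugs <- function(proto) unique(proto$drug)

.report_columns <- c("drug", "n_hits", "es", "nes", "es_p", "es_fdr",
                     "es_pass", "tcs", "ntcs", "tcs_p", "tcs_fdr",
                     "tcs_pass", "leading_edge_size", "leading_edge_genes")

#' Write a screen report to delimited text
#'
#' One row per drug; the leading-edge gene list is joined with
#' `collapse` (default comma). The file round-trips through
#' [read_screen_report()].
#'
#' @param report a `dpgsea_report` as returned by [screen()].
#' @param path output path.
#' @param sep field delimiter, default tab.
#' @param collapse separator used to join leading-edge genes.
#' @export
write_screen_report <- function(report, path, sep = "\t", collapse = ",") {
  stopifnot(inherits(report, "data.frame"))
  out <- as.data.frame(report)
  out$leading_edge_genes <- vapply(out$leading_edge_genes,
                                   function(g) paste(g, collapse = collapse),
                                   character(1))
  out <- out[, intersect(.report_columns, names(out)), drop = FALSE]
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(out, con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read back a screen report written by [write_screen_report()]
#' @inheritParams write_screen_report
#' @return a `dpgsea_report` data frame with the leading-edge genes split
#'   back into a list column.
#' @export
read_screen_report <- function(path, sep = "\t", collapse = ",") {
  raw <- utils::read.delim(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  le_col <- as.character(raw$leading_edge_genes)
  le_col[is.na(le_col)] <- ""
  le <- strsplit(le_col, collapse, fixed = TRUE)
  raw$leading_edge_genes <- lapply(le, function(g) g[nzchar(g)])
  for (col in c("es_pass", "tcs_pass"))
    if (col %in% names(raw)) raw[[col]] <- as.logical(raw[[col]])
  class(raw) <- c("dpgsea_report", "data.frame")
  raw
}
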