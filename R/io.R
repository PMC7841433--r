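#' Read a bipartite network from a TSV edge list or dense matrix
#'
#' The edge-list dialect is the common PANDA export: a tab-separated file
#' with header `tf`, `gene`, `weight` (a fourth optional column `motif`
#' with 0/1 entries is read into the motif prior). Because inferred PANDA
#' networks are complete, missing TF-gene pairs default to weight 0;
#' `strict = TRUE` instead rejects incomplete lists. The dense dialect is a
#' matrix TSV with TFs as rows (first column = TF id, header = gene ids).
#'
#' @param path Path to a TSV file.
#' @param format `"edgelist"` (default) or `"dense"`.
#' @param strict Logical; when `TRUE`, a file that does not list every
#'   TF-gene pair is an error.
#' @return A [bipartite_network()].
#' @export
read_edge_list <- function(path, format = c("edgelist", "dense"), strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "dense") {
    dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
    w <- as.matrix(dt[, -1L, drop = FALSE])
    rownames(w) <- as.character(dt[[1L]])
    storage.mode(w) <- "double"
    return(bipartite_network(w))
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty edge list: ", path, call. = FALSE)
  need <- c("tf", "gene", "weight")
  if (!all(need %in% names(dt))) {
    stop("edge list must have header columns tf, gene, weight", call. = FALSE)
  }
  tf <- as.character(dt$tf)
  gene <- as.character(dt$gene)
  wcol <- dt$weight
  if (!is.numeric(wcol)) stop("non-numeric weight column in ", path, call. = FALSE)
  dup <- duplicated(paste0(tf, "\r", gene))
  if (any(dup)) {
    i <- which(dup)[1L]
    stop(sprintf("duplicate edge row for pair (%s, %s)", tf[i], gene[i]), call. = FALSE)
  }
  tf_ids <- unique(tf)
  gene_ids <- unique(gene)
  m <- length(tf_ids)
  n <- length(gene_ids)
  if (strict && nrow(dt) != m * n) {
    stop(sprintf("strict mode: edge list has %d rows but %d x %d = %d pairs",
                 nrow(dt), m, n, m * n), call. = FALSE)
  }
  w <- matrix(0, m, n, dimnames = list(tf_ids, gene_ids))
  idx <- cbind(match(tf, tf_ids), match(gene, gene_ids))
  w[idx] <- wcol
  prior <- NULL
  if ("motif" %in% names(dt)) {
    prior <- matrix(FALSE, m, n)
    prior[idx] <- as.logical(as.integer(dt$motif))
  }
  bipartite_network(w, tf_ids, gene_ids, motif_prior = prior)
}

#' Write a bipartite network as a TSV edge list
#'
#' Weights are serialized at full double precision (`%.17g`) so that
#' `read_edge_list(write_edge_list(net))` reproduces the network exactly.
#' When the network carries a motif prior, a fourth 0/1 column `motif` is
#' written.
#'
#' @param net A [bipartite_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "bipartite_network"))
  m <- length(net$tf_ids)
  n <- length(net$gene_ids)
  tf <- rep(net$tf_ids, times = n)
  gene <- rep(net$gene_ids, each = m)
  w <- sprintf("%.17g", as.vector(net$weights))
  if (is.null(net$motif_prior)) {
    lines <- c("tf\tgene\tweight", paste(tf, gene, w, sep = "\t"))
  } else {
    p <- as.integer(as.vector(net$motif_prior))
    lines <- c("tf\tgene\tweight\tmotif", paste(tf, gene, w, p, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a node partition as two-column TSV
#'
#' Tab-separated with header `node`, `community`.
#'
#' @param path Path to a TSV file.
#' @return For `read_partition`, a canonicalized partition vector.
#' @export
read_partition <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  if (!all(c("node", "community") %in% names(dt))) {
    stop("partition file must have header columns node, community", call. = FALSE)
  }
  as_partition(dt[, c("node", "community")])
}

#' @rdname read_partition
#' @param partition Named community-label vector.
#' @export
write_partition <- function(partition, path) {
  partition <- as_partition(partition)
  writeLines(c("node\tcommunity",
               paste(names(partition), partition, sep = "\t")), path)
  invisible(path)
}

#' Read a gene-set collection in GMT format
#'
#' @param path Path to a `.gmt` file (tab-separated: set name, description,
#'   member genes).
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}
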