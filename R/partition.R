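#' Node partition
#'
#' A partition assigns every network node to exactly one community. It is
#' represented as a named integer vector (names = node identifiers, values =
#' community labels). [canonicalize_partition()] relabels communities to the
#' contiguous set `1..K` in order of first appearance, which makes partitions
#' comparable across runs.
#'
#' @param x Named vector coercible to integer community labels, or a
#'   two-column data frame (node, community).
#' @return A named integer vector with contiguous labels starting at 1.
#' @examples
#' as_partition(c(a = 5, b = 5, c = 9))  # relabeled to 1, 1, 2
#' @export
as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("partition data frame needs columns node, community", call. = FALSE)
    v <- x[[2L]]
    names(v) <- as.character(x[[1L]])
    x <- v
  }
  if (is.null(names(x)) || any(names(x) == "")) {
    stop("a partition must be a named vector (names = node ids)", call. = FALSE)
  }
  if (anyDuplicated(names(x))) stop("duplicated node ids in partition", call. = FALSE)
  labs <- as.integer(x)
  if (anyNA(labs)) stop("community labels must be integers", call. = FALSE)
  names(labs) <- names(x)
  canonicalize_partition(labs)
}

#' @rdname as_partition
#' @export
canonicalize_partition <- function(x) {
  new <- match(x, unique(x))
  names(new) <- names(x)
  new
}

#' Normalized mutual information between two partitions
#'
#' Similarity between two partitions of the same node set, in `[0, 1]`.
#' Mutual information is normalized by the arithmetic mean of the two
#' partition entropies, `NMI = 2 I(p1; p2) / (H(p1) + H(p2))`, the same
#' normalization as igraph's `compare(method = "nmi")`. Two identical
#' partitions (up to relabeling) score 1; a partition carrying no
#' information about the other (including the single-community partition
#' against any non-trivial partition) scores 0.
#'
#' @param p1,p2 Partitions (named vectors, see [as_partition()]) over the
#'   same node set.
#' @return A number in `[0, 1]`.
#' @export
nmi <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (!setequal(names(p1), names(p2))) {
    stop("partitions must cover the same node set", call. = FALSE)
  }
  p2 <- p2[names(p1)]
  n <- length(p1)
  ct <- table(p1, p2)
  pij <- ct / n
  pi_ <- rowSums(pij)
  p_j <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, p_j)[nz]))
  h1 <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  h2 <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  if (h1 + h2 == 0) return(1)  # both trivial partitions: identical
  val <- 2 * mi / (h1 + h2)
  min(max(val, 0), 1)
}
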