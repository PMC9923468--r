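# Pairwise nucleotide differences with pairwise deletion of uncalled sites.
#
# Distances are raw site counts (unscaled), the convention needed to call two
# genomes "identical" despite ~50 uncalled bases each: a site contributes to
# d_ij only when both genomes carry a called base (A/C/G/T) there.

# integer encoding: A=1 C=2 G=3 T=4, N/- = NA; generators attach the
# encoding as an attribute so repeated analyses skip the re-encode
encode_alignment <- function(a) {
  enc <- attr(a, "encoded")
  if (!is.null(enc)) return(enc)
  m <- match(a$seq, c("A", "C", "G", "T"))
  dim(m) <- dim(a$seq)
  rownames(m) <- a$ids
  m
}

# per-column counts of each called base (L x 4)
column_base_counts <- function(M) {
  vapply(1:4, function(b) colSums(M == b, na.rm = TRUE),
         numeric(ncol(M)))
}

#' Pairwise nucleotide-difference matrix
#'
#' Computes, for every unordered pair of colonies, the number of alignment
#' positions at which both genomes carry a called base and those bases
#' differ (\code{D}), and the number of jointly called positions (\code{C}).
#' Uncalled positions (\code{N} or \code{-} in either member of a pair) are
#' excluded pair by pair (pairwise deletion).
#'
#' Only variable columns can contribute to \code{D}, so the computation
#' scans the (few) polymorphic columns; \code{C} is assembled from per-genome
#' missingness and the sparse overlap of uncalled positions.
#'
#' @param a a \code{mito_alignment}.
#' @return An object of class \code{mito_dist}: list with \code{D} and
#'   \code{C} (symmetric integer matrices with the colony ids as dimnames),
#'   \code{ids}, \code{L}, and \code{convention}.
#' @export
pairwise_difference_matrix <- function(a) {
  stopifnot(inherits(a, "mito_alignment"))
  M <- encode_alignment(a)
  n <- nrow(M); L <- ncol(M)
  called <- !is.na(M)
  n_miss <- L - rowSums(called)

  # jointly called sites: L - m_i - m_j + |miss_i intersect miss_j|
  C <- matrix(L, n, n) - outer(n_miss, n_miss, "+")
  if (any(n_miss > 0)) {
    idx <- which(!called, arr.ind = TRUE)
    S <- Matrix::sparseMatrix(i = idx[, 1L], j = idx[, 2L], x = 1,
                              dims = dim(M))
    C <- C + as.matrix(Matrix::tcrossprod(S))
  }

  counts <- column_base_counts(M)
  var_cols <- which(rowSums(counts > 0) >= 2L)
  # over the variable columns: differing called pairs = jointly called
  # minus same-base matches, via base-indicator crossproducts
  V <- M[, var_cols, drop = FALSE]
  Vc <- !is.na(V)
  D <- tcrossprod(Vc * 1)
  for (b in 1:4) {
    Ib <- (V == b & Vc) * 1
    D <- D - tcrossprod(Ib)
  }
  storage.mode(D) <- "integer"
  storage.mode(C) <- "integer"
  dimnames(D) <- dimnames(C) <- list(a$ids, a$ids)
  structure(list(D = D, C = C, ids = a$ids, L = L,
                 var_cols = var_cols,
                 convention = "pairwise deletion; raw site counts"),
            class = "mito_dist")
}

#' @export
print.mito_dist <- function(x, ...) {
  cat("Pairwise nucleotide differences (", x$convention, ")\n", sep = "")
  cat(" ", length(x$ids), "colonies,", x$L, "aligned bases\n")
  ut <- upper.tri(x$D)
  cat("  mean difference:", round(mean(x$D[ut]), 2), "bases;",
      "median jointly called:", stats::median(x$C[ut]), "\n")
  invisible(x)
}

#' Number of variable (polymorphic) alignment columns
#'
#' A column is variable when at least two distinct called bases
#' (\code{A/C/G/T}) occur in it; \code{N} and gaps are ignored.
#'
#' @param a a \code{mito_alignment}.
#' @return integer count of polymorphic columns.
#' @export
variable_site_count <- function(a) {
  stopifnot(inherits(a, "mito_alignment"))
  counts <- column_base_counts(encode_alignment(a))
  sum(rowSums(counts > 0) >= 2L)
}

#' Mean pairwise nucleotide difference
#'
#' Arithmetic mean of the site-count differences over the N(N-1)/2
#' unordered colony pairs. The value also carries, as attribute
#' \code{"fraction"}, the same mean expressed as a fraction of the median
#' number of jointly called sites.
#'
#' @param dm a \code{mito_dist}.
#' @return numeric scalar (mean differing bases) with attribute
#'   \code{fraction}.
#' @export
mean_pairwise_difference <- function(dm) {
  stopifnot(inherits(dm, "mito_dist"))
  n <- length(dm$ids)
  if (n < 2L) stop("insufficient data: need at least 2 sequences")
  ut <- upper.tri(dm$D)
  out <- mean(dm$D[ut])
  attr(out, "fraction") <- out / stats::median(dm$C[ut])
  out
}

#' Write a distance matrix as square TSV
#'
#' @param dm a \code{mito_dist}.
#' @param path output path.
#' @param which \code{"D"} (differences) or \code{"C"} (jointly called).
#' @return \code{path}, invisibly.
#' @export
write_distance_matrix <- function(dm, path, which = c("D", "C")) {
  which <- match.arg(which)
  utils::write.table(dm[[which]], path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
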