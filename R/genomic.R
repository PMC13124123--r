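#' Quality-control filter for a genotype matrix
#'
#' Removes SNPs with a minor allele frequency below `maf_min` or a call
#' rate below `call_threshold`; remaining missing genotypes are imputed to
#' the SNP mean. Allele frequencies are recomputed on the retained SNPs.
#'
#' @param geno animals x SNPs matrix of allele counts (0/1/2, NA allowed),
#'   with animal ids as rownames.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_threshold minimum per-SNP call rate (default 0.9).
#' @return Filtered numeric matrix with attribute `p` (allele
#'   frequencies of the retained SNPs).
#' @export
qc_filter <- function(geno, maf_min = 0.01, call_threshold = 0.9) {
  geno <- as.matrix(geno)
  call_rate <- 1 - colMeans(is.na(geno))
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- call_rate >= call_threshold & maf >= maf_min & maf > 0
  if (!any(keep)) stop("no SNPs survive QC (maf_min = ", maf_min, ")")
  out <- geno[, keep, drop = FALSE]
  if (anyNA(out)) {
    for (j in which(colSums(is.na(out)) > 0)) {
      mj <- mean(out[, j], na.rm = TRUE)
      out[is.na(out[, j]), j] <- mj
    }
  }
  attr(out, "p") <- colMeans(out) / 2
  out
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G* = Z Z' / (2 sum p_j (1 - p_j))` with `Z` the allele counts centered
#' by twice the allele frequency. Frequencies are computed from the
#' observed genotyped animals.
#'
#' @param geno animals x SNPs allele-count matrix (0/1/2, no missing).
#' @return Dense symmetric matrix with attribute `kernel = "Gstar"`.
#' @export
vanraden_G <- function(geno) {
  geno <- as.matrix(geno)
  p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all SNPs are monomorphic: sum 2 p (1 - p) = 0, G is undefined")
  Z <- sweep(geno, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  dimnames(G) <- list(rownames(geno), rownames(geno))
  attr(G, "kernel") <- "Gstar"
  G
}

#' Blend a genomic relationship matrix with its pedigree counterpart
#'
#' `G = w G* + (1 - w) A22`, which guarantees invertibility for `w < 1`
#' when `A22` is positive definite.
#'
#' @param Gstar raw genomic relationship matrix.
#' @param A22 pedigree relationships of the same (identically ordered)
#'   animals.
#' @param w weight on the genomic part (default 0.9).
#' @return Dense symmetric matrix with attribute `kernel = "G"`.
#' @export
blend_G <- function(Gstar, A22, w = 0.9) {
  if (!identical(rownames(Gstar), rownames(A22)))
    stop("G* and A22 must be indexed by the same animals in the same order")
  G <- w * as.matrix(Gstar) + (1 - w) * as.matrix(A22)
  dimnames(G) <- dimnames(as.matrix(Gstar))
  attr(G, "kernel") <- "G"
  G
}

#' Single-step relationship matrix inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` on the genotyped x genotyped
#' block, in the canonical animal order of `a_inv`.
#'
#' @param a_inv sparse pedigree A-inverse from [a_inverse()] (no groups,
#'   or with group rows appended — the correction never touches group
#'   equations).
#' @param G blended genomic relationship matrix.
#' @param A22 pedigree relationships of the genotyped animals, ordered as
#'   `G`.
#' @param genotyped_ids ids of the genotyped animals (must match `G`'s
#'   rownames as a set).
#' @return Sparse symmetric `Matrix` with attribute `kernel = "Hinv"`.
#' @export
h_inverse <- function(a_inv, G, A22, genotyped_ids = rownames(G)) {
  genotyped_ids <- as.character(genotyped_ids)
  if (!setequal(genotyped_ids, rownames(G)))
    stop("genotyped_ids do not match the animals in G")
  if (!all(genotyped_ids %in% rownames(a_inv)))
    stop("genotyped animals missing from the pedigree A-inverse")
  ord <- rownames(G)
  A22 <- as.matrix(A22)[ord, ord, drop = FALSE]
  Ginv <- chol2inv(chol(as.matrix(G)))
  A22inv <- chol2inv(chol(A22))
  corr <- Ginv - A22inv
  idx <- match(ord, rownames(a_inv))
  H <- as(a_inv, "CsparseMatrix")
  ng <- length(idx)
  Corr <- Matrix::sparseMatrix(
    i = rep(idx, ng), j = rep(idx, each = ng), x = as.vector(corr),
    dims = dim(a_inv), dimnames = dimnames(a_inv)
  )
  out <- Matrix::forceSymmetric((H + Corr + Matrix::t(H + Corr)) / 2)
  attr(out, "kernel") <- "Hinv"
  out
}

#' Read a whitespace-delimited genotype table
#'
#' First column is the animal id, remaining columns are 0/1/2 allele
#' counts (NA allowed).
#'
#' @param path file path.
#' @return Numeric matrix with animal ids as rownames.
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  M <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- ids
  M
}

#' Write a genotype matrix as whitespace-delimited text
#'
#' @param geno animals x SNPs matrix with rownames.
#' @param path file path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = rownames(geno), as.data.frame(geno),
                   check.names = FALSE)
  utils::write.table(df, path, quote = FALSE, row.names = FALSE)
}
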