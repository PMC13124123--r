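# Selected inverse of a sparse SPD matrix via the Takahashi equations on
# its simplicial LDL' factor: yields every inverse entry on the filled
# factor pattern, which covers the mixed-model-equation pattern needed
# for the EM-REML trace terms at a fraction of the cost of a dense
# inverse.

.ldl_factor <- function(C) {
  Matrix::Cholesky(Matrix::forceSymmetric(C), LDL = TRUE, perm = TRUE,
                   super = FALSE)
}

# returns an environment with the factor pattern, inverse values on the
# pattern, the permutation, and log|C|
.selected_inverse <- function(fac) {
  n <- length(fac@perm)
  z <- takahashi_inverse(fac@p, fac@i, fac@x, n)
  d <- fac@x[fac@p[seq_len(n)] + 1L]
  invp <- integer(n)
  invp[fac@perm + 1L] <- seq_len(n) - 1L   # 0-based positions in P
  list(p = fac@p, i = fac@i, z = z, invp = invp, logdet = sum(log(d)))
}

# inverse entries in the original (unpermuted) indexing; rows/cols 1-based
.cinv_entries <- function(sel, rows, cols) {
  pattern_lookup(sel$p, sel$i, sel$z,
                 sel$invp[rows], sel$invp[cols])
}
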