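# shared fixtures, memoized so expensive simulations run once per session
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

small_config <- function(seed = 42, ...) {
  sim_config(n_founders = 60, n_generations = 3, offspring_per_mating = 2,
             n_cows = 70, weeks_per_cow = 10, n_snps = 300, seed = seed, ...)
}

small_study <- function() memo("small_study", {
  st <- simulate_study(small_config())
  st$derived <- derive_metrics(st$records)
  st
})

small_study_rfi <- function() memo("small_study_rfi", {
  st <- simulate_study(small_config(seed = 7, dmi_structure = "rfi"))
  st$derived <- derive_metrics(st$records)
  st
})

# an LR-validation-sized study: enough cows and genotypes for forward
# splits, still quick to fit
lr_config <- function(seed, dmi_structure = "refi") {
  sim_config(n_founders = 80, n_generations = 4, offspring_per_mating = 2,
             n_cows = 140, weeks_per_cow = 10, n_snps = 600,
             genotyped_fraction = 0.5, dmi_structure = dmi_structure,
             seed = seed)
}

# dense GLS / BLUP oracle: V = ZGZ' + R, beta by GLS, u = GZ'Vinv(y - Xb)
gls_blup_oracle <- function(X, Z_list, G_list, Rdiag, y) {
  n <- length(y)
  V <- diag(Rdiag, n)
  for (k in seq_along(Z_list))
    V <- V + Z_list[[k]] %*% G_list[[k]] %*% t(Z_list[[k]])
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  beta <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% beta
  u <- lapply(seq_along(Z_list), function(k)
    as.vector(G_list[[k]] %*% t(Z_list[[k]]) %*% Vi %*% r))
  list(beta = as.vector(beta), u = u)
}

# textbook dense single-step H from A and G (genotyped animals last)
dense_H_oracle <- function(A, G, genotyped) {
  ids <- rownames(A)
  ng <- setdiff(ids, genotyped)
  ord <- c(ng, genotyped)
  A <- A[ord, ord]
  i1 <- seq_along(ng)
  i2 <- length(ng) + seq_along(genotyped)
  A11 <- A[i1, i1]; A12 <- A[i1, i2]; A22 <- A[i2, i2]
  G <- as.matrix(G)[genotyped, genotyped]
  A22i <- solve(A22)
  H11 <- A11 + A12 %*% A22i %*% (G - A22) %*% A22i %*% t(A12)
  H12 <- A12 %*% A22i %*% G
  H <- rbind(cbind(H11, H12), cbind(t(H12), G))
  dimnames(H) <- list(ord, ord)
  H
}
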