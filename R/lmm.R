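#' Legendre polynomial basis for lactation weeks
#'
#' Standardizes the week to `t = 2 (w - w_min) / (w_max - w_min) - 1` and
#' evaluates the plain (unnormalized) Legendre polynomials P0..P_order at
#' `t`.
#'
#' @param week lactation week(s), within `[w_min, w_max]`.
#' @param order polynomial order (default 4, i.e. five coefficients).
#' @param w_min,w_max standardization range (default 1 and 44).
#' @return Matrix `length(week) x (order + 1)`.
#' @export
legendre_basis <- function(week, order = 4, w_min = 1, w_max = 44) {
  if (any(week < w_min | week > w_max))
    stop("week outside the standardization range [", w_min, ", ", w_max, "]")
  t <- 2 * (week - w_min) / (w_max - w_min) - 1
  P <- matrix(0, length(t), order + 1)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- t
  if (order >= 2) for (k in 2:order) {
    # Bonnet recurrence: k P_k = (2k-1) t P_{k-1} - (k-1) P_{k-2}
    P[, k + 1] <- ((2 * k - 1) * t * P[, k] - (k - 1) * P[, k - 1]) / k
  }
  colnames(P) <- paste0("P", 0:order)
  P
}

#' Variance components for a univariate repeatability model
#'
#' @param htm variance of the herd-trial-month effect (intercept or
#'   regression-coefficient scale).
#' @param pe permanent-environment variance.
#' @param animal additive-genetic variance.
#' @param residual vector of residual variances, one per lactation period
#'   class (recycled to 5).
#' @param slope_scale logical; `TRUE` for regression-on-expected-intake
#'   models whose pe/animal components are on the regression-coefficient
#'   scale (see [heritability()]).
#' @return An object of class `fe_varcomp`.
#' @export
fe_varcomp <- function(htm, pe, animal, residual, slope_scale = FALSE) {
  stopifnot(htm > 0, pe > 0, animal > 0, all(residual > 0))
  structure(list(type = "univariate",
                 components = c(htm = htm, pe = pe, animal = animal),
                 residual = rep_len(residual, 5),
                 slope_scale = slope_scale),
            class = "fe_varcomp")
}

#' Variance components for the multi-trait energy-sink model
#'
#' @param M,P,Va 5x5 (co)variance matrices for the herd-trial-month,
#'   permanent-environment and additive-genetic effects of the traits
#'   (DMI, ECM, MBW, BWL, BWG).
#' @param Rp list of five 5x5 residual (co)variance matrices, one per
#'   lactation period class (a single matrix is recycled).
#' @param traits trait names.
#' @return An object of class `fe_varcomp`.
#' @export
fe_varcomp_mt <- function(M, P, Va, Rp,
                          traits = c("DMI", "ECM", "MBW", "BWL", "BWG")) {
  if (is.matrix(Rp)) Rp <- rep(list(Rp), 5)
  stopifnot(length(Rp) == 5)
  chk <- function(S) {
    S <- as.matrix(S)
    stopifnot(nrow(S) == length(traits), isSymmetric(unname(S), tol = 1e-8))
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("variance matrix is not positive semi-definite")
    dimnames(S) <- list(traits, traits)
    S
  }
  structure(list(type = "multitrait", traits = traits,
                 M = chk(M), P = chk(P), Va = chk(Va), Rp = lapply(Rp, chk)),
            class = "fe_varcomp")
}

#' Model specification for the six evaluation models
#'
#' Maps a metric name to the full mixed-model layout:
#' * `refi_rdc`, `refi_nrc2021` — DMI regressed on the corresponding eDMI
#'   with a fixed regression nested in herd-production-year and random
#'   regressions for herd-trial-month, permanent environment and the
#'   additive-genetic effect (no general intercept: the fixed
#'   herd-production-year slopes absorb level differences).
#' * `rfi` — one-step residual feed intake: DMI on the four energy-sink
#'   covariates plus fixed herd-production-year and random
#'   herd-trial-month, permanent-environment and additive intercepts.
#' * `ece` — as `rfi` with the sink covariates replaced by fixed
#'   lactation-week classes.
#' * `multitrait` — five traits (DMI, ECM, MBW, BWL, BWG) with a fixed
#'   fourth-order Legendre regression on lactation week nested in herd and
#'   the same random intercepts, all with 5x5 covariance structure.
#'
#' @param metric one of `"refi_rdc"`, `"refi_nrc2021"`, `"rfi"`, `"ece"`,
#'   `"multitrait"`.
#' @param legendre_range week-standardization range for the multi-trait
#'   model.
#' @return A list of class `fe_modelspec`.
#' @export
build_spec <- function(metric = c("refi_rdc", "refi_nrc2021", "rfi", "ece",
                                  "multitrait"),
                       legendre_range = c(1, 44)) {
  metric <- match.arg(metric)
  rand_int <- list(
    list(name = "htm", col = "htm", covariate = NULL, kernel = "iid"),
    list(name = "pe", col = "cow", covariate = NULL, kernel = "iid"),
    list(name = "animal", col = "cow", covariate = NULL, kernel = "pedigree")
  )
  spec <- switch(metric,
    refi_rdc = ,
    refi_nrc2021 = {
      ecol <- if (metric == "refi_rdc") "eDMI_RDC" else "eDMI_NRC2021"
      list(response = "dmi", multitrait = FALSE, edmi_col = ecol,
           fixed = list(list(type = "slope_by_class", col = "hpy",
                             covariate = ecol, name = "alpha_hpy")),
           random = list(
             list(name = "htm", col = "htm", covariate = ecol, kernel = "iid"),
             list(name = "pe", col = "cow", covariate = ecol, kernel = "iid"),
             list(name = "animal", col = "cow", covariate = ecol,
                  kernel = "pedigree")))
    },
    rfi = list(response = "dmi", multitrait = FALSE, edmi_col = NULL,
               fixed = list(
                 list(type = "cov", cols = c("ECM", "MBW", "BWL", "BWG"),
                      name = "sinks"),
                 list(type = "class", col = "hpy", name = "hpy")),
               random = rand_int),
    ece = list(response = "ECE", multitrait = FALSE, edmi_col = NULL,
               fixed = list(
                 list(type = "class", col = "week", name = "lwk"),
                 list(type = "class", col = "hpy", name = "hpy")),
               random = rand_int),
    multitrait = list(response = c("dmi", "ECM", "MBW", "BWL", "BWG"),
                      multitrait = TRUE, edmi_col = NULL,
                      legendre_range = legendre_range,
                      fixed = list(list(type = "legendre_by_class",
                                        col = "herd", name = "curve")),
                      random = rand_int)
  )
  spec$metric <- metric
  class(spec) <- "fe_modelspec"
  spec
}

# ---- design-matrix helpers --------------------------------------------------

.ind_matrix <- function(f, x = NULL, levels = NULL) {
  f <- as.character(f)
  if (is.null(levels)) levels <- sort(unique(f))
  j <- match(f, levels)
  if (anyNA(j)) stop("factor level missing from the configured level set")
  Matrix::sparseMatrix(i = seq_along(f), j = j,
                       x = if (is.null(x)) rep(1, length(f)) else x,
                       dims = c(length(f), length(levels)),
                       dimnames = list(NULL, levels))
}

# Build design columns for one term; returns list(mat, levels)
.term_design <- function(term, data, spec, ped_ids = NULL) {
  if (!is.null(term$type) && term$type == "cov") {
    M <- Matrix::Matrix(as.matrix(data[term$cols]), sparse = TRUE)
    colnames(M) <- term$cols
    return(list(mat = M, levels = term$cols))
  }
  if (!is.null(term$type) && term$type == "legendre_by_class") {
    rng <- spec$legendre_range
    B <- legendre_basis(data$week, order = 4, w_min = rng[1], w_max = rng[2])
    lev <- sort(unique(as.character(data[[term$col]])))
    mats <- lapply(lev, function(l) {
      ind <- as.numeric(data[[term$col]] == l)
      Matrix::Matrix(B * ind, sparse = TRUE)
    })
    M <- do.call(cbind, mats)
    cn <- as.vector(outer(colnames(B), lev, function(p, l) paste(l, p, sep = ":")))
    colnames(M) <- cn
    return(list(mat = M, levels = cn))
  }
  levels <- if (!is.null(term$kernel) && term$kernel != "iid") ped_ids else NULL
  x <- if (!is.null(term$covariate)) data[[term$covariate]] else NULL
  M <- .ind_matrix(data[[term$col]], x = x, levels = levels)
  list(mat = M, levels = colnames(M))
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse symmetric system `C s = r` for a model
#' specification, with per-record residual weighting by the lactation
#' period class and random-effect blocks augmented by the appropriate
#' precision (identity or relationship-matrix inverse, scaled by the
#' variance components). Multi-trait models use the Kronecker structure
#' of the trait (co)variances with trait-within-effect equation ordering.
#'
#' Rank-deficient fixed blocks are resolved by constraining the pivoted-out
#' columns to zero; the dropped levels are reported in the result.
#'
#' @param spec an [build_spec()] model specification.
#' @param data weekly record table with derived columns (see
#'   [derive_metrics()]) and effect codes `hpy`, `htm`, `cow`, `period`.
#' @param vc an [fe_varcomp()] or [fe_varcomp_mt()] object.
#' @param kernel_inverse sparse inverse relationship matrix (A-inverse or
#'   H-inverse) whose rownames define the additive-effect level space.
#' @return A list of class `fe_mme` with the coefficient matrix, right-hand
#'   side, design information and block index map.
#' @export
assemble_mme <- function(spec, data, vc, kernel_inverse = NULL) {
  has_kernel <- any(vapply(spec$random, function(t) t$kernel != "iid",
                           logical(1)))
  ped_ids <- if (has_kernel) rownames(kernel_inverse) else NULL
  if (has_kernel && is.null(ped_ids))
    stop("kernel_inverse must carry animal ids as dimnames")
  per <- data$period
  stopifnot(all(per %in% 1:5))

  designs <- list()
  blocks <- list()
  col0 <- 0
  for (term in spec$fixed) {
    d <- .term_design(term, data, spec, ped_ids)
    blocks[[term$name]] <- list(name = term$name, kind = "fixed",
                                idx = col0 + seq_len(ncol(d$mat)),
                                levels = d$levels)
    designs[[term$name]] <- d$mat
    col0 <- col0 + ncol(d$mat)
  }
  n_fixed_cols <- col0
  for (term in spec$random) {
    d <- .term_design(term, data, spec, ped_ids)
    blocks[[term$name]] <- list(name = term$name, kind = term$kernel,
                                idx = col0 + seq_len(ncol(d$mat)),
                                levels = d$levels)
    designs[[term$name]] <- d$mat
    col0 <- col0 + ncol(d$mat)
  }
  W <- do.call(cbind, designs)
  m <- ncol(W)

  if (!spec$multitrait) {
    y <- data[[spec$response]]
    w <- 1 / vc$residual[per]
    sW <- sqrt(w)
    # fixed-block rank check: constrain pivoted-out columns to zero
    dropped <- character(0)
    if (n_fixed_cols > 0) {
      Xd <- as.matrix(Matrix::crossprod(W[, seq_len(n_fixed_cols), drop = FALSE] * sW))
      qd <- qr(Xd)
      if (qd$rank < n_fixed_cols) {
        drop_idx <- sort(qd$pivot[(qd$rank + 1):n_fixed_cols])
        dropped <- colnames(W)[drop_idx]
        keep <- setdiff(seq_len(m), drop_idx)
        W <- W[, keep, drop = FALSE]
        shift <- function(ix) match(ix, keep)
        blocks <- lapply(blocks, function(b) {
          b$keep <- !is.na(shift(b$idx))
          b$levels <- b$levels[b$keep]
          b$idx <- shift(b$idx)[b$keep]
          b
        })
        m <- ncol(W)
      }
    }
    Ws <- W * sW
    C <- Matrix::forceSymmetric(Matrix::crossprod(Ws))
    rhs <- as.vector(Matrix::crossprod(W, w * y))
    C <- as(C, "generalMatrix")
    for (term in spec$random) {
      b <- blocks[[term$name]]
      sig <- vc$components[[term$name]]
      if (term$kernel == "iid") {
        C[cbind(b$idx, b$idx)] <- C[cbind(b$idx, b$idx)] + 1 / sig
      } else {
        C[b$idx, b$idx] <- C[b$idx, b$idx] + kernel_inverse / sig
      }
    }
    out <- list(C = Matrix::forceSymmetric(C), rhs = rhs, W = W, y = y,
                weights = w, blocks = blocks, spec = spec, vc = vc,
                n_traits = 1L, dropped = dropped, period = per,
                kernel_inverse = kernel_inverse)
  } else {
    traits <- vc$traits
    nt <- length(traits)
    Y <- as.matrix(data[spec$response])
    Rp_inv <- lapply(vc$Rp, function(S) chol2inv(chol(S)))
    C <- NULL
    rmat <- matrix(0, m, nt)
    for (p in sort(unique(per))) {
      rows <- which(per == p)
      Wp <- W[rows, , drop = FALSE]
      Sp <- Matrix::crossprod(Wp)
      Kp <- Matrix::kronecker(Sp, Matrix::Matrix(Rp_inv[[p]]))
      C <- if (is.null(C)) Kp else C + Kp
      rmat <- rmat + as.matrix(Matrix::crossprod(Wp, Y[rows, , drop = FALSE] %*% Rp_inv[[p]]))
    }
    rhs <- as.vector(t(rmat))
    C <- as(C, "CsparseMatrix")
    prec <- list(htm = chol2inv(chol(vc$M)), pe = chol2inv(chol(vc$P)),
                 animal = chol2inv(chol(vc$Va)))
    for (term in spec$random) {
      b <- blocks[[term$name]]
      eq <- as.vector(vapply(b$idx, function(j) as.integer((j - 1L) * nt) + seq_len(nt),
                             integer(nt)))
      K <- if (term$kernel == "iid") Matrix::Diagonal(length(b$idx)) else kernel_inverse
      C[eq, eq] <- C[eq, eq] + Matrix::kronecker(K, Matrix::Matrix(prec[[term$name]]))
    }
    out <- list(C = Matrix::forceSymmetric(C), rhs = rhs, W = W, y = Y,
                blocks = blocks, spec = spec, vc = vc, n_traits = nt,
                traits = traits, dropped = character(0), period = per,
                kernel_inverse = kernel_inverse)
  }
  class(out) <- "fe_mme"
  out
}

#' Solve assembled mixed-model equations
#'
#' Direct sparse Cholesky factorization up to `direct_max` equations,
#' otherwise Jacobi-preconditioned conjugate gradients.
#'
#' @param sys an [assemble_mme()] system.
#' @param method `"auto"`, `"direct"` or `"cg"`.
#' @param tol relative-residual convergence tolerance for CG.
#' @param max_iter CG iteration cap.
#' @param direct_max largest system solved directly under `"auto"`.
#' @return A list of class `fe_fit`; see [fitted_parts()] and [ebv()].
#' @export
solve_mme <- function(sys, method = c("auto", "direct", "cg"), tol = 1e-10,
                      max_iter = 5000, direct_max = 60000) {
  method <- match.arg(method)
  n <- length(sys$rhs)
  use_direct <- method == "direct" || (method == "auto" && n <= direct_max)
  if (use_direct) {
    sol <- tryCatch({
      fac <- Matrix::Cholesky(sys$C, LDL = FALSE, perm = TRUE)
      as.vector(Matrix::solve(fac, sys$rhs))
    }, error = function(e) as.vector(Matrix::solve(sys$C, sys$rhs)))
    iters <- NA_integer_
  } else {
    cg <- .pcg(sys$C, sys$rhs, tol = tol, max_iter = max_iter)
    if (!cg$converged)
      stop("conjugate-gradient solver did not converge in ", max_iter,
           " iterations (relative residual ", signif(cg$relres, 3), ")")
    sol <- cg$x
    iters <- cg$iters
  }
  relres <- sqrt(sum((as.vector(sys$C %*% sol) - sys$rhs)^2)) /
    max(sqrt(sum(sys$rhs^2)), .Machine$double.eps)
  .make_fit(sys, sol, iters = iters, relres = relres)
}

.pcg <- function(C, b, x0 = NULL, tol = 1e-10, max_iter = 5000) {
  d <- Matrix::diag(C)
  d[d <= 0] <- 1
  x <- if (is.null(x0)) numeric(length(b)) else x0
  r <- b - as.vector(C %*% x)
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bn <- max(sqrt(sum(b^2)), .Machine$double.eps)
  for (it in seq_len(max_iter)) {
    Cp <- as.vector(C %*% p)
    alpha <- rz / sum(p * Cp)
    x <- x + alpha * p
    r <- r - alpha * Cp
    if (sqrt(sum(r^2)) / bn < tol)
      return(list(x = x, iters = it, converged = TRUE,
                  relres = sqrt(sum(r^2)) / bn))
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  list(x = x, iters = max_iter, converged = FALSE,
       relres = sqrt(sum(r^2)) / bn)
}

.make_fit <- function(sys, sol, iters = NA, relres = NA) {
  nt <- sys$n_traits
  solutions <- lapply(sys$blocks, function(b) {
    if (nt == 1L) {
      v <- sol[b$idx]
      names(v) <- b$levels
      v
    } else {
      eq <- as.vector(vapply(b$idx, function(j) as.integer((j - 1L) * nt) + seq_len(nt),
                             integer(nt)))
      M <- matrix(sol[eq], ncol = nt, byrow = TRUE,
                  dimnames = list(b$levels, sys$traits))
      M
    }
  })
  if (nt == 1L) {
    fitted <- as.vector(sys$W %*% sol)
    resid <- sys$y - fitted
  } else {
    Smat <- matrix(sol, ncol = nt, byrow = TRUE)
    fitted <- as.matrix(sys$W %*% Smat)
    colnames(fitted) <- sys$traits
    resid <- sys$y - fitted
  }
  fit <- list(solutions = solutions, fitted = fitted, residuals = resid,
              sol = sol, sys = sys, spec = sys$spec, vc = sys$vc,
              dropped = sys$dropped,
              diagnostics = list(iterations = iters, relres = relres))
  # fitted energy-sink part of the one-step RFI model (expected DMI)
  if (sys$spec$metric == "rfi" && nt == 1L) {
    b <- sys$blocks$sinks
    fit$edmi_fit <- as.vector(sys$W[, b$idx, drop = FALSE] %*% sol[b$idx])
    fit$sink_coefficients <- stats::setNames(sol[b$idx], b$levels)
  }
  if (!is.null(sys$spec$edmi_col)) fit$mean_edmi <- attr(sys, "mean_edmi")
  class(fit) <- "fe_fit"
  fit
}

#' Extract breeding values from a fitted model
#'
#' For the regression-on-expected-intake models the additive solutions are
#' slopes per unit eDMI; they are rescaled to the DMI scale by the data
#' mean of the eDMI covariate (stored at fit time) unless `scale =
#' "slope"`. The one-step RFI and ECE models return the additive
#' intercepts directly; the multi-trait model returns one column per
#' trait.
#'
#' @param fit an `fe_fit` object.
#' @param scale `"metric"` (default) or `"slope"`.
#' @return Data frame with `id` and `ebv` (or trait columns).
#' @export
ebv <- function(fit, scale = c("metric", "slope")) {
  scale <- match.arg(scale)
  u <- fit$solutions$animal
  if (is.matrix(u)) {
    return(data.frame(id = rownames(u), as.data.frame(u),
                      row.names = NULL, check.names = FALSE))
  }
  if (!is.null(fit$mean_edmi) && scale == "metric") u <- u * fit$mean_edmi
  data.frame(id = names(u), ebv = unname(u), row.names = NULL)
}

#' Fit an evaluation model for one metric
#'
#' End-to-end convenience: builds the model specification, assembles and
#' solves the mixed-model equations under the pedigree or single-step
#' kernel.
#'
#' @param metric metric name understood by [build_spec()].
#' @param data derived weekly record table.
#' @param ped an [fe_pedigree()].
#' @param vc variance components for the model.
#' @param kernel `"pedigree"` (A-inverse) or `"ssgblup"` (H-inverse).
#' @param geno genotype matrix (required for `"ssgblup"` unless `kinv` is
#'   given).
#' @param kinv optional precomputed kernel inverse (overrides
#'   `kernel`/`geno`); its rownames define the animal equation space.
#' @param groups optional unknown-parent-group assignment from
#'   [assign_upg()], used when building the A-inverse.
#' @param blend_w genomic blending weight (default 0.9).
#' @param ... passed to [solve_mme()].
#' @return An `fe_fit` object.
#' @export
fit_metric <- function(metric, data, ped, vc, kernel = c("pedigree", "ssgblup"),
                       geno = NULL, kinv = NULL, groups = NULL, blend_w = 0.9,
                       ...) {
  kernel <- match.arg(kernel)
  spec <- build_spec(metric)
  if (is.null(kinv)) {
    ainv <- a_inverse(ped, groups = groups)
    if (kernel == "pedigree") {
      kinv <- ainv
    } else {
      if (is.null(geno)) stop("ssgblup kernel requires a genotype matrix")
      A22 <- a_submatrix(ped, rownames(geno))
      G <- blend_G(vanraden_G(geno), A22, w = blend_w)
      kinv <- h_inverse(ainv, G, A22)
    }
  }
  keep <- stats::complete.cases(data[unique(c(spec$response, spec$edmi_col))])
  data <- data[keep, , drop = FALSE]
  sys <- assemble_mme(spec, data, vc, kinv)
  if (!is.null(spec$edmi_col))
    attr(sys, "mean_edmi") <- mean(data[[spec$edmi_col]])
  fit <- solve_mme(sys, ...)
  fit$cow_ids <- as.character(data$cow)
  fit
}
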