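#' EM-REML variance components for a univariate repeatability model
#'
#' Expectation-maximization REML on Henderson's mixed-model equations
#' with exact trace terms computed from the inverse of the coefficient
#' matrix (refactorized each round). Residual variances are updated per
#' lactation period class. The restricted log-likelihood is tracked and
#' is non-decreasing up to numerical slack.
#'
#' @param spec univariate [build_spec()] specification.
#' @param data derived weekly record table.
#' @param init an [fe_varcomp()] with starting values.
#' @param kernel_inverse sparse relationship-matrix inverse (A or H).
#' @param tol relative-change convergence tolerance (default 1e-6).
#' @param max_iter iteration cap (default 500).
#' @param verbose print iteration diagnostics.
#' @return An `fe_varcomp` with attributes `trace` (per-iteration
#'   data frame), `converged`, `iterations` and `n_period` (record counts
#'   per period class, used by [heritability()]).
#' @export
em_reml <- function(spec, data, init, kernel_inverse = NULL, tol = 1e-6,
                    max_iter = 500, verbose = FALSE) {
  if (spec$multitrait) return(em_reml_mt(spec, data, init, kernel_inverse,
                                         tol = tol, max_iter = max_iter,
                                         verbose = verbose))
  keep <- stats::complete.cases(data[unique(c(spec$response, spec$edmi_col))])
  data <- data[keep, , drop = FALSE]
  sys0 <- assemble_mme(spec, data, init, kernel_inverse)
  W <- sys0$W
  y <- sys0$y
  per <- sys0$period
  blocks <- sys0$blocks
  n <- length(y)
  m <- ncol(W)
  periods <- sort(unique(per))
  n_p <- vapply(periods, function(p) sum(per == p), integer(1))
  # per-period cross-product structure (constant across iterations)
  S_p <- lapply(periods, function(p)
    Matrix::forceSymmetric(Matrix::crossprod(W[per == p, , drop = FALSE])))
  Wy_p <- lapply(periods, function(p)
    as.vector(Matrix::crossprod(W[per == p, , drop = FALSE], y[per == p])))
  yy_p <- vapply(periods, function(p) sum(y[per == p]^2), numeric(1))
  S_idx <- lapply(S_p, function(S) {
    tri <- Matrix::mat2triplet(as(S, "generalMatrix"))
    list(i = tri$i, j = tri$j, x = tri$x)
  })
  rblocks <- blocks[vapply(blocks, function(b) b$kind != "fixed", logical(1))]
  has_kernel <- any(vapply(rblocks, function(b) b$kind != "iid", logical(1)))
  Kinv <- kernel_inverse
  ktri <- NULL
  logdet_K <- 0
  if (has_kernel) {
    tri <- Matrix::mat2triplet(as(Kinv, "generalMatrix"))
    ktri <- list(i = tri$i, j = tri$j, x = tri$x)
    f <- Matrix::Cholesky(Matrix::forceSymmetric(Kinv), LDL = FALSE, perm = TRUE)
    logdet_K <- -2 * Matrix::determinant(f, sqrt = TRUE)$modulus  # log|A|
  }

  # unit-value precision patterns, padded to the full equation order,
  # so each round's coefficient matrix is a cheap linear combination
  # with a constant sparsity pattern (one symbolic analysis, reused)
  prec_pad <- lapply(rblocks, function(b) {
    if (b$kind == "iid") {
      Matrix::sparseMatrix(i = b$idx, j = b$idx, x = rep(1, length(b$idx)),
                           dims = c(m, m))
    } else {
      off <- b$idx[1] - 1L
      Matrix::sparseMatrix(i = ktri$i + off, j = ktri$j + off, x = ktri$x,
                           dims = c(m, m))
    }
  })
  build_C <- function(comp, res) {
    C <- Reduce(`+`, Map(function(S, s2) S / s2, S_p, as.list(res)))
    for (b in rblocks)
      C <- C + prec_pad[[b$name]] / comp[[b$name]]
    Matrix::forceSymmetric(C)
  }

  comp <- vapply(rblocks, function(b) init$components[[b$name]], numeric(1))
  names(comp) <- names(rblocks)
  res <- init$residual[periods]
  phen0 <- stats::var(y)
  floor_v <- 1e-10 * phen0
  hist <- data.frame()
  prev <- c(comp, res)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    fac <- .ldl_factor(build_C(comp, res))
    rhs <- Reduce(`+`, Map(function(v, s2) v / s2, Wy_p, as.list(res)))
    sol <- as.vector(Matrix::solve(fac, rhs))
    sel <- .selected_inverse(fac)

    # -2 restricted log-likelihood (constants in n dropped)
    logdet_G <- sum(vapply(rblocks, function(b)
      length(b$idx) * log(comp[[b$name]]), numeric(1))) + logdet_K
    logdet_R <- sum(n_p * log(res))
    yPy <- sum(yy_p / res) - sum(sol * rhs)
    m2ll <- as.numeric(sel$logdet + logdet_G + logdet_R + yPy)

    new_comp <- comp
    for (b in rblocks) {
      s <- sol[b$idx]
      if (b$kind == "iid") {
        tr <- sum(.cinv_entries(sel, b$idx, b$idx))
        new_comp[[b$name]] <- (sum(s^2) + tr) / length(b$idx)
      } else {
        quad <- as.numeric(s %*% (Kinv %*% s))
        off <- b$idx[1] - 1L
        tr <- sum(ktri$x * .cinv_entries(sel, ktri$i + off, ktri$j + off))
        new_comp[[b$name]] <- (quad + tr) / length(b$idx)
      }
    }
    new_res <- res
    for (k in seq_along(periods)) {
      rows <- per == periods[k]
      e <- y[rows] - as.vector(W[rows, , drop = FALSE] %*% sol)
      tr <- sum(S_idx[[k]]$x * .cinv_entries(sel, S_idx[[k]]$i, S_idx[[k]]$j))
      new_res[k] <- (sum(e^2) + tr) / n_p[k]
    }
    new_comp <- pmax(new_comp, floor_v)
    new_res <- pmax(new_res, floor_v)
    cur <- c(new_comp, new_res)
    delta <- max(abs(cur - prev) / pmax(abs(prev), 1e-12))
    hist <- rbind(hist, data.frame(iter = it, t(new_comp),
                                   res_wavg = sum(n_p * new_res) / n,
                                   minus2logL = m2ll, delta = delta))
    if (verbose) message(sprintf("it %3d  -2logL %.4f  delta %.3g", it, m2ll, delta))
    comp <- new_comp
    res <- new_res
    prev <- cur
    if (delta < tol) { converged <- TRUE; break }
  }
  residual5 <- rep(mean(res), 5)
  residual5[periods] <- res
  out <- if (all(c("htm", "pe", "animal") %in% names(comp))) {
    fe_varcomp(htm = comp[["htm"]], pe = comp[["pe"]],
               animal = comp[["animal"]], residual = residual5,
               slope_scale = !is.null(spec$edmi_col))
  } else {
    structure(list(type = "univariate", components = comp,
                   residual = residual5,
                   slope_scale = !is.null(spec$edmi_col)),
              class = "fe_varcomp")
  }
  n_period5 <- integer(5)
  n_period5[periods] <- n_p
  attr(out, "n_period") <- n_period5
  attr(out, "trace") <- hist
  attr(out, "converged") <- converged
  attr(out, "iterations") <- nrow(hist)
  if (!converged)
    warning("EM-REML reached max_iter = ", max_iter,
            " without meeting tol = ", tol)
  out
}

# Multi-trait EM-REML (reduced synthetic scale only): matrix-valued
# updates of M, P, Va and the per-period residual matrices.
em_reml_mt <- function(spec, data, init, kernel_inverse, tol = 1e-6,
                       max_iter = 200, verbose = FALSE, max_equations = 12000) {
  sys0 <- assemble_mme(spec, data, init, kernel_inverse)
  nt <- sys0$n_traits
  m <- ncol(sys0$W)
  if (m * nt > max_equations)
    stop("multi-trait EM-REML is supported at reduced scale only (",
         m * nt, " equations > ", max_equations, ")")
  W <- sys0$W
  Y <- sys0$y
  per <- sys0$period
  blocks <- sys0$blocks
  periods <- sort(unique(per))
  n_p <- vapply(periods, function(p) sum(per == p), integer(1))
  rblocks <- blocks[vapply(blocks, function(b) b$kind != "fixed", logical(1))]
  Kinv <- kernel_inverse
  ktri <- { tri <- Matrix::mat2triplet(as(Kinv, "generalMatrix")); tri }
  vc <- init
  prev <- unlist(c(vc$M, vc$P, vc$Va, vc$Rp))
  converged <- FALSE
  hist <- data.frame()
  eqs <- function(idx) as.vector(vapply(idx, function(j) as.integer((j - 1L) * nt) + seq_len(nt),
                                        integer(nt)))
  for (it in seq_len(max_iter)) {
    sys <- assemble_mme(spec, data, vc, kernel_inverse)
    fac <- Matrix::Cholesky(sys$C, LDL = FALSE, perm = TRUE)
    sol <- as.vector(Matrix::solve(fac, sys$rhs))
    Cinv <- as.matrix(Matrix::solve(fac, Matrix::Diagonal(length(sys$rhs))))
    Smat <- matrix(sol, ncol = nt, byrow = TRUE)
    mats <- list(htm = "M", pe = "P", animal = "Va")
    for (b in rblocks) {
      idx <- b$idx
      Shat <- Smat[idx, , drop = FALSE]
      if (b$kind == "iid") {
        quad <- crossprod(Shat)
        tr <- matrix(0, nt, nt)
        for (j in idx) {
          e <- (j - 1L) * nt + seq_len(nt)
          tr <- tr + Cinv[e, e]
        }
        upd <- (quad + tr) / length(idx)
      } else {
        off <- idx[1] - 1L
        quad <- as.matrix(crossprod(Shat, as.matrix(Kinv %*% Shat)))
        tr <- matrix(0, nt, nt)
        for (z in seq_along(ktri$x)) {
          ei <- (ktri$i[z] + off - 1L) * nt + seq_len(nt)
          ej <- (ktri$j[z] + off - 1L) * nt + seq_len(nt)
          tr <- tr + ktri$x[z] * Cinv[ei, ej]
        }
        upd <- (quad + tr) / length(idx)
      }
      upd <- (upd + t(upd)) / 2
      vc[[mats[[b$name]]]] <- upd
    }
    for (k in seq_along(periods)) {
      rows <- which(per == periods[k])
      Wp <- W[rows, , drop = FALSE]
      E <- Y[rows, , drop = FALSE] - as.matrix(Wp %*% Smat)
      Sp <- as(Matrix::crossprod(Wp), "generalMatrix")
      tri <- Matrix::mat2triplet(Sp)
      tr <- matrix(0, nt, nt)
      for (z in seq_along(tri$x)) {
        ei <- (tri$i[z] - 1L) * nt + seq_len(nt)
        ej <- (tri$j[z] - 1L) * nt + seq_len(nt)
        tr <- tr + tri$x[z] * Cinv[ei, ej]
      }
      upd <- (crossprod(E) + tr) / n_p[k]
      vc$Rp[[periods[k]]] <- (upd + t(upd)) / 2
    }
    cur <- unlist(c(vc$M, vc$P, vc$Va, vc$Rp))
    delta <- max(abs(cur - prev) / pmax(abs(prev), 1e-8))
    hist <- rbind(hist, data.frame(iter = it, delta = delta))
    if (verbose) message(sprintf("mt it %3d delta %.3g", it, delta))
    prev <- cur
    if (delta < tol) { converged <- TRUE; break }
  }
  attr(vc, "trace") <- hist
  attr(vc, "converged") <- converged
  vc
}

#' Heritability and repeatability from variance components
#'
#' `h2 = VarG / (VarPE + VarG + VarR)` and `r = (VarPE + VarG) / (VarPE +
#' VarG + VarR)`, with `VarR` the record-count-weighted average of the
#' period residual variances. For regression-on-expected-intake models
#' (`slope_scale = TRUE`) the genetic and permanent-environment
#' components are first rescaled to the intake scale by the squared mean
#' eDMI, matching the mixed-scale convention in which the residuals are
#' already on the intake scale. The herd-trial-month variance is treated
#' as a contemporary-group component and excluded from the phenotypic
#' denominator.
#'
#' @param vc an [fe_varcomp()].
#' @param mean_edmi data mean of the eDMI covariate (required when
#'   `vc$slope_scale`).
#' @param n_period record counts per period class for the weighted
#'   residual (defaults to the counts recorded by [em_reml()], else equal
#'   weights).
#' @return List with `h2`, `repeatability`, `var_g`, `var_pe`, `var_r`
#'   (all on the reporting scale) and `scale`.
#' @export
heritability <- function(vc, mean_edmi = NULL, n_period = NULL) {
  stopifnot(vc$type == "univariate")
  if (is.null(n_period)) n_period <- attr(vc, "n_period")
  if (is.null(n_period) || !sum(n_period)) n_period <- rep(1, 5)
  var_r <- sum(n_period * vc$residual) / sum(n_period)
  var_g <- vc$components[["animal"]]
  var_pe <- vc$components[["pe"]]
  scale <- "raw"
  if (isTRUE(vc$slope_scale)) {
    if (is.null(mean_edmi))
      stop("mean_edmi is required to put slope-scale components on the intake scale")
    var_g <- var_g * mean_edmi^2
    var_pe <- var_pe * mean_edmi^2
    scale <- "mean-eDMI-scaled"
  }
  total <- var_pe + var_g + var_r
  if (total <= 0) stop("total variance is not positive")
  list(h2 = var_g / total, repeatability = (var_pe + var_g) / total,
       var_g = var_g, var_pe = var_pe, var_r = var_r, scale = scale)
}

#' Scalar variance components of a linear index of the multi-trait model
#'
#' For index weights `w` applied to multi-trait breeding values, the
#' index components are the quadratic forms `w' Va w`, `w' P w` and
#' `w' R_p w`.
#'
#' @param weights numeric length-5 vector in trait order
#'   (DMI, ECM, MBW, BWL, BWG).
#' @param vc an [fe_varcomp_mt()].
#' @return An [fe_varcomp()] on the index scale.
#' @export
index_variances <- function(weights, vc) {
  stopifnot(vc$type == "multitrait")
  if (length(weights) != length(vc$traits))
    stop("weights must have one entry per trait (", length(vc$traits), ")")
  w <- as.numeric(weights)
  qf <- function(S) as.numeric(w %*% S %*% w)
  fe_varcomp(htm = qf(vc$M), pe = qf(vc$P), animal = qf(vc$Va),
             residual = vapply(vc$Rp, qf, numeric(1)))
}

#' Delta-method standard error of a function of variance components
#'
#' First-order delta method: `SE = sqrt(g' Sigma g)` with the gradient
#' `g` obtained by central finite differences.
#'
#' @param fun scalar function of the parameter vector.
#' @param theta parameter estimates.
#' @param Sigma covariance matrix of the estimates (e.g. from a bootstrap
#'   over simulated replicates).
#' @param rel_step relative finite-difference step.
#' @return Standard error (scalar).
#' @export
delta_method_se <- function(fun, theta, Sigma, rel_step = 1e-5) {
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == length(theta), ncol(Sigma) == length(theta))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("estimate covariance matrix is not positive semi-definite")
  g <- vapply(seq_along(theta), function(k) {
    h <- rel_step * max(abs(theta[k]), 1e-8)
    tp <- tm <- theta
    tp[k] <- tp[k] + h
    tm[k] <- tm[k] - h
    (fun(tp) - fun(tm)) / (2 * h)
  }, numeric(1))
  sqrt(max(0, as.numeric(g %*% Sigma %*% g)))
}

#' Delta-method standard errors of heritability and repeatability
#'
#' Convenience wrapper around [delta_method_se()] for the
#' `(pe, animal, residual)` parameterization of [heritability()].
#'
#' @param vc an [fe_varcomp()].
#' @param Sigma covariance of `(var_pe, var_g, var_r_weighted)` on the
#'   same (reporting) scale.
#' @param mean_edmi,n_period passed to [heritability()].
#' @return List with `se_h2` and `se_r`.
#' @export
h2_se <- function(vc, Sigma, mean_edmi = NULL, n_period = NULL) {
  hh <- heritability(vc, mean_edmi = mean_edmi, n_period = n_period)
  th <- c(hh$var_pe, hh$var_g, hh$var_r)
  list(
    se_h2 = delta_method_se(function(t) t[2] / sum(t), th, Sigma),
    se_r = delta_method_se(function(t) (t[1] + t[2]) / sum(t), th, Sigma)
  )
}
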