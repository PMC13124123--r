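oneway_spec <- function() {
  structure(list(metric = "oneway", response = "y", multitrait = FALSE,
                 edmi_col = NULL,
                 fixed = list(list(type = "class", col = "mu", name = "mu")),
                 random = list(list(name = "grp", col = "grp",
                                    covariate = NULL, kernel = "iid"))),
            class = "fe_modelspec")
}

test_that("EM-REML matches closed-form ANOVA REML on a balanced one-way design", {
  set.seed(2)
  q <- 30; nper <- 8
  grp <- rep(sprintf("g%02d", seq_len(q)), each = nper)
  y <- rep(rnorm(q, 0, sqrt(2)), each = nper) +
    rnorm(q * nper, 0, sqrt(3)) + 10
  d <- data.frame(y = y, grp = grp, mu = "m", period = 1L)
  init <- list(components = list(grp = 1), residual = rep(1, 5))
  v <- em_reml(oneway_spec(), d, init, tol = 1e-9, max_iter = 3000)
  gm <- tapply(y, grp, mean)
  msa <- nper * var(gm)
  mse <- sum((y - gm[grp])^2) / (q * (nper - 1))
  expect_lt(abs(v$components[["grp"]] - (msa - mse) / nper), 1e-6)
  expect_lt(abs(v$residual[1] - mse), 1e-6)
})

test_that("the restricted likelihood is monotone and null variance hits the floor", {
  cfg <- small_config(seed = 5, dmi_structure = "rfi",
                      efficiency = list(alpha_sd = 0.3, htm = 0.1, pe = 1.1,
                                        animal = 1e-12,
                                        residual = rep(2.4, 5)))
  st <- simulate_study(cfg)
  d <- derive_metrics(st$records)
  init <- fe_varcomp(htm = 0.5, pe = 1, animal = 1, residual = rep(2, 5))
  v <- suppressWarnings(
    em_reml(build_spec("rfi"), d, init, a_inverse(st$pedigree),
            tol = 1e-5, max_iter = 150))
  tr <- attr(v, "trace")
  expect_true(all(diff(tr$minus2logL) < 1e-9))
  # the spurious additive variance decays monotonically toward the boundary
  expect_true(all(diff(tr$animal) < 0))
  expect_lt(v$components[["animal"]], 0.05 * var(d$dmi))
})

test_that("heritability and repeatability reproduce the repeatability-model table", {
  np <- rep(1, 5)
  rfi <- fe_varcomp(htm = 0.1, pe = 1.127, animal = 1.043,
                    residual = rep(2.369, 5))
  h <- heritability(rfi, n_period = np)
  expect_equal(round(h$h2, 2), 0.23)
  expect_equal(round(h$repeatability, 2), 0.48)
  refi <- fe_varcomp(htm = 0.001, pe = 0.00333, animal = 0.00303,
                     residual = rep(2.502, 5), slope_scale = TRUE)
  h2 <- heritability(refi, mean_edmi = 20.0, n_period = np)
  expect_equal(round(h2$h2, 2), 0.24)
  expect_equal(round(h2$repeatability, 2), 0.50)
  expect_equal(round(h2$var_g, 2), 1.21)    # 0.00303 * 20^2
  nrc <- fe_varcomp(htm = 0.001, pe = 0.00244, animal = 0.00334,
                    residual = rep(2.348, 5), slope_scale = TRUE)
  h3 <- heritability(nrc, mean_edmi = 20.8, n_period = np)
  expect_equal(round(h3$h2, 2), 0.30)
  expect_equal(round(h3$repeatability, 2), 0.52)
  expect_equal(round(h3$var_g, 2), 1.45)    # 0.00334 * 20.8^2
  ecev <- fe_varcomp(htm = 1e-6, pe = 0.000118, animal = 0.000081,
                     residual = rep(0.000157, 5))
  h4 <- heritability(ecev, n_period = np)
  expect_equal(round(h4$h2, 2), 0.23)
  expect_equal(round(h4$repeatability, 2), 0.56)
  # vanishing permanent environment: repeatability collapses to h2
  h5 <- heritability(fe_varcomp(1e-6, 1e-12, 1, rep(1, 5)), n_period = np)
  expect_equal(h5$h2, h5$repeatability, tolerance = 1e-6)
  expect_error(heritability(refi), "mean_edmi")
})

test_that("index variances are the quadratic forms of the index weights", {
  vc <- default_multitrait_vc()
  w_dmi <- c(1, 0, 0, 0, 0)
  iv <- index_variances(w_dmi, vc)
  expect_equal(iv$components[["animal"]], vc$Va["DMI", "DMI"])
  expect_equal(iv$components[["pe"]], vc$P["DMI", "DMI"])
  # identity genetic covariance: sum of squared weights
  vi <- fe_varcomp_mt(M = diag(5), P = diag(5), Va = diag(5), Rp = diag(5))
  w <- c(1, -0.456, 0.0508, -3.25, 3.25)
  expect_equal(index_variances(w, vi)$components[["animal"]],
               sum(w^2))
  expect_lt(abs(index_variances(w, vi)$components[["animal"]] - 22.335), 0.01)
  expect_true(all(unlist(index_variances(rnorm(5), vc)$components) >= 0))
  expect_error(index_variances(1:3, vc), "one entry per trait")
})

test_that("delta-method standard errors match the symbolic gradient", {
  # h2 = a / (a + e): grad = (e, -a) / (a + e)^2
  a <- 1.2; e <- 3.4; va <- 0.09; ve <- 0.16; cae <- 0.02
  Sigma <- matrix(c(va, cae, cae, ve), 2)
  se <- delta_method_se(function(t) t[1] / (t[1] + t[2]), c(a, e), Sigma)
  g <- c(e, -a) / (a + e)^2
  expect_equal(se, sqrt(drop(g %*% Sigma %*% g)), tolerance = 1e-6)
  expect_equal(delta_method_se(function(t) t[1] / sum(t), c(a, e),
                               matrix(0, 2, 2)), 0)
  expect_error(delta_method_se(function(t) t[1], c(1, 1),
                               matrix(c(1, 2, 2, 1), 2)), "definite")
  hs <- h2_se(fe_varcomp(0.1, 1.127, 1.043, rep(2.369, 5)),
              Sigma = diag(c(0.04, 0.04, 0.01)), n_period = rep(1, 5))
  expect_gt(hs$se_h2, 0)
  expect_gt(hs$se_r, 0)
})

test_that("multi-trait EM-REML runs at reduced scale and stays symmetric PSD", {
  st <- small_study()
  d <- st$derived[st$derived$cow %in% unique(st$derived$cow)[1:40], ]
  ped <- prune_pedigree(st$pedigree, unique(d$cow), max_generations = 2)
  vc0 <- default_multitrait_vc()
  v <- em_reml(build_spec("multitrait"), d, vc0, a_inverse(ped),
               tol = 1e-2, max_iter = 4)
  for (S in list(v$M, v$P, v$Va, v$Rp[[1]])) {
    expect_true(isSymmetric(unname(S), tol = 1e-8))
    expect_gt(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  big <- simulate_study(sim_config(seed = 1))
  expect_error(em_reml(build_spec("multitrait"), derive_metrics(big$records),
                       vc0, a_inverse(big$pedigree), max_iter = 1),
               "reduced scale")
})
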