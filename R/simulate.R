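#' Configuration for the synthetic feed-intake study generator
#'
#' The defaults emulate the recording scheme of a Nordic nucleus research
#' herd: roughly 791 primiparous cows with 28 weekly records each across
#' 4 herds and about 24 production years, a multi-generation pedigree,
#' and a genotyped subset of around a quarter of the pedigree.
#'
#' The DMI-generating structure is selectable: `"refi"` builds DMI as
#' expected DMI times a multiplicative efficiency factor (the structural
#' assumption of the regression-on-expected-intake models), `"rfi"`
#' builds DMI as expected DMI plus additive contemporary-group,
#' permanent-environment, genetic and residual effects (the one-step RFI
#' structure). Efficiency variance components default to the
#' repeatability-model scale of each structure.
#'
#' @param n_founders number of founder animals (half female).
#' @param n_generations number of descendant generations.
#' @param offspring_per_mating offspring per dam and generation.
#' @param n_cows number of cows with weekly records (youngest females).
#' @param weeks_per_cow weekly records per cow (max 44, i.e. 305 DIM).
#' @param n_snps,maf_range,genotyped_fraction genotype simulation
#'   settings (founder allele frequencies uniform on `maf_range`).
#' @param n_herds,n_years,base_year herd and calendar structure.
#' @param energy_density diet ME content, MJ per kg DM (default 10.94).
#' @param dmi_structure `"refi"` or `"rfi"` (see Details).
#' @param efficiency list of efficiency variance components:
#'   `alpha_sd` (spread of the fixed herd-production-year level), `htm`,
#'   `pe`, `animal`, `residual` (length 5, per lactation period class).
#' @param sink_means trait means (DMI, ECM, MBW, BWL, BWG, BCS).
#' @param sink_covariances latent energy-sink covariance components: 4x4
#'   matrices (`Va`, `P`, `M`, `R`) over (ECM, MBW, dBW, BCS), where dBW
#'   is the latent daily body-weight change later sign-split into
#'   BWL/BWG. These are package defaults, not literature estimates.
#' @param genetic_architecture `"genomic"` (default) builds true breeding
#'   values from additive marker effects on the gene-dropped genotypes,
#'   so genomic relationships carry real information about Mendelian
#'   sampling; `"pedigree"` draws breeding values from the pedigree
#'   multivariate normal instead (genotypes then say nothing about
#'   within-family deviations).
#' @param pasture_gaps drop a late-summer block of weeks for
#'   late-calving cows (off by default).
#' @param inbreeding_adjusted use inbreeding-adjusted Mendelian-sampling
#'   variance when simulating breeding values.
#' @param seed integer master seed; fans out to per-stage child seeds.
#' @return A list of class `fe_simconfig`.
#' @export
sim_config <- function(n_founders = 140, n_generations = 5,
                       offspring_per_mating = 3, n_cows = 791,
                       weeks_per_cow = 28, n_snps = 2000,
                       maf_range = c(0.05, 0.5), genotyped_fraction = 0.27,
                       n_herds = 4, n_years = 24, base_year = 1994,
                       energy_density = 10.94,
                       dmi_structure = c("refi", "rfi"),
                       efficiency = NULL,
                       sink_means = c(DMI = 19.4, ECM = 29.0, MBW = 119.7,
                                      BWL = 0.35, BWG = 0.35, BCS = 3.17),
                       sink_covariances = NULL,
                       genetic_architecture = c("genomic", "pedigree"),
                       pasture_gaps = FALSE, inbreeding_adjusted = FALSE,
                       seed = 1) {
  dmi_structure <- match.arg(dmi_structure)
  genetic_architecture <- match.arg(genetic_architecture)
  stopifnot(n_founders >= 2, n_generations >= 1, offspring_per_mating >= 1,
            weeks_per_cow >= 1, weeks_per_cow <= 44,
            length(maf_range) == 2, all(maf_range > 0), all(maf_range <= 0.5),
            genotyped_fraction > 0, genotyped_fraction <= 1)
  if (is.null(efficiency)) {
    efficiency <- if (dmi_structure == "refi") {
      # regression-coefficient scale; weighted 28-week residual ~ 2.49
      list(alpha_sd = 0.04, htm = 0.001, pe = 0.00333, animal = 0.00303,
           residual = c(3.3, 2.75, 2.45, 2.2, 2.1))
    } else {
      # intake scale; weighted 28-week residual ~ 2.37
      list(alpha_sd = 0.5, htm = 0.1, pe = 1.127, animal = 1.043,
           residual = c(3.14, 2.62, 2.33, 2.09, 2.00))
    }
  }
  stopifnot(length(efficiency$residual) == 5)
  if (is.null(sink_covariances)) sink_covariances <- default_sink_covariances()
  for (S in sink_covariances) {
    stopifnot(isSymmetric(unname(as.matrix(S)), tol = 1e-8))
    if (min(eigen(as.matrix(S), symmetric = TRUE,
                  only.values = TRUE)$values) < -1e-8)
      stop("sink covariance matrices must be positive semi-definite")
  }
  structure(list(
    n_founders = n_founders, n_generations = n_generations,
    offspring_per_mating = offspring_per_mating, n_cows = n_cows,
    weeks_per_cow = weeks_per_cow, n_snps = n_snps, maf_range = maf_range,
    genotyped_fraction = genotyped_fraction, n_herds = n_herds,
    n_years = n_years, base_year = base_year,
    energy_density = energy_density, dmi_structure = dmi_structure,
    efficiency = efficiency, sink_means = sink_means,
    sink_covariances = sink_covariances,
    genetic_architecture = genetic_architecture,
    pasture_gaps = pasture_gaps,
    inbreeding_adjusted = inbreeding_adjusted, seed = seed
  ), class = "fe_simconfig")
}

#' Default latent energy-sink covariance components
#'
#' 4x4 matrices over the latent traits (ECM, MBW, dBW, BCS) for the
#' additive-genetic (`Va`), permanent-environment (`P`),
#' herd-trial-month (`M`) and residual (`R`) components. Marginal
#' variances are set so the phenotypic totals approximate typical
#' first-parity records (ECM SD about 4.5 kg, MBW SD about 9 kg^0.75,
#' daily BW-change SD about 0.3 kg, BCS SD about 0.33); correlations are
#' moderate package choices, not literature estimates.
#'
#' @return Named list of matrices `Va`, `P`, `M`, `R`.
#' @export
default_sink_covariances <- function() {
  traits <- c("ECM", "MBW", "dBW", "BCS")
  cor_t <- matrix(c(
    1, 0.25, -0.25, -0.20,
    0.25, 1, 0.05, 0.35,
    -0.25, 0.05, 1, 0.30,
    -0.20, 0.35, 0.30, 1), 4, 4, dimnames = list(traits, traits))
  build <- function(vars, shrink) {
    R <- cor_t * shrink
    diag(R) <- 1
    S <- diag(sqrt(vars)) %*% R %*% diag(sqrt(vars))
    dimnames(S) <- list(traits, traits)
    S
  }
  list(Va = build(c(7, 40, 0.015, 0.035), 1),
       P = build(c(4, 24, 0.010, 0.030), 0.8),
       M = build(c(1, 2, 0.005, 0.004), 0),
       R = build(c(8, 13, 0.055, 0.040), 0.4))
}

#' Default variance components for fitting the six evaluation models
#'
#' Univariate components follow the repeatability-model estimates the
#' generator emulates (regression-coefficient scale for the two ReFI
#' models, intake scale for RFI, ECE scale for ECE); the multi-trait 5x5
#' matrices are package defaults built from plausible marginal variances
#' and moderate correlations — no published values exist for them.
#'
#' @return Named list with entries `refi_rdc`, `refi_nrc2021`, `rfi`,
#'   `ece` ([fe_varcomp()]) and `multitrait` ([fe_varcomp_mt()]).
#' @export
default_varcomp <- function() {
  pat <- c(3.3, 2.75, 2.45, 2.2, 2.1)
  list(
    refi_rdc = fe_varcomp(htm = 0.001, pe = 0.00333, animal = 0.00303,
                          residual = pat, slope_scale = TRUE),
    refi_nrc2021 = fe_varcomp(htm = 0.001, pe = 0.00244, animal = 0.00334,
                              residual = pat * (2.348 / 2.502),
                              slope_scale = TRUE),
    rfi = fe_varcomp(htm = 0.1, pe = 1.127, animal = 1.043,
                     residual = c(3.14, 2.62, 2.33, 2.09, 2.00)),
    ece = fe_varcomp(htm = 0.00001, pe = 0.000118, animal = 0.000081,
                     residual = rep(0.000157, 5)),
    multitrait = default_multitrait_vc()
  )
}

#' Default multi-trait variance matrices for (DMI, ECM, MBW, BWL, BWG)
#'
#' Package defaults for fitting the five-trait energy-sink model:
#' marginal phenotypic variances matching typical first-parity records,
#' split 30% genetic, 22% permanent environment, 5% herd-trial-month and
#' 43% residual, with moderate correlations. Not literature estimates.
#'
#' @return An [fe_varcomp_mt()] object.
#' @export
default_multitrait_vc <- function() {
  traits <- c("DMI", "ECM", "MBW", "BWL", "BWG")
  phen <- c(DMI = 9.3, ECM = 19.9, MBW = 79.4, BWL = 0.09, BWG = 0.05)
  cor_t <- matrix(c(
    1, 0.60, 0.35, -0.05, 0.25,
    0.60, 1, 0.20, 0.15, -0.10,
    0.35, 0.20, 1, 0.05, 0.10,
    -0.05, 0.15, 0.05, 1, -0.35,
    0.25, -0.10, 0.10, -0.35, 1), 5, 5, dimnames = list(traits, traits))
  build <- function(frac, shrink) {
    R <- cor_t * shrink
    diag(R) <- 1
    S <- diag(sqrt(frac * phen)) %*% R %*% diag(sqrt(frac * phen))
    dimnames(S) <- list(traits, traits)
    S
  }
  fe_varcomp_mt(M = build(0.05, 0), P = build(0.22, 0.7),
                Va = build(0.30, 1), Rp = build(0.43, 0.4), traits = traits)
}

.child_seeds <- function(seed, n) {
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a multi-generation pedigree
#'
#' Founders (half female) start the population; in each generation every
#' female of the previous generation produces `offspring_per_mating`
#' offspring by a sire sampled from a limited pool of recent males,
#' giving the strong paternal-half-sib structure of a nucleus breeding
#' scheme. Birth years increase with generation across the configured
#' calendar span.
#'
#' @param config an [sim_config()].
#' @return An [fe_pedigree()] with a `sex` column and attribute
#'   `generation`.
#' @export
simulate_pedigree <- function(config) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(.child_seeds(config$seed, 1))
  step <- max(2, round(config$n_years / config$n_generations))
  nf <- config$n_founders
  id <- sprintf("A%05d", seq_len(nf))
  sex <- rep(c("F", "M"), length.out = nf)
  gen <- rep(0L, nf)
  sire <- dam <- rep(NA_character_, nf)
  birth <- config$base_year + sample(0:(step - 1), nf, replace = TRUE)
  next_id <- nf + 1L
  for (g in seq_len(config$n_generations)) {
    dams <- id[sex == "F" & gen == g - 1L]
    sire_pool <- id[sex == "M" & gen >= g - 2L & gen <= g - 1L]
    if (!length(sire_pool)) sire_pool <- id[sex == "M"]
    n_active <- max(3L, ceiling(length(sire_pool) * 0.2))
    active <- sample(sire_pool, min(n_active, length(sire_pool)))
    for (dm in dams) {
      sr <- sample(active, 1)
      for (k in seq_len(config$offspring_per_mating)) {
        id <- c(id, sprintf("A%05d", next_id))
        next_id <- next_id + 1L
        sex <- c(sex, sample(c("F", "M"), 1))
        gen <- c(gen, g)
        sire <- c(sire, sr)
        dam <- c(dam, dm)
        birth <- c(birth, config$base_year + g * step +
                     sample(0:(step - 1), 1))
      }
    }
  }
  origin <- ifelse(gen == 0L, "import", "nucleus")
  ped <- fe_pedigree(id, sire, dam, birth, origin = origin, sex = sex)
  attr(ped, "generation") <- gen[match(ped$id, id)]
  ped
}

#' Drop genes through a pedigree
#'
#' Founder haplotypes are sampled in Hardy-Weinberg proportions at
#' per-locus allele frequencies drawn uniformly from `maf_range`;
#' descendants inherit one allele per locus from each parent (loci
#' unlinked). Alleles of unknown parents are drawn from the founder
#' frequencies.
#'
#' @param ped an [fe_pedigree()].
#' @param config an [sim_config()] (uses `n_snps`, `maf_range`, `seed`).
#' @param ids animals whose genotypes to return (default all).
#' @return Allele-count (0/1/2) matrix with animal ids as rownames and
#'   attribute `freq` (founder allele frequencies).
#' @export
gene_drop <- function(ped, config, ids = NULL) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(.child_seeds(config$seed, 2)[2])
  n <- nrow(ped)
  ns <- config$n_snps
  p <- stats::runif(ns, config$maf_range[1], config$maf_range[2])
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  H1 <- H2 <- matrix(0L, n, ns)
  draw_pop <- function() as.integer(stats::runif(ns) < p)
  inherit <- function(j) {
    pick <- stats::runif(ns) < 0.5
    ifelse(pick, H1[j, ], H2[j, ])
  }
  for (i in seq_len(n)) {
    H1[i, ] <- if (is.na(si[i])) draw_pop() else inherit(si[i])
    H2[i, ] <- if (is.na(di[i])) draw_pop() else inherit(di[i])
  }
  M <- H1 + H2
  rownames(M) <- ped$id
  colnames(M) <- sprintf("snp%04d", seq_len(ns))
  if (!is.null(ids)) {
    miss <- setdiff(as.character(ids), ped$id)
    if (length(miss)) stop("animals not in pedigree: ",
                           paste(miss, collapse = ", "))
    M <- M[as.character(ids), , drop = FALSE]
  }
  attr(M, "freq") <- p
  M
}

#' Simulate multi-trait breeding values over a pedigree
#'
#' Founders are drawn from `MVN(0, Va)`; each non-founder is the parent
#' average plus a Mendelian-sampling deviation with covariance `Va/2`
#' (both parents known; `3 Va/4` with one, `Va` with none). With
#' `inbreeding_adjusted`, the Mendelian-sampling variance is reduced by
#' the parents' inbreeding.
#'
#' @param ped an [fe_pedigree()].
#' @param Va trait covariance matrix (any dimension; PSD).
#' @param seed RNG seed.
#' @param inbreeding_adjusted logical.
#' @return Matrix animals x traits with ids as rownames.
#' @export
simulate_breeding_values <- function(ped, Va, seed = 1,
                                     inbreeding_adjusted = FALSE) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  Va <- as.matrix(Va)
  k <- nrow(Va)
  ev <- eigen(Va, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("genetic covariance matrix is not positive semi-definite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  f <- if (inbreeding_adjusted) inbreeding(ped) else numeric(n)
  U <- matrix(0, n, k)
  for (i in seq_len(n)) {
    pa <- numeric(k)
    scale <- 1
    if (!is.na(si[i]) && !is.na(di[i])) {
      pa <- 0.5 * (U[si[i], ] + U[di[i], ])
      scale <- 0.5 - 0.25 * (f[si[i]] + f[di[i]])
    } else if (!is.na(si[i])) {
      pa <- 0.5 * U[si[i], ]
      scale <- 0.75 - 0.25 * f[si[i]]
    } else if (!is.na(di[i])) {
      pa <- 0.5 * U[di[i], ]
      scale <- 0.75 - 0.25 * f[di[i]]
    }
    U[i, ] <- pa + sqrt(scale) * as.vector(L %*% stats::rnorm(k))
  }
  rownames(U) <- ped$id
  colnames(U) <- colnames(Va)
  U
}

#' Breeding values from additive marker effects
#'
#' Draws per-locus effect vectors from `MVN(0, Va / (2 sum p q))` at the
#' founder allele frequencies and sums them over centered allele counts,
#' so the founder-generation genetic covariance approximates `Va` and
#' descendants' values carry genotype-linked Mendelian sampling.
#'
#' @param geno allele-count matrix for every animal (from [gene_drop()]
#'   with founder frequencies in `attr(, "freq")`).
#' @param Va trait covariance matrix (any dimension; PSD).
#' @param seed RNG seed.
#' @return Matrix animals x traits.
#' @export
marker_breeding_values <- function(geno, Va, seed = 1) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  Va <- as.matrix(Va)
  k <- nrow(Va)
  p <- attr(geno, "freq")
  if (is.null(p)) p <- colMeans(geno) / 2
  denom <- 2 * sum(p * (1 - p))
  ev <- eigen(Va / denom, symmetric = TRUE)
  if (min(ev$values) < -1e-12 * max(abs(ev$values), 1))
    stop("genetic covariance matrix is not positive semi-definite")
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  a <- matrix(stats::rnorm(ncol(geno) * k), ncol(geno)) %*% t(L)
  Z <- sweep(geno, 2, 2 * p, "-")
  U <- Z %*% a
  rownames(U) <- rownames(geno)
  colnames(U) <- colnames(Va)
  U
}

# lactation-stage mean curves, centred where the trait mean carries the level
.ecm_curve <- function(w) {
  c0 <- 2.2 * exp(-((w - 6)^2) / 180) - 0.08 * w
  c0 - mean(c0)
}
.mbw_curve <- function(w) 0.22 * (w - mean(w))
.dbw_curve <- function(w) 0.45 - 1.1 * exp(-0.18 * w)
.bcs_curve <- function(w) {
  c0 <- -0.25 * exp(-((w - 8)^2) / 120)
  c0 - mean(c0)
}

#' Simulate weekly lactation records
#'
#' Generates, for every record cow, `weeks_per_cow` weekly records with
#' herd-production-year, herd-trial-month, permanent-environment,
#' additive-genetic and period-specific residual structure. Energy sinks
#' follow lactation-stage mean curves plus the latent-trait covariance
#' components; BWL/BWG are the sign split of the latent body-weight
#' change. DMI is built from the Nordic Red expected-intake formula under
#' the configured structure (multiplicative efficiency for `"refi"`,
#' additive for `"rfi"`), and MEI is DMI times the diet energy density.
#'
#' @param ped an [fe_pedigree()] with a `sex` column.
#' @param bv_sinks latent sink breeding values from
#'   [simulate_breeding_values()] (columns ECM, MBW, dBW, BCS).
#' @param bv_eff named numeric vector of efficiency breeding values
#'   (slope scale for `"refi"`, kg DMI for `"rfi"`).
#' @param config an [sim_config()].
#' @return List with `records` (data frame) and `cows` (cow-level
#'   assignment table).
#' @export
simulate_records <- function(ped, bv_sinks, bv_eff, config) {
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(.child_seeds(config$seed, 3)[3])
  eff <- config$efficiency
  # record cows: youngest non-founder females
  cand <- ped[!is.na(ped$sire) & !is.na(ped$dam) & ped$sex == "F", ]
  cand <- cand[order(-cand$birth_year, cand$id), ]
  if (nrow(cand) < config$n_cows)
    warning("only ", nrow(cand), " candidate cows available (requested ",
            config$n_cows, ")")
  cows <- utils::head(cand$id, config$n_cows)
  nc <- length(cows)
  herd <- sample(seq_len(config$n_herds), nc, replace = TRUE,
                 prob = c(0.35, 0.3, 0.2, 0.15)[seq_len(config$n_herds)] /
                   sum(c(0.35, 0.3, 0.2, 0.15)[seq_len(config$n_herds)]))
  by <- ped$birth_year[match(cows, ped$id)]
  py <- pmin(pmax(by + 2L, config$base_year + 4L),
             config$base_year + config$n_years + 3L)
  m0 <- sample(1:9, nc, replace = TRUE)  # calving month (pre-pasture)
  cow_tab <- data.frame(cow = cows, herd = herd, birth_year = by,
                        production_year = py, calving_month = m0,
                        stringsAsFactors = FALSE)

  w <- seq_len(config$weeks_per_cow)
  nW <- length(w)
  rec <- data.frame(
    cow = rep(cows, each = nW), herd = rep(herd, each = nW),
    week = rep(w, nc), production_year = rep(py, each = nW)
  )
  rec$DIM <- (rec$week - 1) * 7 + 4
  month <- ((rep(m0, each = nW) - 1 + rec$DIM %/% 30) %% 12) + 1
  rec$hpy <- paste0("h", rec$herd, ":y", rec$production_year)
  # trial = consecutive 3-year blocks within herd; test months pooled in
  # pairs, keeping the contemporary-group count near the real design
  trial <- (rec$production_year - config$base_year) %/% 3
  rec$htm <- paste0("h", rec$herd, ":t", trial, ":m", (month + 1) %/% 2)
  n <- nrow(rec)

  # latent sink components
  sc <- config$sink_covariances
  msqrt <- function(S) {
    ev <- eigen(as.matrix(S), symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S))
  }
  Lp <- msqrt(sc$P); Lm <- msqrt(sc$M); Lr <- msqrt(sc$R)
  pe_sink <- matrix(stats::rnorm(nc * 4), nc) %*% t(Lp)
  rownames(pe_sink) <- cows
  htm_lev <- sort(unique(rec$htm))
  htm_sink <- matrix(stats::rnorm(length(htm_lev) * 4), length(htm_lev)) %*% t(Lm)
  rownames(htm_sink) <- htm_lev
  res_sink <- matrix(stats::rnorm(n * 4), n) %*% t(Lr)
  ci <- match(rec$cow, cows)
  hi <- match(rec$htm, htm_lev)
  g_sink <- bv_sinks[match(rec$cow, rownames(bv_sinks)), , drop = FALSE]
  sink <- g_sink + pe_sink[ci, ] + htm_sink[hi, ] + res_sink
  mu <- config$sink_means
  ECM <- pmax(mu[["ECM"]] + .ecm_curve(rec$week) + sink[, "ECM"], 1)
  MBW <- pmax(mu[["MBW"]] + .mbw_curve(rec$week) + sink[, "MBW"], 60)
  dBW <- .dbw_curve(rec$week) + sink[, "dBW"]
  BCS <- pmin(pmax(mu[["BCS"]] + .bcs_curve(rec$week) + sink[, "BCS"], 1), 5)
  sp <- split_bw_change(dBW)
  edmi <- edmi_rdc(ECM, MBW, sp$BWL, sp$BWG)
  per <- period_class(rec$week)

  # efficiency effects
  hpy_lev <- sort(unique(rec$hpy))
  alpha <- stats::rnorm(length(hpy_lev), 0, eff$alpha_sd)
  names(alpha) <- hpy_lev
  beta <- stats::rnorm(length(htm_lev), 0, sqrt(eff$htm))
  names(beta) <- htm_lev
  gamma <- stats::rnorm(nc, 0, sqrt(eff$pe))
  names(gamma) <- cows
  delta <- bv_eff[match(rec$cow, names(bv_eff))]
  e <- stats::rnorm(n, 0, sqrt(eff$residual)[per])
  if (config$dmi_structure == "refi") {
    slope <- 1 + alpha[rec$hpy] + beta[rec$htm] + gamma[rec$cow] + delta
    dmi <- edmi * slope + e
  } else {
    dmi <- edmi + alpha[rec$hpy] + beta[rec$htm] + gamma[rec$cow] + delta + e
  }
  dmi <- pmax(dmi, 1)

  # milk composition consistent with the generated ECM
  fat <- pmax(stats::rnorm(n, 44.3, 3.5), 20)
  protein <- pmax(stats::rnorm(n, 36.3, 2.2), 20)
  lactose <- pmax(stats::rnorm(n, 45.0, 1.3), 35)
  milk <- ECM * 3140 / (38.30 * fat + 24.20 * protein + 16.54 * lactose + 20.7)

  rec$milk <- milk
  rec$fat <- fat
  rec$protein <- protein
  rec$lactose <- lactose
  rec$bw <- MBW^(4 / 3)
  rec$delta_bw <- dBW
  rec$bcs <- BCS
  rec$dmi <- dmi
  rec$mei <- dmi * config$energy_density
  if (config$pasture_gaps) {
    # late-calving cows lose the weeks that fall in July-September
    late <- rep(m0, each = nW) >= 7
    gap <- late & month %in% 7:9
    rec <- rec[!gap, , drop = FALSE]
  }
  list(records = rec, cows = cow_tab)
}

#' Simulate a complete synthetic feed-intake study
#'
#' Runs the full generator: pedigree, latent sink and efficiency breeding
#' values, weekly records, gene-dropped genotypes for a genotyped subset
#' (all late-born record cows plus parents of record cows, filled to the
#' configured fraction).
#'
#' @param config an [sim_config()].
#' @return A list of class `fe_study` with `pedigree`, `genotypes`,
#'   `records`, `cows`, `true_breeding_values` (per-animal efficiency and
#'   latent sink values), `genotyped_ids` and `config`.
#' @export
simulate_study <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  seeds <- .child_seeds(config$seed, 6)
  va_eff <- config$efficiency$animal
  if (config$genetic_architecture == "genomic") {
    geno_all <- gene_drop(ped, config)
    bv_sinks <- marker_breeding_values(geno_all, config$sink_covariances$Va,
                                       seed = seeds[4])
    bv_eff <- as.vector(marker_breeding_values(geno_all,
                                               matrix(va_eff, 1, 1),
                                               seed = seeds[5]))
  } else {
    geno_all <- NULL
    bv_sinks <- simulate_breeding_values(ped, config$sink_covariances$Va,
                                         seed = seeds[4],
                                         inbreeding_adjusted = config$inbreeding_adjusted)
    bv_eff <- as.vector(simulate_breeding_values(ped, matrix(va_eff, 1, 1),
                                                 seed = seeds[5],
                                                 inbreeding_adjusted = config$inbreeding_adjusted))
  }
  names(bv_eff) <- ped$id
  sim <- simulate_records(ped, bv_sinks, bv_eff, config)

  # genotyped subset: youngest record cows first, then their parents
  old <- .Random.seed_safe(); on.exit(.restore_seed(old), add = TRUE)
  set.seed(seeds[6])
  target <- max(2, round(config$genotyped_fraction * nrow(ped)))
  rc <- sim$cows$cow[order(-sim$cows$birth_year)]
  parents <- unique(stats::na.omit(c(ped$sire[match(rc, ped$id)],
                                     ped$dam[match(rc, ped$id)])))
  pool <- unique(c(rc, parents, sample(ped$id)))
  gids <- utils::head(pool, target)
  geno <- if (is.null(geno_all)) gene_drop(ped, config, ids = gids) else {
    out <- geno_all[gids, , drop = FALSE]
    attr(out, "freq") <- attr(geno_all, "freq")
    out
  }

  tb <- data.frame(id = ped$id,
                   eff = bv_eff[ped$id],
                   as.data.frame(bv_sinks[ped$id, , drop = FALSE]),
                   row.names = NULL)
  mean_edmi_target <- mean(edmi_rdc(config$sink_means[["ECM"]],
                                    config$sink_means[["MBW"]],
                                    config$sink_means[["BWL"]],
                                    config$sink_means[["BWG"]]))
  tb$eff_dmi <- if (config$dmi_structure == "refi")
    tb$eff * mean_edmi_target else tb$eff
  structure(list(pedigree = ped, genotypes = geno, records = sim$records,
                 cows = sim$cows, true_breeding_values = tb,
                 genotyped_ids = rownames(geno), config = config),
            class = "fe_study")
}
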