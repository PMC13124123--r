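#' Forward split of a record table for LR validation
#'
#' Defines the validation group as the genotyped animals with records
#' born at or after `cutoff_birth_year`, excluding any whose daughters
#' keep records in the reduced data, and removes the group's records and
#' their daughters' records from the reduced dataset.
#'
#' @param data weekly record table with a `cow` column.
#' @param ped an [fe_pedigree()].
#' @param cutoff_birth_year first birth year of validation candidates.
#' @param genotyped_ids ids of genotyped animals.
#' @return List with `full`, `reduced` (record tables) and `group`
#'   (a list with `ids`, `cutoff`, `n_excluded`).
#' @export
split_forward <- function(data, ped, cutoff_birth_year, genotyped_ids) {
  genotyped_ids <- as.character(genotyped_ids)
  by <- ped$birth_year[match(as.character(data$cow), ped$id)]
  rec_ids <- unique(as.character(data$cow))
  cand <- intersect(genotyped_ids,
                    ped$id[ped$birth_year >= cutoff_birth_year])
  cand <- intersect(cand, rec_ids)
  if (!length(cand))
    stop("empty validation group: no genotyped animals with records born >= ",
         cutoff_birth_year)
  # daughters of candidates that would keep records in the reduced data
  reduced <- data[by < cutoff_birth_year, , drop = FALSE]
  red_ids <- unique(as.character(reduced$cow))
  has_young_daughter <- vapply(cand, function(a) {
    dtrs <- ped$id[!is.na(ped$dam) & ped$dam == a]
    any(dtrs %in% red_ids)
  }, logical(1))
  group <- cand[!has_young_daughter]
  if (!length(group)) stop("empty validation group after daughter exclusion")
  # reduced data: drop records of group members and of their daughters
  dtrs <- ped$id[!is.na(ped$dam) & ped$dam %in% group]
  reduced <- reduced[!(as.character(reduced$cow) %in% c(group, dtrs)), ,
                     drop = FALSE]
  list(full = data, reduced = reduced,
       group = list(ids = group, cutoff = cutoff_birth_year,
                    n_excluded = sum(has_young_daughter)))
}

#' Linear-regression (LR) forward validation
#'
#' Ordinary least squares of whole-data breeding values on partial-data
#' breeding values over the validation group:
#' `EBV_full = b0 + b1 EBV_reduced`. `b0` estimates bias, `b1`
#' dispersion, and the Pearson correlation is the prediction accuracy.
#'
#' @param ebv_full,ebv_reduced data frames with `id` and `ebv` columns.
#' @param group validation group (list from [split_forward()] or a
#'   character vector of ids).
#' @param var_g optional additive-genetic variance on the EBV scale, used
#'   to express the bias in genetic standard deviations.
#' @param n_boot bootstrap replicates for standard errors (0 = none).
#' @param seed bootstrap seed.
#' @return List of class `fe_lr` with `b0`, `b1`, `corr`, `n_validation`,
#'   standard errors and `bias_in_genetic_sd` (when `var_g` given).
#' @export
lr_validation <- function(ebv_full, ebv_reduced, group, var_g = NULL,
                          n_boot = 0, seed = 1) {
  ids <- if (is.list(group)) group$ids else as.character(group)
  xf <- ebv_full$ebv[match(ids, ebv_full$id)]
  xr <- ebv_reduced$ebv[match(ids, ebv_reduced$id)]
  if (anyNA(xf) || anyNA(xr))
    stop("breeding-value tables do not cover the validation group")
  if (length(ids) < 3) stop("validation group has fewer than 3 animals")
  if (stats::var(xr) <= 0) stop("reduced-data EBVs have zero variance")
  b1 <- stats::cov(xf, xr) / stats::var(xr)
  b0 <- mean(xf) - b1 * mean(xr)
  corr <- stats::cor(xf, xr)
  out <- list(b0 = b0, b1 = b1, corr = corr, n_validation = length(ids))
  if (!is.null(var_g)) out$bias_in_genetic_sd <- abs(b0) / sqrt(var_g)
  if (n_boot > 0) {
    pairs <- data.frame(x = xr, y = xf)
    out$se_b0 <- bootstrap_se(pairs, "b0", n_boot = n_boot, seed = seed)
    out$se_b1 <- bootstrap_se(pairs, "b1", n_boot = n_boot, seed = seed + 1)
    out$se_corr <- bootstrap_se(pairs, "corr", n_boot = n_boot, seed = seed + 2)
  }
  class(out) <- "fe_lr"
  out
}

#' Nonparametric bootstrap standard error over animal pairs
#'
#' Resamples the rows of a two-column table with replacement and returns
#' the standard deviation of the statistic across resamples. Degenerate
#' resamples (zero variance in either column) are skipped and counted.
#'
#' @param pairs data frame with columns `x` and `y`.
#' @param statistic one of `"b0"`, `"b1"`, `"corr"` (Pearson),
#'   `"pearson"`, `"spearman"`.
#' @param n_boot number of bootstrap replicates (>= 100 recommended).
#' @param seed RNG seed (resampling is deterministic given the seed).
#' @return Standard error, with attribute `n_skipped`.
#' @export
bootstrap_se <- function(pairs, statistic = c("b1", "b0", "corr", "pearson",
                                              "spearman"),
                         n_boot = 1000, seed = 1) {
  statistic <- match.arg(statistic)
  stat_fun <- switch(statistic,
    b1 = function(x, y) stats::cov(y, x) / stats::var(x),
    b0 = function(x, y) mean(y) - stats::cov(y, x) / stats::var(x) * mean(x),
    corr = ,
    pearson = function(x, y) stats::cor(x, y),
    spearman = function(x, y) stats::cor(x, y, method = "spearman")
  )
  n <- nrow(pairs)
  old <- .Random.seed_safe()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(seed)
  vals <- numeric(0)
  skipped <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    x <- pairs$x[idx]; y <- pairs$y[idx]
    if (stats::var(x) <= 0 || stats::var(y) <= 0) { skipped <- skipped + 1; next }
    vals <- c(vals, stat_fun(x, y))
  }
  se <- stats::sd(vals)
  attr(se, "n_skipped") <- skipped
  se
}

.Random.seed_safe <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Adjusted energy-conversion-efficiency phenotypes
#'
#' Removes every estimated effect of the ECE model except the additive
#' genetic one from each record (leaving `u + e`), then averages per cow
#' — an ECE yield deviation.
#'
#' @param fit an `fe_fit` from the `"ece"` model.
#' @param data the record table the model was fitted to is taken from the
#'   fit itself; `data` is accepted for interface symmetry and ignored
#'   when `NULL`.
#' @return Data frame with `id` and `adjusted` (mean adjusted phenotype).
#' @export
adjusted_ece <- function(fit, data = NULL) {
  sys <- fit$sys
  b <- sys$blocks$animal
  u_part <- as.vector(sys$W[, b$idx, drop = FALSE] %*% fit$sol[b$idx])
  adj <- fit$residuals + u_part
  cow <- fit$cow_ids
  if (is.null(cow)) stop("fit carries no record-to-cow mapping")
  agg <- tapply(adj, cow, mean)
  data.frame(id = names(agg), adjusted = as.numeric(agg), row.names = NULL)
}

#' Cross-metric correlations of breeding values
#'
#' Pairwise Pearson (upper triangle) and Spearman (lower triangle)
#' correlations of per-animal breeding values across metrics, over a
#' common animal set (typically the phenotyped cows), with optional
#' bootstrap standard errors; optionally also the correlations of each
#' metric's values with adjusted ECE phenotypes.
#'
#' @param tables named list of data frames with `id` and `ebv`.
#' @param ids animal set over which to correlate (default: intersection).
#' @param adjusted optional data frame from [adjusted_ece()].
#' @param n_boot bootstrap replicates for SEs (0 = none).
#' @param seed bootstrap seed.
#' @return List with `pearson`, `spearman` matrices (and SE matrices when
#'   `n_boot > 0`), and `adjusted` (data frame) when supplied.
#' @export
metric_correlations <- function(tables, ids = NULL, adjusted = NULL,
                                n_boot = 0, seed = 1) {
  stopifnot(length(tables) >= 2, !is.null(names(tables)))
  if (is.null(ids))
    ids <- Reduce(intersect, lapply(tables, function(t) as.character(t$id)))
  if (!length(ids)) stop("metric breeding-value tables share no animals")
  M <- vapply(tables, function(t) t$ebv[match(ids, t$id)],
              numeric(length(ids)))
  if (anyNA(M)) stop("mismatched animal sets across metric tables")
  k <- ncol(M)
  pe <- stats::cor(M)
  sp <- stats::cor(M, method = "spearman")
  out <- list(pearson = pe, spearman = sp, ids = ids)
  if (n_boot > 0) {
    pse <- sse <- matrix(NA_real_, k, k, dimnames = dimnames(pe))
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      pr <- data.frame(x = M[, i], y = M[, j])
      pse[i, j] <- pse[j, i] <-
        bootstrap_se(pr, "pearson", n_boot = n_boot, seed = seed)
      sse[i, j] <- sse[j, i] <-
        bootstrap_se(pr, "spearman", n_boot = n_boot, seed = seed)
    }
    out$pearson_se <- pse
    out$spearman_se <- sse
  }
  if (!is.null(adjusted)) {
    av <- adjusted$adjusted[match(ids, adjusted$id)]
    out$adjusted <- data.frame(
      metric = colnames(M),
      pearson = apply(M, 2, stats::cor, y = av, use = "complete.obs"),
      spearman = apply(M, 2, stats::cor, y = av, method = "spearman",
                       use = "complete.obs"),
      row.names = NULL)
  }
  out
}

#' Run the full metric-comparison workflow on a simulated study
#'
#' For each requested metric and kernel: fits the model on the full and
#' the forward-reduced data, extracts breeding values (combining
#' multi-trait values into the RFI index and RZFE), runs LR validation,
#' and computes cross-metric GEBV correlations and adjusted-ECE
#' correlations over the phenotyped cows.
#'
#' @param study an [simulate_study()] result (or a list with `records`,
#'   `pedigree`, `genotypes`, `genotyped_ids`).
#' @param vc named list of variance components: entries `refi_rdc`,
#'   `refi_nrc2021`, `rfi`, `ece` ([fe_varcomp()]) and `multitrait`
#'   ([fe_varcomp_mt()]); defaults to the generator's values via
#'   [default_varcomp()].
#' @param metrics metrics to evaluate.
#' @param kernels `"pedigree"`, `"ssgblup"` or both.
#' @param cutoff_birth_year forward-validation cutoff (default: so that
#'   roughly the youngest tenth of genotyped cows validate).
#' @param n_boot bootstrap replicates for SEs (0 = none, the default).
#' @return List of class `fe_comparison` with `lr` (one row per metric x
#'   kernel), `correlations` (per kernel), `ebv` tables and the split.
#' @export
run_comparison <- function(study, vc = NULL,
                           metrics = c("refi_rdc", "refi_nrc2021",
                                       "rfi_index", "rzfe", "rfi", "ece"),
                           kernels = c("pedigree", "ssgblup"),
                           cutoff_birth_year = NULL, n_boot = 0) {
  data <- derive_metrics(study$records)
  ped <- study$pedigree
  if (is.null(vc)) vc <- default_varcomp()
  geno <- study$genotypes
  if (is.null(cutoff_birth_year)) {
    gcows <- intersect(rownames(geno), unique(as.character(data$cow)))
    yrs <- sort(ped$birth_year[match(gcows, ped$id)])
    cutoff_birth_year <- yrs[ceiling(0.9 * length(yrs))]
  }
  sp <- split_forward(data, ped, cutoff_birth_year, rownames(geno))

  ainv <- a_inverse(ped)
  kinvs <- list()
  if ("pedigree" %in% kernels) kinvs$pedigree <- ainv
  if ("ssgblup" %in% kernels) {
    A22 <- a_submatrix(ped, rownames(geno))
    G <- blend_G(vanraden_G(geno), A22)
    kinvs$ssgblup <- h_inverse(ainv, G, A22)
  }

  needs_mt <- any(c("rfi_index", "rzfe") %in% metrics)
  direct <- setdiff(metrics, c("rfi_index", "rzfe"))
  lr_rows <- list()
  ebv_tabs <- list()
  cors <- list()
  for (kn in names(kinvs)) {
    tabs_full <- tabs_red <- list()
    ece_fit_full <- NULL
    if (needs_mt) {
      mf <- fit_metric("multitrait", sp$full, ped, vc$multitrait, kinv = kinvs[[kn]])
      mr <- fit_metric("multitrait", sp$reduced, ped, vc$multitrait, kinv = kinvs[[kn]])
      bf <- ebv(mf); br <- ebv(mr)
      if ("rfi_index" %in% metrics) {
        tabs_full$rfi_index <- rfi_index(bf); tabs_red$rfi_index <- rfi_index(br)
      }
      if ("rzfe" %in% metrics) {
        tabs_full$rzfe <- rzfe(bf); tabs_red$rzfe <- rzfe(br)
      }
    }
    vg_map <- list()
    if (needs_mt && !is.null(vc$multitrait)) {
      vg_map$rfi_index <- index_variances(c(1, -0.456, 0.0508, -3.25, 3.25),
                                          vc$multitrait)$components[["animal"]]
      vg_map$rzfe <- index_variances(c(-1, 0.4, 0, -4.5, 4.5),
                                     vc$multitrait)$components[["animal"]]
    }
    for (mt in direct) {
      ff <- fit_metric(mt, sp$full, ped, vc[[mt]], kinv = kinvs[[kn]])
      fr <- fit_metric(mt, sp$reduced, ped, vc[[mt]], kinv = kinvs[[kn]])
      tabs_full[[mt]] <- ebv(ff)
      tabs_red[[mt]] <- ebv(fr)
      vg_map[[mt]] <- vc[[mt]]$components[["animal"]] *
        if (isTRUE(vc[[mt]]$slope_scale)) ff$mean_edmi^2 else 1
      if (mt == "ece") ece_fit_full <- ff
    }
    for (mt in metrics) {
      vg <- vg_map[[mt]]
      lr <- lr_validation(tabs_full[[mt]], tabs_red[[mt]], sp$group,
                          var_g = vg, n_boot = n_boot)
      lr_rows[[paste(mt, kn)]] <- data.frame(
        metric = mt, kernel = kn, b0 = lr$b0, b1 = lr$b1, corr = lr$corr,
        n_validation = lr$n_validation,
        bias_in_genetic_sd = if (is.null(lr$bias_in_genetic_sd)) NA else lr$bias_in_genetic_sd,
        se_b0 = if (is.null(lr$se_b0)) NA else as.numeric(lr$se_b0),
        se_b1 = if (is.null(lr$se_b1)) NA else as.numeric(lr$se_b1),
        se_corr = if (is.null(lr$se_corr)) NA else as.numeric(lr$se_corr))
    }
    phen <- unique(as.character(data$cow))
    adj <- if (!is.null(ece_fit_full)) adjusted_ece(ece_fit_full) else NULL
    cors[[kn]] <- metric_correlations(tabs_full, ids = phen, adjusted = adj,
                                      n_boot = n_boot)
    ebv_tabs[[kn]] <- tabs_full
  }
  out <- list(lr = do.call(rbind, c(lr_rows, list(make.row.names = FALSE))),
              correlations = cors, ebv = ebv_tabs, split = sp,
              cutoff_birth_year = cutoff_birth_year)
  class(out) <- "fe_comparison"
  out
}
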