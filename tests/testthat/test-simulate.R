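test_that("simulation is reproducible from the master seed", {
  cfg1 <- small_config(seed = 11)
  st1 <- simulate_study(cfg1)
  st2 <- simulate_study(small_config(seed = 11))
  expect_identical(st1$pedigree, st2$pedigree)
  expect_identical(st1$records, st2$records)
  expect_identical(st1$genotypes, st2$genotypes)
  st3 <- simulate_study(small_config(seed = 12))
  expect_false(identical(st1$pedigree$sire, st3$pedigree$sire))
  expect_false(identical(st1$records$dmi, st3$records$dmi))
})

test_that("simulated pedigrees are closed, acyclic and generation-ordered", {
  cfg <- sim_config(n_founders = 10, n_generations = 3,
                    offspring_per_mating = 2, seed = 2)
  ped <- simulate_pedigree(cfg)
  known <- !is.na(ped$sire)
  expect_true(all(ped$sire[known] %in% ped$id))
  expect_true(all(ped$dam[!is.na(ped$dam)] %in% ped$id))
  # each non-founder's parents are born earlier
  bi <- ped$birth_year
  si <- match(ped$sire, ped$id)
  expect_true(all(bi[si[known]] < bi[known]))
  expect_error(sim_config(n_founders = 1), "n_founders")
})

test_that("gene dropping obeys Mendelian inheritance", {
  cfg <- sim_config(n_founders = 40, n_generations = 2,
                    offspring_per_mating = 2, n_snps = 200, seed = 9)
  ped <- simulate_pedigree(cfg)
  M <- gene_drop(ped, cfg)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  kids <- which(!is.na(si) & !is.na(di))
  for (i in kids[1:20]) {
    gs <- M[si[i], ]; gd <- M[di[i], ]; go <- M[i, ]
    both0 <- gs == 0 & gd == 0
    expect_true(all(go[both0] == 0))
    forced_het <- (gs == 2 & gd == 0) | (gs == 0 & gd == 2)
    expect_true(all(go[forced_het] == 1))
    expect_true(all(go >= 0 & go <= 2))
  }
  expect_error(gene_drop(ped, cfg, ids = "ghost"), "not in pedigree")
})

test_that("breeding-value simulation matches its sampling distribution", {
  founders <- fe_pedigree(sprintf("f%04d", 1:5000), rep(NA, 5000),
                          rep(NA, 5000), rep(2000, 5000))
  U <- simulate_breeding_values(founders, matrix(1, 1, 1), seed = 3)
  expect_gt(var(U[, 1]), 0.92)
  expect_lt(var(U[, 1]), 1.08)
  # zero genetic variance: all values exactly zero
  U0 <- simulate_breeding_values(founders[1:50, ], matrix(0, 1, 1), seed = 1)
  expect_true(all(U0 == 0))
  # offspring vs mid-parent correlation ~ sqrt(0.5)
  n <- 2000
  trio_ped <- fe_pedigree(
    id = c(sprintf("s%04d", 1:n), sprintf("d%04d", 1:n), sprintf("o%04d", 1:n)),
    sire = c(rep(NA, 2 * n), sprintf("s%04d", 1:n)),
    dam = c(rep(NA, 2 * n), sprintf("d%04d", 1:n)),
    birth_year = rep(c(1, 1, 2), each = n))
  U <- simulate_breeding_values(trio_ped, matrix(1, 1, 1), seed = 3)
  mid <- (U[sprintf("s%04d", 1:n), 1] + U[sprintf("d%04d", 1:n), 1]) / 2
  off <- U[sprintf("o%04d", 1:n), 1]
  expect_lt(abs(cor(off, mid) - sqrt(0.5)), 0.05)
  expect_error(simulate_breeding_values(founders[1:5, ],
                                        matrix(c(1, 2, 2, 1), 2), seed = 1),
               "definite")
})

test_that("weekly records carry the designed structure", {
  st <- small_study()
  rec <- st$records
  cfg <- st$config
  expect_equal(nrow(rec), nrow(st$cows) * cfg$weeks_per_cow)
  expect_true(all(rec$week >= 1 & rec$week <= 44))
  expect_true(all(rec$cow %in% st$pedigree$id))
  expect_true(all(st$genotyped_ids %in% st$pedigree$id))
  d <- st$derived
  expect_true(all(d$BWL * d$BWG == 0))
  expect_equal(d$mei, d$dmi * cfg$energy_density)
  expect_true(all(table(rec$cow) == cfg$weeks_per_cow))
})

test_that("with no efficiency variation, intake equals expected intake", {
  cfg <- small_config(seed = 21,
                      efficiency = list(alpha_sd = 0, htm = 0, pe = 0,
                                        animal = 0, residual = rep(0, 5)))
  st <- simulate_study(cfg)
  d <- derive_metrics(st$records)
  expect_equal(d$dmi, d$eDMI_RDC, tolerance = 1e-12, ignore_attr = TRUE)
  # per-cow regression of DMI on eDMI has slope one
  sl <- coef(lm(dmi ~ eDMI_RDC, data = d))[2]
  expect_lt(abs(sl - 1), 1e-8)
})

test_that("regressing intake on expected intake has unit slope under pure noise", {
  cfg <- small_config(seed = 22,
                      efficiency = list(alpha_sd = 0, htm = 0, pe = 0,
                                        animal = 0,
                                        residual = rep(2.5, 5)))
  st <- simulate_study(cfg)
  d <- derive_metrics(st$records)
  sl <- coef(lm(dmi ~ 0 + eDMI_RDC, data = d))[1]
  expect_lt(abs(sl - 1), 0.02)
})

test_that("pasture gaps remove late-summer records of late-calving cows only", {
  cfg <- small_config(seed = 23, pasture_gaps = TRUE)
  st <- simulate_study(cfg)
  full <- simulate_study(small_config(seed = 23))
  expect_lt(nrow(st$records), nrow(full$records))
  expect_true(all(table(st$records$cow) <= cfg$weeks_per_cow))
})

test_that("pedigree and record tables round-trip through their text formats", {
  st <- small_study()
  f1 <- tempfile(fileext = ".csv")
  write_pedigree(st$pedigree, f1)
  p2 <- read_pedigree(f1)
  expect_equal(p2$id, st$pedigree$id)
  expect_equal(p2$sire, st$pedigree$sire)
  expect_equal(p2$birth_year, st$pedigree$birth_year)
  f2 <- tempfile(fileext = ".csv")
  write_records(st$records[1:20, ], f2)
  r2 <- read_records(f2)
  expect_equal(r2$dmi, st$records$dmi[1:20], tolerance = 1e-10)
  vcf <- tempfile(fileext = ".yaml")
  write_varcomp(default_varcomp()$rfi, vcf)
  v2 <- read_varcomp(vcf)
  expect_equal(v2$components, default_varcomp()$rfi$components)
  unlink(c(f1, f2, vcf))
})
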