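trio <- function() fe_pedigree(c("s", "d", "x"), c(NA, NA, "s"),
                               c(NA, NA, "d"), c(2000, 2000, 2002))

test_that("pedigree construction orders parents first and rejects cycles", {
  ped <- fe_pedigree(c("x", "s", "d"), c("s", NA, NA), c("d", NA, NA),
                     c(2002, 2000, 2000))
  expect_equal(ped$id, c("d", "s", "x"))
  expect_error(fe_pedigree(c("a", "b"), c("b", "a"), c(NA, NA), c(1, 1)),
               "cycle")
  expect_error(fe_pedigree(c("a", "a"), c(NA, NA), c(NA, NA), c(1, 1)),
               "unique")
  expect_error(fe_pedigree("a", "ghost", NA, 1), "ghost")
})

test_that("pruning respects the generation horizon and is idempotent", {
  ped <- trio()
  p0 <- prune_pedigree(ped, "x", max_generations = 0)
  expect_equal(p0$id, "x")
  expect_true(is.na(p0$sire) && is.na(p0$dam))
  expect_equal(nrow(prune_pedigree(ped, "x", 1)), 3)
  # 4-generation chain: great-grandparent dropped at horizon 2
  chain <- fe_pedigree(c("a", "b", "c", "e"), c(NA, "a", "b", "c"),
                       c(NA, NA, NA, NA), 1:4)
  p2 <- prune_pedigree(chain, "e", 2)
  expect_setequal(p2$id, c("e", "c", "b"))
  expect_true(is.na(p2$sire[p2$id == "b"]))
  expect_identical(prune_pedigree(p2, "e", 2), p2)
  expect_error(prune_pedigree(ped, "nope", 1), "unknown focal")
})

test_that("tabular A reproduces hand-derived relationships and inbreeding", {
  two <- fe_pedigree(c("a", "b"), c(NA, NA), c(NA, NA), c(1, 1))
  expect_equal(unname(tabular_A(two)), diag(2) * 1.0, ignore_attr = TRUE)
  A <- tabular_A(trio())
  expect_equal(A["x", "s"], 0.5)
  expect_equal(A["x", "d"], 0.5)
  expect_equal(A["x", "x"], 1.0)
  # offspring of a sire-daughter mating: F = 0.25
  inbred <- fe_pedigree(c("s", "d", "x", "y"), c(NA, NA, "s", "s"),
                        c(NA, NA, "d", "x"), c(1, 1, 2, 3))
  expect_equal(tabular_A(inbred)["y", "y"], 1.25)
  expect_equal(inbreeding(inbred)[["y"]], 0.25)
})

test_that("sparse A-inverse matches Henderson's trio entries and the dense inverse", {
  founders <- fe_pedigree(c("a", "b", "c"), rep(NA, 3), rep(NA, 3), 1:3)
  expect_equal(as.matrix(a_inverse(founders)), diag(3),
               ignore_attr = TRUE)
  Ai <- as.matrix(a_inverse(trio()))
  expect_equal(Ai["x", "x"], 2)
  expect_equal(Ai["s", "s"], 1.5)
  expect_equal(Ai["s", "d"], 0.5)
  expect_equal(Ai["x", "s"], -1)
  # definitional identity and dense-inverse agreement on generated pedigrees
  for (seed in c(1, 2)) {
    cfg <- sim_config(n_founders = 30, n_generations = 3,
                      offspring_per_mating = 2, seed = seed)
    ped <- simulate_pedigree(cfg)
    A <- tabular_A(ped)
    Ai <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(A %*% Ai - diag(nrow(A)))), 1e-8)
    expect_lt(max(abs(Ai - solve(A))), 1e-6)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("fully outbred pedigrees have unit diagonal", {
  cfg <- sim_config(n_founders = 40, n_generations = 1,
                    offspring_per_mating = 1, seed = 5)
  ped <- simulate_pedigree(cfg)
  f <- inbreeding(ped)
  if (all(f == 0)) expect_equal(unname(diag(tabular_A(ped))),
                                rep(1, nrow(ped)))
  expect_true(all(diag(tabular_A(ped)) >= 1))
})

test_that("unknown-parent groups bin by origin and birth year", {
  ped <- fe_pedigree(sprintf("a%02d", 1:30), rep(NA, 30), rep(NA, 30),
                     birth_year = 1990:2019, origin = "base")
  g1 <- assign_upg(ped, n_groups = 1)
  expect_equal(length(g1$levels), 1)
  g10 <- assign_upg(ped, n_groups = 10)
  expect_equal(length(g10$levels), 10)
  # 3-year bins, boundary year in the earlier bin
  expect_equal(g10$sire_group[ped$birth_year == 1990],
               g10$sire_group[ped$birth_year == 1992])
  expect_false(g10$sire_group[ped$birth_year == 1992] ==
                 g10$sire_group[ped$birth_year == 1993])
  ped2 <- fe_pedigree(sprintf("b%02d", 1:20), rep(NA, 20), rep(NA, 20),
                      birth_year = rep(2000:2009, 2),
                      origin = rep(c("x", "y"), each = 10))
  g <- assign_upg(ped2, n_groups = 6)
  expect_lte(length(g$levels), 6)
  expect_error(assign_upg(ped2, n_groups = 1), "origins")
})

test_that("A-inverse with groups absorbs unknown parents into group equations", {
  ped <- trio()
  grp <- assign_upg(ped, n_groups = 1)
  Ai <- a_inverse(ped, groups = grp)
  expect_equal(nrow(Ai), 4)
  # animal block unchanged for the offspring equation
  expect_equal(as.matrix(Ai)["x", "x"], 2)
  # founder diagonal picks up its own-record contribution plus group terms
  expect_gt(as.matrix(Ai)[grp$levels[1], grp$levels[1]], 0)
})
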