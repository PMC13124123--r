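#' Construct a validated pedigree
#'
#' Builds the canonical pedigree object used throughout the package: a
#' data frame with one row per animal, topologically ordered so that every
#' parent precedes its offspring, and sorted by birth year (ties broken by
#' id). Unknown parents are encoded as `NA`.
#'
#' @param id character or integer vector of unique animal identifiers.
#' @param sire,dam parent identifiers; `NA` or `"0"`/`0` for unknown.
#' @param birth_year integer birth years (used for ordering and for
#'   unknown-parent-group assignment).
#' @param origin categorical origin label (e.g. herd of recruitment);
#'   recycled if length one.
#' @param sex optional `"M"`/`"F"` vector; kept if supplied.
#'
#' @return A `data.frame` of class `"fe_pedigree"` with columns `id`,
#'   `sire`, `dam`, `birth_year`, `origin` (and `sex` if given), ordered
#'   parents-first.
#' @export
fe_pedigree <- function(id, sire, dam, birth_year, origin = "base", sex = NULL) {
  id <- as.character(id)
  sire <- as.character(sire)
  dam <- as.character(dam)
  sire[sire %in% c("0", "", "NA")] <- NA_character_
  dam[dam %in% c("0", "", "NA")] <- NA_character_
  if (anyDuplicated(id)) stop("animal ids must be unique")
  n <- length(id)
  stopifnot(length(sire) == n, length(dam) == n, length(birth_year) == n)
  ped <- data.frame(
    id = id, sire = sire, dam = dam,
    birth_year = as.integer(birth_year),
    origin = rep_len(as.character(origin), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(sex)) ped$sex <- rep_len(as.character(sex), n)
  bad <- setdiff(c(ped$sire, ped$dam), c(NA, ped$id))
  if (length(bad)) stop("parents not in pedigree: ", paste(bad, collapse = ", "))
  ped <- ped_toposort(ped)
  class(ped) <- c("fe_pedigree", "data.frame")
  ped
}

# Kahn-style topological sort (parents first), with birth_year then id as
# the tie-break so the ordering is canonical and reproducible.
ped_toposort <- function(ped) {
  n <- nrow(ped)
  idx <- match(ped$id, ped$id)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  placed <- logical(n)
  out <- integer(0)
  ord <- order(ped$birth_year, ped$id)
  remaining <- ord
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(i) {
      (is.na(si[i]) || placed[si[i]]) && (is.na(di[i]) || placed[di[i]])
    }, logical(1))]
    if (!length(ready)) stop("pedigree contains a cycle (an animal is its own ancestor)")
    placed[ready] <- TRUE
    out <- c(out, ready)
    remaining <- setdiff(remaining, ready)
  }
  ped[out, , drop = FALSE]
}

#' Prune a pedigree to focal animals and a generation horizon
#'
#' Keeps the focal animals plus all ancestors reachable within
#' `max_generations` parent steps. Parents that fall outside the horizon
#' become unknown.
#'
#' @param ped an [fe_pedigree()] object.
#' @param focal_ids animals whose ancestry is to be retained.
#' @param max_generations number of ancestral generations to keep
#'   (0 keeps only the focal animals themselves).
#' @return A pruned `fe_pedigree`.
#' @export
prune_pedigree <- function(ped, focal_ids, max_generations = 5) {
  focal_ids <- as.character(focal_ids)
  missing <- setdiff(focal_ids, ped$id)
  if (length(missing)) stop("unknown focal ids: ", paste(missing, collapse = ", "))
  keep <- unique(focal_ids)
  frontier <- keep
  g <- 0
  while (g < max_generations && length(frontier)) {
    rows <- ped[match(frontier, ped$id), ]
    parents <- setdiff(unique(c(rows$sire, rows$dam)), c(NA, keep))
    keep <- c(keep, parents)
    frontier <- parents
    g <- g + 1
  }
  out <- ped[ped$id %in% keep, , drop = FALSE]
  out$sire[!(out$sire %in% out$id)] <- NA_character_
  out$dam[!(out$dam %in% out$id)] <- NA_character_
  out <- ped_toposort(out)
  class(out) <- c("fe_pedigree", "data.frame")
  out
}

#' Numerator relationship matrix (tabular method)
#'
#' Wright's numerator relationship matrix A by the tabular method;
#' diagonals are `1 + F_i` with `F_i` the inbreeding coefficient.
#'
#' @param ped an [fe_pedigree()] (parents-first order enforced by the
#'   constructor).
#' @return Dense symmetric matrix with animal ids as dimnames and
#'   attribute `kernel = "A"`.
#' @export
tabular_A <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  attr(A, "kernel") <- "A"
  A
}

#' Inbreeding coefficients
#'
#' @param ped an [fe_pedigree()].
#' @return Named numeric vector of inbreeding coefficients `F_i`.
#' @export
inbreeding <- function(ped) {
  f <- diag(tabular_A(ped)) - 1
  names(f) <- ped$id
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules with inbreeding
#' accounted for (Mendelian sampling variances from the parents'
#' inbreeding coefficients). With a `groups` assignment, unknown parents
#' are replaced by genetic-group codes (Quaas-Pollak absorption) and the
#' returned matrix is augmented with one row/column per group.
#'
#' @param ped an [fe_pedigree()].
#' @param groups optional result of [assign_upg()]: a list with
#'   `sire_group` and `dam_group` character vectors (NA where the parent
#'   is known) and `levels`.
#' @return Sparse symmetric `Matrix` (class `dsCMatrix`) indexed by animal
#'   ids, followed by group labels when `groups` is supplied.
#' @export
a_inverse <- function(ped, groups = NULL) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  f <- inbreeding(ped)
  fs <- ifelse(is.na(si), -1, f[si])   # F of unknown parent enters as -1,
  fd <- ifelse(is.na(di), -1, f[di])   # giving d = 1 (both) or 0.75 - F/4 (one)
  d <- 0.5 - 0.25 * (fs + fd)
  labels <- ped$id
  gs <- gd <- rep(NA_integer_, n)
  if (!is.null(groups)) {
    labels <- c(labels, groups$levels)
    gs <- match(groups$sire_group, groups$levels) + n
    gd <- match(groups$dam_group, groups$levels) + n
    si <- ifelse(is.na(si), gs, si)
    di <- ifelse(is.na(di), gd, di)
  }
  m <- length(labels)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  alpha <- 1 / d
  # vectorized Henderson rules
  add(seq_len(n), seq_len(n), alpha)
  hs <- !is.na(si); hd <- !is.na(di)
  add(seq_len(n)[hs], si[hs], -0.5 * alpha[hs])
  add(si[hs], seq_len(n)[hs], -0.5 * alpha[hs])
  add(seq_len(n)[hd], di[hd], -0.5 * alpha[hd])
  add(di[hd], seq_len(n)[hd], -0.5 * alpha[hd])
  add(si[hs], si[hs], 0.25 * alpha[hs])
  add(di[hd], di[hd], 0.25 * alpha[hd])
  b <- hs & hd
  add(si[b], di[b], 0.25 * alpha[b])
  add(di[b], si[b], 0.25 * alpha[b])
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, m),
                            dimnames = list(labels, labels))
  Matrix::forceSymmetric((M + Matrix::t(M)) / 2)
}

#' Assign unknown parents to genetic groups
#'
#' Partitions unknown-parent slots into at most `n_groups` groups by the
#' offspring's origin and equal-width birth-year bins within origin
#' (boundary years fall in the earlier bin).
#'
#' @param ped an [fe_pedigree()].
#' @param n_groups maximum number of groups over all origins.
#' @param year_range optional `c(min, max)` birth-year range for binning;
#'   defaults to the range observed among animals with an unknown parent.
#' @return A list with `sire_group`/`dam_group` (character per animal, NA
#'   where the parent is known) and `levels`.
#' @export
assign_upg <- function(ped, n_groups = 10, year_range = NULL) {
  origins <- sort(unique(ped$origin))
  if (n_groups < length(origins))
    stop("n_groups (", n_groups, ") is smaller than the number of origins (",
         length(origins), ")")
  unk <- is.na(ped$sire) | is.na(ped$dam)
  if (is.null(year_range)) year_range <- range(ped$birth_year[unk])
  bins_per_origin <- max(1L, n_groups %/% length(origins))
  width <- max(1, (diff(year_range) + 1) / bins_per_origin)
  bin_of <- function(y) {
    b <- ceiling((y - year_range[1] + 1) / width)   # boundary -> earlier bin
    pmin(pmax(b, 1L), bins_per_origin)
  }
  lab <- function(unknown) {
    out <- rep(NA_character_, nrow(ped))
    out[unknown] <- sprintf("UPG_%s_%d", ped$origin[unknown],
                            bin_of(ped$birth_year[unknown]))
    out
  }
  sire_group <- lab(is.na(ped$sire))
  dam_group <- lab(is.na(ped$dam))
  levels <- sort(unique(stats::na.omit(c(sire_group, dam_group))))
  list(sire_group = sire_group, dam_group = dam_group, levels = levels)
}

#' Pedigree relationship submatrix of the genotyped animals
#'
#' @param ped an [fe_pedigree()].
#' @param ids animal ids selecting the submatrix (typically the genotyped
#'   set).
#' @return Dense symmetric matrix `A22` with attribute `kernel = "A22"`.
#' @export
a_submatrix <- function(ped, ids) {
  ids <- as.character(ids)
  A <- tabular_A(ped)
  out <- A[ids, ids, drop = FALSE]
  attr(out, "kernel") <- "A22"
  out
}
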