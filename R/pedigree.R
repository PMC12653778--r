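#' @useDynLib markqg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rpois qnorm pnorm dnorm quantile
#'   median sd var uniroot rchisq cor complete.cases setNames aggregate
#' @importFrom utils head tail write.csv
NULL

UNKNOWN_PARENT <- NA_character_

.as_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

#' Pedigree tables
#'
#' A pedigree table is a `data.frame` with columns `animal`, `sire`, `dam`
#' (character; `NA` = unknown parent) and optionally `birth_year` and `sex`,
#' ordered so that parents always precede their offspring.  All relationship
#' algebra in the package (inbreeding coefficients, the numerator
#' relationship matrix A and its sparse inverse) starts from this object.
#'
#' @param animal,sire,dam character vectors of equal length; unknown parents
#'   may be given as `NA`, `""` or `"0"`.
#' @param birth_year optional integer vector.
#' @param sex optional character vector (`"male"`/`"female"`).
#' @param on_missing_parent what to do when a parent id never appears as an
#'   animal: `"insert"` adds it as a founder, `"error"` aborts.
#' @return A `data.frame` of class `pedigree_table`, topologically ordered
#'   (Kahn's algorithm, input-order tie-breaking).
#' @export
pedigree_table <- function(animal, sire, dam, birth_year = NULL, sex = NULL,
                           on_missing_parent = c("insert", "error")) {
  on_missing_parent <- match.arg(on_missing_parent)
  animal <- as.character(animal)
  sire <- .as_parent(sire)
  dam <- .as_parent(dam)
  if (anyNA(animal) || any(animal == "")) stop("animal ids must be non-missing")
  if (anyDuplicated(animal)) {
    stop("duplicated animal id: ", animal[duplicated(animal)][1L])
  }
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  if (!is.null(birth_year)) ped$birth_year <- as.integer(birth_year)
  if (!is.null(sex)) ped$sex <- as.character(sex)

  parents <- unique(c(ped$sire, ped$dam))
  parents <- parents[!is.na(parents)]
  missing <- setdiff(parents, ped$animal)
  if (length(missing)) {
    if (on_missing_parent == "error") {
      stop("parent referenced but never defined: ", missing[1L])
    }
    add <- ped[rep.int(NA_integer_, length(missing)), , drop = FALSE]
    add$animal <- missing
    add$sire <- NA_character_
    add$dam <- NA_character_
    ped <- rbind(add, ped)
    rownames(ped) <- NULL
  }
  ped <- .order_pedigree(ped)
  class(ped) <- c("pedigree_table", "data.frame")
  ped
}

# Kahn topological sort, stable in input order; errors with an animal on a
# cycle (includes self-ancestry such as A -> C -> A).
.order_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$animal
  si <- idx[ped$sire]
  di <- idx[ped$dam]
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  order_out <- integer(0)
  ready <- which(indeg == 0L)          # ascending input order
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    order_out <- c(order_out, i)
    kids <- children[[i]]
    if (length(kids)) {
      indeg[kids] <- indeg[kids] - 1L
      newly <- kids[indeg[kids] == 0L]
      if (length(newly)) ready <- sort(c(ready, newly))
    }
  }
  if (length(order_out) < n) {
    on_cycle <- ped$animal[setdiff(seq_len(n), order_out)]
    stop("pedigree cycle detected involving animal: ", on_cycle[1L])
  }
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a pedigree file
#'
#' Reads a delimited text file with header `animal,sire,dam[,birth_year][,sex]`
#' (comma or tab autodetected). Unknown parents are encoded as an empty field
#' or `"0"`. Rows are validated and reordered so parents precede offspring.
#'
#' @param path file path.
#' @param on_missing_parent see [pedigree_table()].
#' @return A `pedigree_table`.
#' @export
load_pedigree <- function(path, on_missing_parent = c("insert", "error")) {
  dt <- data.table::fread(path, header = TRUE, colClasses = "character",
                          na.strings = c("", "NA"), data.table = FALSE)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(dt))) {
    stop("pedigree file must have columns animal, sire, dam")
  }
  pedigree_table(dt$animal, dt$sire, dt$dam,
                 birth_year = if ("birth_year" %in% names(dt)) dt$birth_year,
                 sex = if ("sex" %in% names(dt)) dt$sex,
                 on_missing_parent = on_missing_parent)
}

#' Write a pedigree file
#'
#' Emits the same CSV schema read by [load_pedigree()]; unknown parents are
#' written as empty fields.
#'
#' @param ped a `pedigree_table`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  data.table::fwrite(out, path)
  invisible(path)
}

# parent indices (0 = unknown) for an ordered pedigree
.parent_index <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  s <- idx[ped$sire]; s[is.na(s)] <- 0L
  d <- idx[ped$dam]; d[is.na(d)] <- 0L
  list(sire = as.integer(unname(s)), dam = as.integer(unname(d)))
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes the pedigree inbreeding coefficient F for every animal with the
#' Meuwissen & Luo ancestor-tracing algorithm: exact, O(n x pedigree depth),
#' no dense matrix formed.  Founders have F = 0; otherwise
#' F_i = a(sire_i, dam_i) / 2 where a is the additive relationship.
#'
#' @param ped an ordered `pedigree_table`.
#' @return Named numeric vector of F in `[0, 1)`, one per animal, in pedigree
#'   order.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "pedigree_table"))
  p <- .parent_index(ped)
  f <- meuwissen_luo_cpp(p$sire, p$dam)
  names(f) <- ped$animal
  f
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive (numerator) relationship matrix A by the tabular
#' method: for ordered animals, `a_ij = (a_{j,s(i)} + a_{j,d(i)}) / 2` for
#' j < i and `a_ii = 1 + a_{s(i),d(i)} / 2`.  Diagonal entries equal 1 + F.
#' Intended for small to medium pedigrees; refuses to allocate above
#' `max_animals`.
#'
#' @param ped an ordered `pedigree_table`.
#' @param max_animals dense-size guard (default 5000).
#' @return Symmetric numeric matrix with dimnames = animal ids.
#' @export
relationship_matrix <- function(ped, max_animals = 5000L) {
  stopifnot(inherits(ped, "pedigree_table"))
  n <- nrow(ped)
  if (n > max_animals) {
    stop("dense relationship matrix refused for ", n, " animals (limit ",
         max_animals, "); use a_inverse() for large pedigrees")
  }
  p <- .parent_index(ped)
  A <- tabular_a_cpp(p$sire, p$dam)
  dimnames(A) <- list(ped$animal, ped$animal)
  A
}

# Mendelian-sampling variance d_i given parent F and knowledge pattern:
# both parents known  d = 0.5 - 0.25 (F_s + F_d)
# one parent known    d = 0.75 - 0.25 F_known
# no parent known     d = 1
mendelian_variance <- function(sire_idx, dam_idx, f) {
  fs <- ifelse(sire_idx > 0L, f[pmax(sire_idx, 1L)], 0)
  fd <- ifelse(dam_idx > 0L, f[pmax(dam_idx, 1L)], 0)
  known <- (sire_idx > 0L) + (dam_idx > 0L)
  1 - 0.25 * known - 0.25 * (fs + fd)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules with
#' the inbreeding adjustment: each animal i contributes 1/d_i to the
#' (i,i) entry, -1/(2 d_i) to (i, parent) and 1/(4 d_i) to (parent, parent),
#' where d_i is the Mendelian-sampling variance computed from parental
#' inbreeding (unknown parents count as non-inbred unrelated founders).
#' A is never formed.
#'
#' @param ped an ordered `pedigree_table`.
#' @param f optional precomputed inbreeding coefficients (from
#'   [inbreeding_coefficients()]); computed if missing.
#' @return A sparse symmetric `Matrix::dsCMatrix` with dimnames = animal ids.
#' @export
a_inverse <- function(ped, f = NULL) {
  stopifnot(inherits(ped, "pedigree_table"))
  if (is.null(f)) f <- inbreeding_coefficients(ped)
  n <- nrow(ped)
  p <- .parent_index(ped)
  d <- mendelian_variance(p$sire, p$dam, unname(f))
  w <- 1 / d

  ii <- seq_len(n)
  rows <- list(ii); cols <- list(ii); vals <- list(w)
  for (par in list(p$sire, p$dam)) {
    has <- par > 0L
    rows <- c(rows, list(ii[has], par[has], par[has]))
    cols <- c(cols, list(par[has], ii[has], par[has]))
    vals <- c(vals, list(-0.5 * w[has], -0.5 * w[has], 0.25 * w[has]))
  }
  # sire-dam cross terms
  both <- p$sire > 0L & p$dam > 0L
  rows <- c(rows, list(p$sire[both], p$dam[both]))
  cols <- c(cols, list(p$dam[both], p$sire[both]))
  vals <- c(vals, list(0.25 * w[both], 0.25 * w[both]))

  Ai <- Matrix::sparseMatrix(i = unlist(rows), j = unlist(cols),
                             x = unlist(vals), dims = c(n, n),
                             dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ai)
}
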