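#' Pedigree additive relationship matrix (tabular method)
#'
#' Builds the expected additive relationship matrix A by the tabular
#' recursion: `A_ii = 1 + 0.5 A(sire_i, dam_i)` and
#' `A_ij = 0.5 (A(j, sire_i) + A(j, dam_i))` for j processed before i, with
#' unknown parents contributing 0. Parents must be listed before their
#' offspring (rows are sorted by the `generation` column when present,
#' otherwise topologically). Individuals of different populations share no
#' recorded ancestor, so across-population entries are 0 under the
#' base-animal founder convention.
#'
#' @param pedigree data frame with columns `id`, `sire`, `dam` (unknown as
#'   `NA`), optionally `population` and `generation`.
#' @return symmetric matrix A with `id` dimnames.
#' @export
compute_a_matrix <- function(pedigree) {
  ped <- as.data.frame(pedigree)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  if (anyDuplicated(ped$id) > 0) stop("duplicate ids in pedigree", call. = FALSE)
  if ("generation" %in% names(ped)) {
    ped <- ped[order(ped$generation), , drop = FALSE]
  } else {
    # topological sort: repeatedly emit individuals whose parents are placed
    placed <- character(0)
    rest <- ped
    out <- ped[0, ]
    while (nrow(rest) > 0) {
      ready <- (is.na(rest$sire) | rest$sire %in% placed) &
        (is.na(rest$dam) | rest$dam %in% placed)
      # parents outside the pedigree count as unknown
      ready <- ready | ((!rest$sire %in% rest$id | is.na(rest$sire)) &
                          (!rest$dam %in% rest$id | is.na(rest$dam)))
      if (!any(ready)) {
        stop("pedigree contains a cycle (individual its own ancestor)",
             call. = FALSE)
      }
      out <- rbind(out, rest[ready, , drop = FALSE])
      placed <- c(placed, rest$id[ready])
      rest <- rest[!ready, , drop = FALSE]
    }
    ped <- out
  }
  n <- nrow(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  if (any(si >= seq_len(n), na.rm = TRUE) || any(di >= seq_len(n), na.rm = TRUE)) {
    stop("pedigree contains a cycle (individual its own ancestor)",
         call. = FALSE)
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      a <- 0.5 * ((if (!is.na(s)) A[j, s] else 0) +
                    (if (!is.na(d)) A[j, d] else 0))
      A[j, i] <- a
      A[i, j] <- a
    }
    A[i, i] <- 1 + 0.5 * (if (!is.na(s) && !is.na(d)) A[s, d] else 0)
  }
  A
}

#' Number of independent chromosome segments from G and A
#'
#' `M_e = 1 / Var(G_ij - A_ij)`, with the variance taken over a designated
#' pair set: all (reference, candidate) cross pairs (`pairs = "cross"`; used
#' for across-population scenarios, for combined two-population references
#' pooled into one variance, and for the cross-validation pairs of the base
#' scenario), or all unordered distinct pairs within one id set
#' (`pairs = "within"`). The variance uses divisor N (population variance).
#'
#' @param G genomic relationship matrix (or `grm` object) with id dimnames.
#' @param A pedigree relationship matrix with id dimnames; ids absent from
#'   `A` are treated as unrelated (entry 0).
#' @param reference_ids,candidate_ids the pair set; for `pairs = "within"`
#'   only `reference_ids` is used.
#' @param pairs `"cross"` or `"within"`.
#' @return object of class `me_estimate`: `me`, `variance_of_difference`,
#'   `n_pairs`, `pair_set`.
#' @export
estimate_me <- function(G, A, reference_ids, candidate_ids = NULL,
                        pairs = c("cross", "within")) {
  pairs <- match.arg(pairs)
  if (inherits(G, "grm")) G <- G$G
  gid <- rownames(G)
  stopifnot(!is.null(gid), !is.null(rownames(A)))

  lookup <- function(ids1, ids2) {
    # A entries for ids missing from the pedigree are 0 (unrelated base)
    a <- matrix(0, length(ids1), length(ids2))
    i1 <- match(ids1, rownames(A)); i2 <- match(ids2, rownames(A))
    ok1 <- !is.na(i1); ok2 <- !is.na(i2)
    a[ok1, ok2] <- A[i1[ok1], i2[ok2]]
    a
  }

  if (pairs == "cross") {
    if (is.null(candidate_ids)) stop("candidate_ids required for cross pairs",
                                     call. = FALSE)
    if (length(intersect(reference_ids, candidate_ids)) > 0) {
      stop("reference and candidate id sets must be disjoint", call. = FALSE)
    }
    d <- G[reference_ids, candidate_ids, drop = FALSE] -
      lookup(reference_ids, candidate_ids)
    d <- as.numeric(d)
  } else {
    ids <- reference_ids
    d <- G[ids, ids, drop = FALSE] - lookup(ids, ids)
    d <- d[upper.tri(d)]
  }
  if (length(d) < 2L) stop("fewer than 2 pairs", call. = FALSE)
  v <- mean((d - mean(d))^2) # divisor N
  if (v == 0) {
    stop(sprintf("zero variance of G - A over %d pairs: M_e infinite",
                 length(d)), call. = FALSE)
  }
  structure(list(me = 1 / v, variance_of_difference = v,
                 n_pairs = length(d),
                 pair_set = pairs),
            class = "me_estimate")
}

#' @export
print.me_estimate <- function(x, ...) {
  cat(sprintf("M_e = %.1f  (Var(G - A) = %.3g over %d %s pairs)\n",
              x$me, x$variance_of_difference, x$n_pairs, x$pair_set))
  invisible(x)
}
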