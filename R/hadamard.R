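#' Sylvester Hadamard matrix
#'
#' Recursive Sylvester construction: `H_1 = [1]`,
#' `H_{2n} = [[H_n, H_n], [H_n, -H_n]]`. Rows are mutually orthogonal, so
#' `H %*% t(H) == order * I`.
#'
#' @param order matrix order; must be a power of 2.
#' @return `order x order` matrix of +1/-1.
#' @export
hadamard_matrix <- function(order) {
  assert_scalar_num(order, "order", lower = 1)
  order <- as.integer(order)
  if (bitwAnd(order, order - 1L) != 0L)
    stop("`order` must be a power of 2, got ", order)
  H <- matrix(1, 1, 1)
  while (nrow(H) < order) H <- rbind(cbind(H, H), cbind(H, -H))
  H
}

#' Sequency (sign-change count) of Hadamard rows
#'
#' Sequency is the number of sign changes along a row of a +1/-1 matrix, the
#' Walsh analogue of spatial frequency used to rank illumination patterns.
#'
#' @param H matrix of +1/-1 rows.
#' @return integer vector, one count per row.
#' @export
sequency <- function(H) {
  as.integer(rowSums(H[, -1, drop = FALSE] != H[, -ncol(H), drop = FALSE]))
}

#' Build a bank of binary Hadamard illumination patterns
#'
#' Takes the first `k` rows of an `order x order` Sylvester Hadamard matrix
#' (optionally re-ranked by sequency as a spatial-frequency proxy), binarizes
#' each as `(H + 1) / 2` and reshapes it row-major to a `side x side` mask.
#' With `order = side^2` every non-DC binarized pattern has exactly
#' `order / 2` ones, and the DC row gives the all-ones full-field pattern.
#'
#' `source = "hadamard_pos"` models acquisition of the positive binary
#' patterns only; `source = "hadamard_pair"` models complementary-pair
#' acquisition whose differenced measurement carries the signed +1/-1 weights.
#'
#' @param order Hadamard order (power of 2); must equal `side^2`.
#' @param k number of patterns to keep (`k <= order`).
#' @param ranking `"sequency"` (default) or `"natural"` row order.
#' @param side image side length; default `sqrt(order)`.
#' @param source `"hadamard_pos"` or `"hadamard_pair"`.
#' @return object of class `pattern_bank`: `P` (`k x side^2` binary matrix,
#'   one vectorized pattern per row, column-major pixel order), `H_rows`
#'   (the signed rows), `order`, `k`, `side`, `ranking`, `source`, `rows`
#'   (original Hadamard row indices in bank order), `bank_id`.
#' @export
build_hadamard_bank <- function(order = 1024L, k = 512L,
                                ranking = c("sequency", "natural"),
                                side = NULL,
                                source = c("hadamard_pos", "hadamard_pair")) {
  ranking <- match.arg(ranking)
  source <- match.arg(source)
  order <- as.integer(order); k <- as.integer(k)
  if (bitwAnd(order, order - 1L) != 0L)
    stop("`order` must be a power of 2, got ", order)
  if (k > order) stop("`k` (", k, ") cannot exceed `order` (", order, ")")
  if (k < 1) stop("`k` must be >= 1")
  side <- as.integer(side %||% round(sqrt(order)))
  if (side * side != order)
    stop("`order` must equal side^2 (order ", order, ", side ", side, ")")

  H <- hadamard_matrix(order)
  idx <- seq_len(order)
  if (ranking == "sequency") idx <- order(sequency(H))  # stable; DC row first
  idx <- idx[seq_len(k)]
  Hk <- H[idx, , drop = FALSE]

  # Row-major reshape of each Hadamard row to side x side, then re-vectorize
  # column-major so pattern rows line up with column-major image vectors.
  perm <- as.vector(matrix(seq_len(order), side, side, byrow = TRUE))
  H_rows <- Hk[, perm, drop = FALSE]
  P <- (H_rows + 1) / 2

  structure(list(
    P = P, H_rows = H_rows, order = order, k = k, side = side,
    ranking = ranking, source = source, rows = idx,
    bank_id = sprintf("hadamard%d_k%d_%s_%s", order, k, ranking, source)
  ), class = "pattern_bank")
}

#' @export
print.pattern_bank <- function(x, ...) {
  cat(sprintf("<pattern_bank> %d of %d Hadamard patterns (%s order, %s), %dx%d masks\n",
              x$k, x$order, x$ranking, x$source, x$side, x$side))
  invisible(x)
}

#' Retrieve one pattern as a binary image matrix
#' @param bank a [build_hadamard_bank()] result.
#' @param i pattern index (1-based, bank order).
#' @return `side x side` 0/1 matrix.
#' @export
bank_pattern <- function(bank, i) {
  stopifnot(inherits(bank, "pattern_bank"))
  if (i < 1 || i > bank$k) stop("pattern index out of range")
  matrix(bank$P[i, ], bank$side, bank$side)
}
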