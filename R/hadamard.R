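#' Normalized Hadamard matrix
#'
#' Returns a +/-1 Hadamard matrix of the requested order with its first row
#' and first column all ones, so that the first row is the all-control cycle
#' and the first column can serve as the static-tissue column. Orders 2, 4
#' and 8 use the Sylvester doubling construction; order 12 uses the Paley
#' construction over GF(11), row-negated into normalized form.
#'
#' @param order Matrix order: 2, 4, 8 or 12.
#' @return An `order` x `order` matrix `H` with `H %*% t(H) = order * I`.
#' @examples
#' H <- hadamard(4)
#' crossprod(H) # 4 * diag(4)
#' @export
hadamard <- function(order) {
  if (!order %in% c(2, 4, 8, 12))
    stop("no supported Hadamard construction of order ", order,
         " (use 2, 4, 8 or 12)")
  if (order %in% c(2, 4, 8)) {
    h <- matrix(1, 1, 1)
    while (ncol(h) < order)
      h <- rbind(cbind(h, h), cbind(h, -h))
    return(h)
  }
  # Paley I over GF(11): quadratic-residue character chi, Jacobsthal core
  q <- 11
  chi <- rep(-1L, q)
  chi[(seq_len(q)^2 %% q) + 1L] <- 1L # chi[k+1] = chi(k); chi(0) overwritten
  chi[1] <- 0L
  Q <- outer(0:(q - 1), 0:(q - 1),
             function(i, j) chi[((j - i) %% q) + 1L])
  S <- rbind(c(0, rep(1, q)), cbind(rep(-1, q), Q))
  H <- diag(q + 1) + S
  # negate rows 2..12 so the first column (and still the first row) is ones
  H[-1, ] <- -H[-1, ]
  H
}

#' Provisional ideal encoding matrix
#'
#' Builds the ideal +/-1 vessel-encoding matrix for `n_vessels` vessels from
#' the smallest admissible Hadamard order of at least `n_vessels + 1`. The
#' all-ones column is reserved for static tissue; the remaining columns are
#' permuted (randomly, unless `canonical = TRUE`) and the first `n_vessels`
#' of them assigned to the vessels. Rows are encoding cycles; the all-ones
#' row is the nonselective control cycle.
#'
#' @param n_vessels Number of vessels (2 to 11).
#' @param canonical If `TRUE`, keep the natural column order (the original
#'   OES baseline); otherwise permute using the current RNG state.
#' @return A list with `matrix` (cycles x vessels, entries +/-1), `order`,
#'   and `columns` (the Hadamard columns assigned to the vessels).
#' @export
provisional_ideal <- function(n_vessels, canonical = FALSE) {
  if (n_vessels < 2) stop("need at least 2 vessels")
  orders <- c(4, 8, 12)
  ok <- orders[orders >= n_vessels + 1]
  if (length(ok) == 0)
    stop("too many vessels for the available Hadamard orders (max 11)")
  ord <- min(ok)
  H <- hadamard(ord)
  cand <- 2:ord # column 1 (all ones) is reserved for static tissue
  cols <- if (canonical) cand[seq_len(n_vessels)]
          else sample(cand)[seq_len(n_vessels)]
  list(matrix = H[, cols, drop = FALSE], order = ord, columns = cols)
}
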