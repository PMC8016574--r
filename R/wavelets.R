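#' Orthonormal discrete wavelet and wavelet-packet transforms
#'
#' Periodized (circular) pyramid transforms with Daubechies filters. With an
#' orthonormal filter pair the transform conserves energy exactly
#' (Parseval), which the feature extractors rely on: subband energies then
#' partition the signal energy. Inputs are zero-padded to the next multiple
#' of `2^level` so every decomposition stage sees an even length;
#' zero-padding leaves the total energy unchanged.
#'
#' @name wavelets
NULL

# Daubechies scaling (low-pass decomposition) filters, orthonormal.
daubechies_filter <- function(basis) {
  switch(
    basis,
    db1 = ,
    haar = c(1, 1) / sqrt(2),
    db2 = c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2)),
    db4 = c(0.230377813308855230, 0.714846570552541500,
            0.630880767929590400, -0.027983769416983850,
            -0.187034811718881140, 0.030841381835986965,
            0.032883011666982945, -0.010597401784997278),
    stop("unsupported wavelet basis: ", basis,
         " (available: db1/haar, db2, db4)", call. = FALSE)
  )
}

# one periodized analysis step: x (even length) -> list(low, high)
dwt_step <- function(x, h) {
  n <- length(x)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1L)  # quadrature mirror high-pass
  half <- n %/% 2L
  idx <- outer(2L * (seq_len(half) - 1L), seq_len(L) - 1L, `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = half)
  list(low = as.numeric(xm %*% h), high = as.numeric(xm %*% g))
}

pad_pow2 <- function(x, level) {
  block <- 2L^level
  rem <- length(x) %% block
  if (rem != 0L) x <- c(x, numeric(block - rem))
  x
}

#' Discrete wavelet transform into level + 1 subbands
#'
#' Decomposes a single channel to depth `level` and returns the `level + 1`
#' coefficient vectors ordered coarse-to-fine:
#' `a<level>, d<level>, ..., d1`. For a 3-level transform this is the
#' familiar `a3, d3, d2, d1` set.
#'
#' @param x Numeric vector, length >= `2^level`.
#' @param basis Wavelet name: `"db1"`/`"haar"`, `"db2"` or `"db4"`
#'   (default `"db4"`, the common sEMG choice).
#' @param level Decomposition depth, typically 3 to 5 (default 3).
#' @return Named list of `level + 1` numeric coefficient vectors.
#' @examples
#' sb <- dwt_subbands(rnorm(256), "db4", 3)
#' names(sb)  # "a3" "d3" "d2" "d1"
#' @export
dwt_subbands <- function(x, basis = "db4", level = 3L) {
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  if (length(x) < 2L^level) {
    stop(sprintf("signal too short for a %d-level transform: need >= %d samples, got %d",
                 level, 2L^level, length(x)), call. = FALSE)
  }
  h <- daubechies_filter(basis)
  a <- pad_pow2(as.numeric(x), level)
  details <- vector("list", level)
  for (l in seq_len(level)) {
    st <- dwt_step(a, h)
    a <- st$low
    details[[l]] <- st$high
  }
  out <- c(list(a), rev(details))
  names(out) <- c(paste0("a", level), paste0("d", rev(seq_len(level))))
  out
}

#' Wavelet-packet energy spectrum
#'
#' Full wavelet-packet decomposition to depth `level` (both low- and
#' high-pass branches are split at every node); returns the energy
#' `sum(coefficients^2)` of each of the `2^level` terminal subspaces, in
#' the tree's natural (Paley) order. With the default `db1` basis at level
#' 3 this is the 8-element energy-spectrum feature.
#'
#' @param x Numeric vector, length >= `2^level`.
#' @param basis Wavelet name (default `"db1"`).
#' @param level Decomposition depth (default 3).
#' @return Numeric vector of `2^level` nonnegative energies, named
#'   `wpe1 ... wpe<2^level>`.
#' @export
wavelet_packet_energy <- function(x, basis = "db1", level = 3L) {
  level <- as.integer(level)
  if (level < 1L) stop("`level` must be >= 1", call. = FALSE)
  if (length(x) < 2L^level) {
    stop(sprintf("window too short for a %d-level packet transform: need >= %d samples, got %d",
                 level, 2L^level, length(x)), call. = FALSE)
  }
  h <- daubechies_filter(basis)
  nodes <- list(pad_pow2(as.numeric(x), level))
  for (l in seq_len(level)) {
    nodes <- unlist(lapply(nodes, function(v) {
      st <- dwt_step(v, h)
      list(st$low, st$high)
    }), recursive = FALSE)
  }
  en <- vapply(nodes, function(v) sum(v^2), numeric(1))
  names(en) <- paste0("wpe", seq_along(en))
  en
}
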