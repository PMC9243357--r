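# Shared internal helpers: array shifting, 3D neighborhoods, seed derivation.

# additive constant inside every entropy log (base 2); keeps log(0) finite
# without visible bias at float precision
.EPS_LOG <- 1e-16

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
log2e <- function(p) log2(p + .EPS_LOG)

# The 26-neighborhood offsets of a voxel, as a 26 x 3 integer matrix.
#' @noRd
neighborhood_offsets <- function() {
  g <- as.matrix(expand.grid(d1 = -1:1, d2 = -1:1, d3 = -1:1))
  g[rowSums(abs(g)) > 0, , drop = FALSE]
}

# The 13 unique direction pairs (half of the 26-neighborhood): the first
# nonzero component is positive, so d and -d are never both present.
#' @noRd
unique_directions <- function() {
  off <- neighborhood_offsets()
  keep <- apply(off, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  off[keep, , drop = FALSE]
}

# Shift a 3D array by offset d: result[v] = a[v + d], NA outside the grid.
#' @noRd
shift_array <- function(a, d) {
  dm <- dim(a)
  if (any(abs(d) >= dm)) {
    return(array(a[NA_integer_][1], dm))
  }
  dst <- src <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      dst[[ax]] <- seq_len(dm[ax] - d[ax])
    } else {
      dst[[ax]] <- seq.int(1L - d[ax], dm[ax])
    }
    src[[ax]] <- dst[[ax]] + d[ax]
  }
  out <- array(a[NA_integer_][1], dm)
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    a[src[[1]], src[[2]], src[[3]]]
  out
}

# Deterministic seed derivation: every random draw in the pipeline traces to
# a base seed through (stage, repetition, fold) via a splitmix-style integer
# mix, kept inside the 31-bit range R accepts for set.seed().
#' @noRd
derive_seed <- function(base_seed, ...) {
  keys <- c(base_seed, ...)
  h <- 0
  for (k in keys) {
    kk <- if (is.character(k)) sum(utf8ToInt(k) * seq_along(utf8ToInt(k))) else as.numeric(k)
    h <- (h * 1000003 + kk + 12820163) %% 2147483647
  }
  as.integer(h)
}

# Polynomial rolling hash (two lanes, mod large primes) of a character
# vector, reported as hex; used for manifest/config fingerprints
# (pure R, reproducible across platforms).
#' @noRd
content_hash <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h1 <- 17; h2 <- 101
  for (b in bytes) {
    h1 <- (h1 * 131 + b) %% 2147483647
    h2 <- (h2 * 137 + b) %% 2147483629
  }
  sprintf("%08x%08x", h1, h2)
}

#' @noRd
is_binary_mask <- function(mask) {
  v <- unique(as.vector(mask))
  all(v %in% c(0, 1, TRUE, FALSE, NA))
}
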