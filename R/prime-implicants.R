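#' Prime implicants of a truth table (Quine-McCluskey)
#'
#' Returns *all* prime implicants of `f == value` (the Blake canonical form),
#' not a minimal cover: completeness is what the expanded-network construction
#' for stable-motif analysis requires. An implicant is encoded as an integer
#' pair `c(bits, mask)`: `mask` flags the cared input positions, `bits` their
#' required values (uncared bits are zero).
#'
#' @param tt Integer truth table of length `2^k` (input bit `i` has weight
#'   `2^(i-1)`).
#' @param k Number of inputs (at most 16).
#' @param value Target function value, 1 (default) or 0.
#' @return List of named integer vectors `c(bits=, mask=)`; a constant-true
#'   function yields the single empty implicant `c(0, 0)`.
#' @export
prime_implicants <- function(tt, k, value = 1L) {
  if (k > 16L) stop("prime implicant computation limited to 16 inputs")
  minterms <- which(tt == value) - 1L
  if (length(minterms) == 0L) return(list())
  full_mask <- as.integer(2^k - 1)
  if (length(minterms) == 2^k) return(list(c(bits = 0L, mask = 0L)))

  cur <- cbind(bits = as.integer(minterms), mask = full_mask)
  primes <- NULL
  while (nrow(cur) > 0L) {
    combined <- rep(FALSE, nrow(cur))
    nxt <- NULL
    # group by mask, combine pairs differing in exactly one cared bit
    for (m in unique(cur[, "mask"])) {
      rows <- which(cur[, "mask"] == m)
      bits <- cur[rows, "bits"]
      for (b in seq_len(k)) {
        w <- as.integer(2^(b - 1))
        if (bitwAnd(m, w) == 0L) next
        lo <- rows[bitwAnd(bits, w) == 0L]
        hi <- rows[bitwAnd(bits, w) != 0L]
        if (!length(lo) || !length(hi)) next
        hi_partner <- bitwOr(cur[lo, "bits"], w)
        match_idx <- match(hi_partner, cur[hi, "bits"])
        ok <- !is.na(match_idx)
        if (any(ok)) {
          combined[lo[ok]] <- TRUE
          combined[hi[match_idx[ok]]] <- TRUE
          nxt <- rbind(nxt, cbind(bits = cur[lo[ok], "bits"],
                                  mask = bitwAnd(m, bitwNot(w))))
        }
      }
    }
    primes <- rbind(primes, cur[!combined, , drop = FALSE])
    if (is.null(nxt)) break
    cur <- unique(nxt)
  }
  primes <- unique(primes)
  lapply(seq_len(nrow(primes)), function(i)
    c(bits = unname(primes[i, "bits"]), mask = unname(primes[i, "mask"])))
}

# literals of an implicant as data.frame(input, value) given rule inputs
implicant_literals <- function(pi, inputs) {
  k <- length(inputs)
  pos <- which(bitwAnd(pi["mask"], 2^(seq_len(k) - 1)) != 0)
  data.frame(input = inputs[pos],
             value = as.integer(bitwAnd(pi["bits"], 2^(pos - 1)) != 0),
             stringsAsFactors = FALSE)
}
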