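# Internal interval arithmetic on 0-based half-open intervals, represented as
# a two-column numeric matrix (start, end). Kept dependency-free because these
# run inside the meiosis hot loop; the user-facing BED path goes through
# rtracklayer/IRanges instead.

iv_empty <- function() matrix(numeric(0), ncol = 2L)

#' @noRd
iv_merge <- function(iv) {
  n <- nrow(iv)
  if (n <= 1L) return(iv)
  o <- order(iv[, 1L])
  s <- iv[o, 1L]; e <- iv[o, 2L]
  ks <- s[1L]; ke <- e[1L]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(n - 1L) + 1L) {
    if (s[i] <= ke) {
      ke <- max(ke, e[i])
    } else {
      out_s <- c(out_s, ks); out_e <- c(out_e, ke)
      ks <- s[i]; ke <- e[i]
    }
  }
  cbind(c(out_s, ks), c(out_e, ke))
}

# total length of iv (assumed merged)
iv_length <- function(iv) if (nrow(iv) == 0L) 0 else sum(iv[, 2L] - iv[, 1L])

# is point x inside any interval? (half-open)
iv_contains <- function(iv, x) {
  n <- nrow(iv)
  if (n == 0L) return(FALSE)
  any(x >= iv[, 1L] & x < iv[, 2L])
}

# intersection of two merged interval sets
iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  out <- iv_empty()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1L], b[, 1L])
    e <- pmin(a[i, 2L], b[, 2L])
    keep <- s < e
    if (any(keep)) out <- rbind(out, cbind(s[keep], e[keep]))
  }
  iv_merge(out)
}

# length of the symmetric difference of two merged interval sets
iv_symdiff_length <- function(a, b) {
  la <- iv_length(a); lb <- iv_length(b)
  li <- iv_length(iv_intersect(a, b))
  (la - li) + (lb - li)
}
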