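# Independent oracles for cross-checking the metric implementations.
# All operate on plain R strings and deliberately share no code with the
# package internals.

# Memoized recursive Levenshtein: distance between suffixes a[i..], b[j..].
lev_oracle <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  # f(i, j): distance between the suffixes a[i..n] and b[j..m]
  f <- function(i, j) {
    if (i > n) return(m - j + 1L)
    if (j > m) return(n - i + 1L)
    if (!is.na(memo[i, j])) return(memo[i, j])
    cost <- if (ca[i] == cb[j]) 0L else 1L
    val <- min(f(i + 1L, j) + 1L, f(i, j + 1L) + 1L, f(i + 1L, j + 1L) + cost)
    memo[i, j] <<- val
    val
  }
  memo <- matrix(NA_integer_, n + 1, m + 1)
  f(1L, 1L)
}

# Exhaustive-with-memo Jaro matching oracle: the maximum number of matched
# character pairs over all legal assignments (identical characters, position
# difference within the window, each character used at most once). States are
# (position in b, bitmask of used positions in a); strings must be short.
jaro_s_oracle <- function(a, b) {
  ca <- utf8ToInt(a); cb <- utf8ToInt(b)
  A <- length(ca); B <- length(cb)
  stopifnot(A <= 12)
  window <- max(0L, max(A, B) %/% 2L - 1L)
  memo <- new.env(hash = TRUE)
  best <- function(j, mask) {
    if (j > B) return(0L)
    key <- paste0(j, "_", mask)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- best(j + 1L, mask)  # leave b[j] unmatched
    for (i in seq_len(A)) {
      if (ca[i] == cb[j] && abs(i - j) <= window &&
          !bitwAnd(mask, bitwShiftL(1L, i - 1L))) {
        res <- max(res, 1L + best(j + 1L, bitwOr(mask, bitwShiftL(1L, i - 1L))))
      }
    }
    memo[[key]] <- res
    res
  }
  best(1L, 0L)
}

# Exhaustive longest-common-substring search: try every substring of a,
# longest first, and return the length of the first one contained in b.
lcs_len_oracle <- function(a, b) {
  n <- nchar(a)
  if (n == 0 || nchar(b) == 0) return(0L)
  for (len in rev(seq_len(n))) {
    for (start in seq_len(n - len + 1L)) {
      if (grepl(substr(a, start, start + len - 1L), b, fixed = TRUE))
        return(len)
    }
  }
  0L
}

# Random lowercase string over a small alphabet (collision-rich).
rand_string <- function(max_len, alphabet = c("a", "b", "c", " "),
                        min_len = 0) {
  len <- sample(seq.int(min_len, max_len), 1)
  if (len == 0) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}
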