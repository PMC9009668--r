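# Independent oracles, written before (and kept independent of) the package
# implementations they check.

# --- alignment oracle -------------------------------------------------------
# Full dynamic-programming containment alignment: the shorter sequence is
# aligned in full, terminal gaps free on the longer sequence only; match +1,
# mismatch -1, linear gap -2. Identity = 100 * matches / aligned columns.

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", toupper(x)), "")[[1]]), collapse = "")
}

oracle_align_one <- function(short, long) {
  S <- strsplit(toupper(short), "")[[1]]
  L <- strsplit(toupper(long), "")[[1]]
  m <- length(S)
  n <- length(L)
  M <- matrix(0, m + 1L, n + 1L)
  M[1L, ] <- 0 # free leading gap in the longer sequence
  for (i in seq_len(m)) {
    M[i + 1L, 1L] <- -2 * i
    diag_ <- M[i, 1:n] + ifelse(S[i] == L, 1, -1)
    up <- M[i, 2:(n + 1L)] - 2
    V <- pmax(diag_, up)
    W <- c(M[i + 1L, 1L], V) + 2 * (0:n)
    M[i + 1L, ] <- cummax(W) - 2 * (0:n)
  }
  jmax <- which.max(M[m + 1L, ]) - 1L # free trailing gap in longer seq
  score <- M[m + 1L, jmax + 1L]
  i <- m
  j <- jmax
  matches <- 0L
  cols <- 0L
  while (i > 0L) {
    if (j > 0L &&
      M[i + 1L, j + 1L] == M[i, j] + (if (S[i] == L[j]) 1 else -1)) {
      matches <- matches + (S[i] == L[j])
      i <- i - 1L
      j <- j - 1L
    } else if (M[i + 1L, j + 1L] == M[i, j + 1L] - 2) {
      i <- i - 1L
    } else if (j > 0L && M[i + 1L, j + 1L] == M[i + 1L, j] - 2) {
      j <- j - 1L
    } else {
      stop("oracle traceback failed")
    }
    cols <- cols + 1L
  }
  list(score = score, identity = 100 * matches / cols)
}

oracle_identity <- function(a, b) {
  if (nchar(a) > nchar(b)) {
    tmp <- a
    a <- b
    b <- tmp
  }
  max(
    oracle_align_one(a, b)$identity,
    oracle_align_one(oracle_revcomp(a), b)$identity
  )
}

# --- chi-square oracle ------------------------------------------------------
# textbook sum((O - E)^2 / E) with margin-derived expectations
oracle_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - expected)^2 / expected)
}
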