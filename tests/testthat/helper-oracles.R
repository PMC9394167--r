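# Independent reference implementations used to check the package's fast
# paths. Kept deliberately naive.

# Plain-R optimal-string-alignment DP over the full (n+1) x (m+1) table,
# written directly from the recurrence, no early exit, no rolling rows.
osa_oracle <- function(a, b) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      cost <- if (A[i] == B[j]) 0L else 1L
      v <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && A[i] == B[j - 1] && A[i - 1] == B[j])
        v <- min(v, d[i - 1, j - 1] + 1L)
      d[i + 1, j + 1] <- v
    }
  }
  d[n + 1, m + 1]
}

# all strings over `alphabet` of length 0..max_len
enumerate_strings <- function(alphabet, max_len) {
  out <- ""
  for (len in seq_len(max_len)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, do.call(paste0, grid))
  }
  out
}

# Closed-form pooled two-sample t-test, textbook formulation.
pooled_t_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  beta <- mean(y) - mean(x)
  t <- beta / se
  list(beta = beta, se = se, t = t, df = nx + ny - 2,
       p = 2 * pt(-abs(t), nx + ny - 2))
}

random_dna_vec <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}
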