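# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the PG oracle samples the infinite gamma
# convolution directly in R, the CRT oracle enumerates the exact pmf through
# Stirling numbers, and the scaled-inv-chi-square CDF comes from pchisq.

# PG(b, c) by direct truncation of the gamma convolution (no tail trick);
# K = 2000 makes the truncation bias negligible at the scales tested
series_pg <- function(n, b, c, K = 2000) {
  d <- (seq_len(K) - 0.5)^2 + c^2 / (4 * pi^2)
  vapply(seq_len(n), function(i) sum(rgamma(K, b, 1) / d), numeric(1)) /
    (2 * pi^2)
}

# unsigned Stirling numbers of the first kind, rows 0..n (recurrence)
stirling1_row <- function(n) {
  s <- 1  # row for n = 0: |s(0, 0)| = 1
  if (n == 0) return(s)
  for (m in seq_len(n)) {
    s_new <- numeric(m + 1)
    s_new[1] <- 0                                   # |s(m, 0)| = 0 for m >= 1
    for (k in seq_len(m))
      s_new[k + 1] <- (m - 1) * (if (k + 1 <= length(s)) s[k + 1] else 0) + s[k]
    s <- s_new
  }
  s  # s[l + 1] = |s(n, l)|, l = 0..n
}

# exact CRT(y, r) pmf on 0..y: |s(y, l)| r^l / (r (r+1) ... (r+y-1))
crt_pmf <- function(y, r) {
  if (y == 0) return(1)
  s <- stirling1_row(y)
  l <- 0:y
  logp <- log(s) + l * log(r) - (lgamma(r + y) - lgamma(r))
  p <- exp(logp)
  p[s == 0] <- 0
  p
}

# CDF of the scaled inverse chi-square(nu, S)
pinvchisq <- function(q, nu, S) {
  pchisq(nu * S / q, df = nu, lower.tail = FALSE)
}

# small balanced panel with given counts (counts recycled over the grid)
toy_panel <- function(I = 2, J = 3, K = 1, n = 2, counts = NULL) {
  g <- expand.grid(rep = seq_len(n), block = paste0("B", seq_len(K)),
                   line = sprintf("L%02d", seq_len(J)),
                   env = paste0("E", seq_len(I)),
                   stringsAsFactors = FALSE)
  if (is.null(counts)) counts <- seq_len(nrow(g)) %% 7
  g$count <- rep_len(counts, nrow(g))
  count_panel(g[, c("env", "block", "line", "rep", "count")])
}
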