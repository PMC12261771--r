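# Independent brute-force oracles for the complexity metrics and the
# episode detector. Deliberately naive (explicit loops, different
# formulations from the package implementations) so agreement is a real
# cross-check.

sampen_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  count <- function(mm) {
    nt <- n - m              # both template sets share this count
    c0 <- 0
    for (i in 1:(nt - 1)) {
      for (j in (i + 1):nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          c0 <- c0 + 1
      }
    }
    c0
  }
  B <- count(m); A <- count(m + 1)
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

apen_oracle <- function(x, m = 2, r = 0.2 * sd(x)) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    s <- 0
    for (i in 1:nt) {
      c0 <- 0
      for (j in 1:nt) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r)
          c0 <- c0 + 1
      }
      s <- s + log(c0 / nt)
    }
    s / nt
  }
  phi(m) - phi(m + 1)
}

# LZ76 phrase count via string operations: grow the current phrase until it
# is no longer a substring of everything before its last character.
lz76_oracle <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  if (n == 0) return(0)
  c0 <- 1; i <- 2
  while (i <= n) {
    l <- 1
    while (i + l - 1 <= n &&
           grepl(substr(s, i, i + l - 1),
                 substr(s, 1, i + l - 2), fixed = TRUE)) {
      l <- l + 1
    }
    c0 <- c0 + 1
    i <- i + l
  }
  c0
}

ctm_oracle <- function(x, rho) {
  n <- length(x)
  cnt <- 0
  for (i in 1:(n - 2)) {
    d1 <- x[i + 1] - x[i]; d2 <- x[i + 2] - x[i + 1]
    if (sqrt(d1^2 + d2^2) < rho) cnt <- cnt + 1
  }
  cnt / (n - 2)
}

poincare_oracle <- function(x) {
  pvar <- function(v) sum((v - mean(v))^2) / length(v)
  sd1 <- sqrt(pvar(diff(x))) / sqrt(2)
  c(SD1 = sd1, SD2 = sqrt(2 * pvar(x) - sd1^2))
}

# Brute-force run-length scan for the hypotension rule: walks the series
# sample by sample.
episode_oracle <- function(map, threshold = 65, min_duration = 60) {
  n <- length(map)
  out <- NULL
  i <- 1
  while (i <= n) {
    if (!is.na(map[i]) && map[i] <= threshold) {
      j <- i
      while (j < n && !is.na(map[j + 1]) && map[j + 1] <= threshold)
        j <- j + 1
      if (j - i + 1 > min_duration)
        out <- rbind(out, c(start = i - 1, end = j))  # 0-based times
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    data.frame(start = numeric(0), end = numeric(0))
  else
    data.frame(start = out[, 1], end = out[, 2])
}
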