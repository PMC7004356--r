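# Independent brute-force permutation oracles for the nonparametric tests.
# These enumerate raw rearrangements and recompute each statistic from
# first principles; they share no code with the package implementations.

all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

oracle_kw_stat <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  num <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    num <- num + sum(rg)^2 / length(rg)
  }
  H0 <- 12 / (N * (N + 1)) * num - 3 * (N + 1)
  tie <- table(values)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  if (corr == 0) 0 else H0 / corr
}

# exact p by permuting the response vector over all N! orderings
oracle_kw_p <- function(values, groups) {
  obs <- oracle_kw_stat(values, groups)
  perms <- all_perms(values)
  mean(vapply(perms, function(v) oracle_kw_stat(v, groups), 0) >= obs - 1e-9)
}

oracle_ranksum_p <- function(x, y, alternative = "two.sided") {
  pooled <- c(x, y)
  nx <- length(x)
  r <- rank(pooled)
  U_of <- function(sel) sum(r[sel]) - nx * (nx + 1) / 2
  obs <- U_of(seq_len(nx))
  mu <- nx * length(y) / 2
  sels <- utils::combn(length(pooled), nx, simplify = FALSE)
  Us <- vapply(sels, U_of, 0)
  switch(alternative,
         two.sided = mean(abs(Us - mu) >= abs(obs - mu) - 1e-9),
         less = mean(Us <= obs + 1e-9),
         greater = mean(Us >= obs - 1e-9))
}

oracle_signedrank_p <- function(x, y, alternative = "two.sided") {
  d <- (x - y)[x != y]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  Vs <- numeric(2^n)
  for (m in 0:(2^n - 1)) {
    bits <- as.logical(bitwAnd(m, 2^(0:(n - 1))))
    Vs[m + 1] <- sum(r[bits])
  }
  switch(alternative,
         two.sided = mean(abs(Vs - mu) >= abs(obs - mu) - 1e-9),
         less = mean(Vs <= obs + 1e-9),
         greater = mean(Vs >= obs - 1e-9))
}

oracle_friedman_stat <- function(y) {
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, rank))
  s0 <- 12 / (n * k * (k + 1)) * sum(colSums(r)^2) - 3 * n * (k + 1)
  tt <- sum(apply(y, 1, function(row) { tb <- table(row); sum(tb^3 - tb) }))
  corr <- 1 - tt / (n * k * (k^2 - 1))
  if (corr <= 0) 0 else s0 / corr
}

oracle_friedman_p <- function(y) {
  obs <- oracle_friedman_stat(y)
  k <- ncol(y); n <- nrow(y)
  perms <- all_perms(seq_len(k))
  idx <- rep(1L, n)
  hits <- 0L; total <- 0L
  repeat {
    yp <- y
    for (i in seq_len(n)) yp[i, ] <- y[i, perms[[idx[i]]]]
    total <- total + 1L
    if (oracle_friedman_stat(yp) >= obs - 1e-9) hits <- hits + 1L
    j <- 1L
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= length(perms)) break
      idx[j] <- 1L; j <- j + 1L
      if (j > n) break
    }
    if (j > n) break
  }
  hits / total
}
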