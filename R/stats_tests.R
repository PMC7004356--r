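# Nonparametric battery relating segment classifications to outcomes.
# Observed statistics delegate to stats:: where a tie-corrected statistic
# exists; p-values switch between exact permutation enumeration (small
# samples) and tie-corrected asymptotics, since chi-square approximations
# are unreliable at the group sizes the rare outcome bins produce.

midranks <- function(x) rank(x, ties.method = "average")

kw_statistic <- function(values, groups) {
  # tie-corrected Kruskal-Wallis H (identical to stats::kruskal.test)
  N <- length(values)
  r <- midranks(values)
  R <- tapply(r, groups, sum)
  n <- tapply(r, groups, length)
  ties <- table(values)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) return(0)
  (12 / (N * (N + 1)) * sum(R^2 / n) - 3 * (N + 1)) / C
}

# all assignments of N pooled observations to groups of the given sizes
enum_assignments <- function(N, sizes) {
  out <- list()
  recurse <- function(remaining, sizes, acc) {
    if (length(sizes) == 1L) {
      out[[length(out) + 1L]] <<- c(acc, list(remaining))
      return(invisible())
    }
    cmb <- utils::combn(remaining, sizes[1], simplify = FALSE)
    for (g in cmb) recurse(setdiff(remaining, g), sizes[-1], c(acc, list(g)))
  }
  recurse(seq_len(N), sizes, list())
  out
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H statistic; exact permutation p-value (enumeration of all
#' group assignments) when the total sample size is at most
#' `cfg$exact_max_n`, chi-square approximation otherwise. Groups with fewer
#' than 2 observations are excluded with a warning; fully tied data give
#' statistic 0 and p-value 1.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @param cfg A [stats_config()].
#' @return List with `statistic`, `p_value`, `df`, `method`
#'   (`"exact"`/`"asymptotic"`), `groups`.
#' @export
kw_test <- function(values, groups, cfg = stats_config()) {
  groups <- factor(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with n < 2: ", paste(small, collapse = ", "))
    keep <- !(groups %in% small)
    values <- values[keep]; groups <- droplevels(groups[keep])
  }
  if (nlevels(groups) < 2 || length(values) < 3)
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_integer_,
                method = "undefined", groups = levels(groups)))
  k <- nlevels(groups)
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, p_value = 1, df = k - 1L,
                method = "degenerate", groups = levels(groups)))
  H <- unname(stats::kruskal.test(values, groups)$statistic)
  N <- length(values)
  if (N <= cfg$exact_max_n) {
    sizes <- as.integer(table(groups))
    asg <- enum_assignments(N, sizes)
    glab <- rep.int(seq_along(sizes), sizes)
    perm <- vapply(asg, function(a) {
      g <- integer(N)
      for (j in seq_along(a)) g[a[[j]]] <- j
      kw_statistic(values, g)
    }, 0)
    p <- mean(perm >= H - 1e-9)
    list(statistic = H, p_value = p, df = k - 1L, method = "exact",
         groups = levels(groups))
  } else {
    list(statistic = H, p_value = stats::pchisq(H, k - 1, lower.tail = FALSE),
         df = k - 1L, method = "asymptotic", groups = levels(groups))
  }
}

friedman_statistic <- function(y) {
  # y: n subjects x k conditions; tie-corrected Friedman chi-square
  n <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, midranks))
  R <- colSums(r)
  stat0 <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  ties <- apply(y, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  })
  C <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (C <= 0) return(0)
  stat0 / C
}

#' Friedman test for repeated segment measures
#'
#' Tie-corrected Friedman chi-square over an `n x k` matrix (subjects x
#' conditions, e.g. the six 10-minute segments). Exact permutation p-value
#' by enumerating all within-subject orderings when `(k!)^n` is small
#' enough (at most `max_enum`), chi-square with `k - 1` df otherwise.
#'
#' @param y Numeric matrix, subjects in rows, conditions in columns;
#'   rows with any `NA` are dropped.
#' @param cfg A [stats_config()].
#' @param max_enum Enumeration budget for the exact path. Default 500000.
#' @return List as in [kw_test()].
#' @export
friedman_test_seg <- function(y, cfg = stats_config(), max_enum = 5e5) {
  y <- y[stats::complete.cases(y), , drop = FALSE]
  n <- nrow(y); k <- ncol(y)
  if (n < 2 || k < 2)
    return(list(statistic = NA_real_, p_value = NA_real_, df = NA_integer_,
                method = "undefined", groups = colnames(y)))
  if (all(apply(y, 1, function(r) length(unique(r)) == 1L)))
    return(list(statistic = 0, p_value = 1, df = k - 1L,
                method = "degenerate", groups = colnames(y)))
  stat <- friedman_statistic(y)
  n_enum <- factorial(k)^n
  if (n <= cfg$exact_max_n && n_enum <= max_enum) {
    perms <- perm_all(k)
    idx <- rep(1L, n)
    count <- 0L; total <- 0L
    repeat {
      yp <- y
      for (i in seq_len(n)) yp[i, ] <- y[i, perms[[idx[i]]]]
      total <- total + 1L
      if (friedman_statistic(yp) >= stat - 1e-9) count <- count + 1L
      j <- 1L
      repeat {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(perms)) break
        idx[j] <- 1L; j <- j + 1L
        if (j > n) break
      }
      if (j > n) break
    }
    list(statistic = stat, p_value = count / total, df = k - 1L,
         method = "exact", groups = colnames(y))
  } else {
    list(statistic = stat,
         p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
         df = k - 1L, method = "asymptotic", groups = colnames(y))
  }
}

perm_all <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- perm_all(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

#' Wilcoxon rank-sum test (Mann-Whitney)
#'
#' Mann-Whitney U statistic; exact permutation p-value (enumeration of all
#' group splits of the pooled sample, valid under ties) when the pooled
#' size is at most `cfg$exact_max_n`, tie-corrected normal approximation
#' otherwise.
#'
#' @param x,y Numeric samples for the two groups.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (distribution of `x` shifted below / above `y`).
#' @param cfg A [stats_config()].
#' @return List with `statistic` (U for `x`), `p_value`, `method`.
#' @export
rank_sum_test <- function(x, y, alternative = c("two.sided", "less", "greater"),
                          cfg = stats_config()) {
  alternative <- match.arg(alternative)
  nx <- length(x); ny <- length(y); N <- nx + ny
  if (nx < 1 || ny < 1)
    return(list(statistic = NA_real_, p_value = NA_real_, method = "undefined"))
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L)
    return(list(statistic = nx * ny / 2, p_value = 1, method = "degenerate"))
  r <- midranks(pooled)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  if (N <= cfg$exact_max_n) {
    mu <- nx * ny / 2
    splits <- utils::combn(N, nx, simplify = FALSE)
    Us <- vapply(splits, function(s) sum(r[s]) - nx * (nx + 1) / 2, 0)
    p <- switch(alternative,
                two.sided = mean(abs(Us - mu) >= abs(U - mu) - 1e-9),
                less = mean(Us <= U + 1e-9),
                greater = mean(Us >= U - 1e-9))
    list(statistic = U, p_value = p, method = "exact")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    list(statistic = U, p_value = wt$p.value, method = "asymptotic")
  }
}

#' Wilcoxon signed-rank test
#'
#' Paired-sample signed-rank statistic (V = sum of positive-difference
#' ranks, zeros dropped); exact sign-flip enumeration when the number of
#' non-zero differences is at most `cfg$exact_max_n`, tie-corrected normal
#' approximation otherwise.
#'
#' @param x,y Paired numeric samples (equal length).
#' @param alternative As in [rank_sum_test()].
#' @param cfg A [stats_config()].
#' @return List with `statistic` (V), `p_value`, `method`.
#' @export
signed_rank_test <- function(x, y,
                             alternative = c("two.sided", "less", "greater"),
                             cfg = stats_config()) {
  alternative <- match.arg(alternative)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0)
    return(list(statistic = 0, p_value = 1, method = "degenerate"))
  r <- midranks(abs(d))
  V <- sum(r[d > 0])
  if (n <= cfg$exact_max_n) {
    mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Vs <- as.vector(signs %*% r)
    p <- switch(alternative,
                two.sided = mean(abs(Vs - mu) >= abs(V - mu) - 1e-9),
                less = mean(Vs <= V + 1e-9),
                greater = mean(Vs >= V - 1e-9))
    list(statistic = V, p_value = p, method = "exact")
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                              alternative = alternative,
                                              exact = FALSE, correct = TRUE))
    list(statistic = V, p_value = wt$p.value, method = "asymptotic")
  }
}

#' Tukey HSD pairwise comparisons
#'
#' Pooled-variance Tukey honest-significant-difference comparisons of group
#' means via the studentized-range distribution
#' ([stats::TukeyHSD()]), used here as the post-hoc pairwise step after a
#' Kruskal-Wallis test. Applied to ordinal classification values as the
#' source analysis lists it; this treats levels as equally spaced scores.
#'
#' @param values Numeric response.
#' @param groups Group labels.
#' @return Data.frame with columns `contrast`, `diff`, `lwr`, `upr`,
#'   `p_value`, or `NULL` when fewer than two groups have `n >= 2`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- factor(groups)
  sizes <- table(groups)
  keep <- groups %in% names(sizes)[sizes >= 2]
  values <- values[keep]; groups <- droplevels(groups[keep])
  if (nlevels(groups) < 2 || stats::var(values) == 0) return(NULL)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_value = tk[, "p adj"], row.names = NULL)
}
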