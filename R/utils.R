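#' Two-sided p-value for a Pearson correlation
#'
#' Standard t transform: t = r * sqrt((n - 2) / (1 - r^2)) referred to a
#' t distribution with n - 2 degrees of freedom.
#'
#' @param r Correlation coefficient(s) in [-1, 1].
#' @param n Sample size used to compute `r`.
#' @param alternative "two.sided", "less" (tests r < 0) or "greater".
#' @return p-value(s), same length as `r`.
#' @export
cor_pvalue <- function(r, n, alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 4, all(abs(r) <= 1))
  df <- n - 2
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  switch(alternative,
    two.sided = 2 * stats::pt(-abs(tt), df),
    less      = stats::pt(tt, df),
    greater   = stats::pt(tt, df, lower.tail = FALSE)
  )
}

# Deterministic per-component sub-seed so adding a component never perturbs
# the random stream of another. Offsets are fixed by name, result < 2^31.
component_seed <- function(seed, component) {
  offsets <- c(
    expression = 11L, traits = 23L, causal = 37L, mirna = 41L,
    studies = 53L, gwas = 67L, preservation = 71L, permutation = 83L,
    scramble = 97L
  )
  off <- offsets[[component]]
  (as.integer(seed) %% 20000L) * 100000L + off
}

# Standardize rows of a matrix to mean 0, variance 1 (sd denominator n-1).
standardize_rows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  if (any(s == 0)) stop("cannot standardize constant rows: ",
                        paste(rownames(x)[s == 0], collapse = ", "))
  (x - mu) / s
}
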