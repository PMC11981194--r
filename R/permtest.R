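.check_scores <- function(x, label) {
  if (!length(x)) stop("group ", label, " is empty")
  if (any(!is.finite(x))) stop("group ", label, " has non-finite scores")
  invisible(x)
}

#' Two-sided permutation test on the difference of group means
#'
#' The test statistic is `T = mean(a) - mean(b)`. Group labels are permuted
#' without replacement `B` times and the two-sided Monte-Carlo p-value is
#' `(#{|T*| >= |T_obs| - eps} + 1) / (B + 1)` with `eps = 1e-12` absorbing
#' float ties; the +1 correction means the reported p is never exactly 0.
#' Designed for ordinal hypersensitive-response scores on the 0 (no
#' necrosis) to 7 (confluent necrosis) scale, but accepts any numeric
#' scores.
#'
#' @param a,b Numeric score vectors (each with at least 2 observations for
#'   a meaningful test; at least 1 required).
#' @param B Number of resamples (default 10000).
#' @param seed Optional integer seed; recorded in the result.
#' @return Object of class `perm_test`: `T_obs`, `p`, `B`, `seed`,
#'   `method = "monte_carlo"`.
#' @export
permutation_test <- function(a, b, B = 10000L, seed = NULL) {
  .check_scores(a, "a"); .check_scores(b, "b")
  stopifnot(B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  x <- c(a, b)
  na <- length(a); n <- length(x)
  tot <- sum(x)
  t_obs <- mean(a) - mean(b)
  # sum of group-a values determines T*: T* = sA/na - (tot - sA)/nb
  nb <- n - na
  t_star <- vapply(seq_len(B), function(i) {
    sA <- sum(x[sample.int(n, na)])
    sA / na - (tot - sA) / nb
  }, 0)
  eps <- 1e-12
  p <- (sum(abs(t_star) >= abs(t_obs) - eps) + 1) / (B + 1)
  structure(list(T_obs = t_obs, p = p, B = B, seed = seed,
                 method = "monte_carlo"),
            class = "perm_test")
}

#' Exact permutation p-value by full enumeration
#'
#' Enumerates all `choose(n, n_a)` assignments of observations to group a
#' and reports `p = #{|T*| >= |T_obs|} / C(n, n_a)` (no +1 correction).
#' Serves as the oracle for the Monte-Carlo test.
#'
#' @param a,b Numeric score vectors.
#' @param max_combinations Guard on `choose(n, n_a)` (default 1e6).
#' @return Object of class `perm_test` with `method = "exact"` and `B` the
#'   number of enumerated assignments.
#' @export
exact_permutation_p <- function(a, b, max_combinations = 1e6) {
  .check_scores(a, "a"); .check_scores(b, "b")
  x <- c(a, b)
  na <- length(a); n <- length(x)
  C <- choose(n, na)
  if (C > max_combinations)
    stop("choose(", n, ", ", na, ") = ", C, " exceeds the enumeration bound")
  nb <- n - na
  tot <- sum(x)
  t_obs <- mean(a) - mean(b)
  idx <- utils::combn(n, na)
  sA <- colSums(matrix(x[idx], nrow = na))
  t_star <- sA / na - (tot - sA) / nb
  eps <- 1e-12
  p <- sum(abs(t_star) >= abs(t_obs) - eps) / C
  structure(list(T_obs = t_obs, p = p, B = C, seed = NULL,
                 method = "exact"),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat("<perm_test> ", x$method, ": T_obs = ", format(x$T_obs),
      ", p = ", format(x$p), " (B = ", x$B, ")\n", sep = "")
  invisible(x)
}

#' Read an HR score table
#'
#' @param path TSV with columns `treatment`, `replicate`, `score`.
#' @return Data frame with integer scores validated to lie in 0..7.
#' @export
read_hr_scores <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("treatment", "replicate", "score")
  if (!all(need %in% names(df)))
    stop("score table needs columns: ", paste(need, collapse = ", "))
  if (any(!(df$score %in% 0:7)))
    stop("HR scores must be integers in 0..7")
  df
}
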