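#' Statistical comparisons for agent and group contrasts
#'
#' Thin, reproducibility-oriented wrappers around the classical tests used
#' to compare fluorescence readouts between groups and agents. Each wrapper
#' enforces an explicit exact/approximate switch and records which was used,
#' so small-sample p-values are exact (verifiable by enumeration) and the
#' computation mode is never silent:
#'
#' * [mann_whitney()] — unpaired two-sample rank test; exact when
#'   `n + m <= 12` and the pooled data are tie-free, otherwise a normal
#'   approximation with tie and continuity correction.
#' * [wilcoxon_signed_rank()] — paired rank test on the differences; zero
#'   differences are discarded (classic convention), exact when the number
#'   of non-zero differences is <= 20 and their magnitudes are tie-free.
#' * [paired_t()] — paired t test on the differences.
#'
#' All p-values are two-sided.
#'
#' @name fgs-tests
NULL

new_fgs_test <- function(test, statistic_name, statistic, p_value,
                         n, m = NA_integer_, method) {
  structure(list(test = test, statistic_name = statistic_name,
                 statistic = unname(statistic), p_value = unname(p_value),
                 n = n, m = m, method = method),
            class = "fgs_test")
}

#' @export
print.fgs_test <- function(x, ...) {
  sizes <- if (is.na(x$m)) sprintf("n = %d", x$n)
           else sprintf("n = %d, m = %d", x$n, x$m)
  cat(sprintf("%s: %s = %.4g, two-sided p = %.4g (%s; %s)\n",
              x$test, x$statistic_name, x$statistic, x$p_value,
              sizes, x$method))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' @param x,y Numeric samples (each non-empty).
#' @return An `fgs_test` with the U statistic (number of `(x, y)` pairs with
#'   `x > y`, counting ties half), the two-sided p-value, sample sizes and
#'   whether the exact distribution or the corrected normal approximation
#'   was used.
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @rdname fgs-tests
#' @export
mann_whitney <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    fgs_abort("both samples must be non-empty", "fgs_input_error")
  }
  if (anyNA(c(x, y))) fgs_abort("samples must not contain NA",
                                "fgs_input_error")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 12L
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact)
  )
  new_fgs_test("Mann-Whitney U test", "U", res$statistic, res$p.value,
               n = length(x), m = length(y),
               method = if (exact) "exact" else "approximate")
}

#' Wilcoxon signed-rank test
#'
#' @param paired_a,paired_b Paired numeric samples of equal length (>= 2);
#'   the test is on the differences `paired_a - paired_b`. Not all
#'   differences may be zero.
#' @return An `fgs_test` with the W statistic (sum of ranks of positive
#'   differences).
#' @examples
#' wilcoxon_signed_rank(c(2, 4, 6, 8, 10), c(1, 2, 3, 4, 5))  # W = 15, p = 0.0625
#' @rdname fgs-tests
#' @export
wilcoxon_signed_rank <- function(paired_a, paired_b) {
  a <- as.numeric(paired_a)
  b <- as.numeric(paired_b)
  if (length(a) != length(b) || length(a) < 2L) {
    fgs_abort("paired samples must have equal length >= 2", "fgs_input_error")
  }
  if (anyNA(c(a, b))) fgs_abort("samples must not contain NA",
                                "fgs_input_error")
  d <- a - b
  d <- d[d != 0]  # classic convention: zero differences carry no sign information
  if (length(d) == 0L) {
    fgs_abort("all paired differences are zero: the test is degenerate",
              "fgs_degenerate_error")
  }
  ties <- anyDuplicated(abs(d)) > 0L
  exact <- !ties && length(d) <= 20L
  res <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = exact, correct = !exact)
  )
  new_fgs_test("Wilcoxon signed-rank test", "W", res$statistic, res$p.value,
               n = length(d),
               method = if (exact) "exact" else "approximate")
}

#' Paired t test
#'
#' @return An `fgs_test` with the t statistic
#'   (`mean(d) / (sd(d) / sqrt(n))`, `n - 1` degrees of freedom).
#' @rdname fgs-tests
#' @export
paired_t <- function(paired_a, paired_b) {
  a <- as.numeric(paired_a)
  b <- as.numeric(paired_b)
  if (length(a) != length(b) || length(a) < 2L) {
    fgs_abort("paired samples must have equal length >= 2", "fgs_input_error")
  }
  if (anyNA(c(a, b))) fgs_abort("samples must not contain NA",
                                "fgs_input_error")
  d <- a - b
  if (sd(d) == 0) {
    fgs_abort("paired differences have zero variance: the t test is degenerate",
              "fgs_degenerate_error")
  }
  res <- t.test(a, b, paired = TRUE)
  new_fgs_test("Paired t test", "t", res$statistic, res$p.value,
               n = length(a), method = "t distribution")
}

#' Compare two agents across a paired cohort table
#'
#' Runs the chosen paired test (or the unpaired Mann-Whitney) on per-animal
#' TNRs of two agents.
#'
#' @param table Data frame with columns `animal_id`, `agent`, `tnr`.
#' @param agents Character 2-vector naming the agents to compare (first
#'   minus/over second).
#' @param test `"wilcoxon"`, `"paired_t"` or `"mann_whitney"`.
#' @return An `fgs_test`.
#' @export
compare_agents <- function(table, agents,
                           test = c("wilcoxon", "paired_t", "mann_whitney")) {
  test <- match.arg(test)
  if (!all(c("animal_id", "agent", "tnr") %in% names(table))) {
    fgs_abort("table must have columns animal_id, agent, tnr",
              "fgs_input_error")
  }
  if (length(agents) != 2L) {
    fgs_abort("exactly two agents must be named", "fgs_input_error")
  }
  ta <- table[table$agent == agents[1], , drop = FALSE]
  tb <- table[table$agent == agents[2], , drop = FALSE]
  if (test == "mann_whitney") return(mann_whitney(ta$tnr, tb$tnr))
  common <- intersect(ta$animal_id, tb$animal_id)
  if (length(common) < 2L) {
    fgs_abort("paired tests need >= 2 animals measured under both agents",
              "fgs_input_error")
  }
  a <- ta$tnr[match(common, ta$animal_id)]
  b <- tb$tnr[match(common, tb$animal_id)]
  if (test == "wilcoxon") wilcoxon_signed_rank(a, b) else paired_t(a, b)
}
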