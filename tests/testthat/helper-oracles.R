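# Independent oracles used to validate the implementation.

# --- Rank-test enumeration oracles -----------------------------------------

# Mann-Whitney U of x over y (no ties assumed for the exact oracle).
mw_u_stat <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of the
# C(n+m, n) equally likely rank assignments under the null.
mw_enum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  u_obs <- mw_u_stat(x, y)
  combs <- utils::combn(n + m, n)
  ranks <- seq_len(n + m)
  us <- apply(combs, 2, function(sel) sum(ranks[sel]) - n * (n + 1) / 2)
  p <- 2 * min(mean(us <= u_obs), mean(us >= u_obs))
  min(1, p)
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all 2^n
# sign patterns on the ranks of |d| (zero differences already removed; no
# tied magnitudes assumed).
wsr_w_stat <- function(d) {
  r <- rank(abs(d))
  sum(r[d > 0])
}

wsr_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  w_obs <- wsr_w_stat(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% r)
  p <- 2 * min(mean(ws <= w_obs), mean(ws >= w_obs))
  min(1, p)
}

# --- Dense unit-sphere search oracle for the optimal projection ------------

# Fibonacci-spiral grid of n near-uniform unit directions.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Brute-force maximizer of |v . (mt - mn)| over the given directions, sign
# fixed so the tumor median projects higher.
brute_projection <- function(median_tumor, median_normal, dirs) {
  proj <- dirs %*% (median_tumor - median_normal)
  i <- which.max(abs(proj))
  v <- dirs[i, ] * sign(proj[i])
  v / sqrt(sum(v^2))
}

angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# --- Misc ------------------------------------------------------------------

iou <- function(a, b) sum(a & b) / sum(a | b)
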