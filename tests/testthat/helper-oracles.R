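# Independent oracles used to validate the package implementations.  These
# are deliberately written with different algorithms than the package code:
# the point-line distance uses the implicit line equation, and the rank-test
# oracles enumerate the permutation space by brute force.

# Signed point-to-line distance oracle: |a x + b y + c| / sqrt(a^2 + b^2)
# with the sign fixed by a half-plane probe on the posterior side.
oracle_scan_lcd <- function(ann) {
  p1 <- ann$bmo[1, ]; p2 <- ann$bmo[2, ]
  A <- p2[2] - p1[2]
  B <- p1[1] - p2[1]
  C <- p2[1] * p1[2] - p1[1] * p2[2]
  raw <- function(pt) (A * pt[1] + B * pt[2] + C) / sqrt(A^2 + B^2)
  probe_dir <- if (ann$axial_positive_is_posterior) c(0, 1) else c(0, -1)
  s <- raw((p1 + p2) / 2 + probe_dir)
  if (s == 0) s <- raw((p1 + p2) / 2 + c(1, 0))  # vertical BMO line
  sgn <- sign(s)
  max(apply(ann$lc, 1, function(pt) sgn * raw(pt)))
}

random_annotation <- function() {
  repeat {
    bmo <- matrix(runif(4, -2000, 2000), 2, 2)
    if (sqrt(sum((bmo[1, ] - bmo[2, ])^2)) > 1) break
  }
  n_lc <- sample(1:8, 1)
  lc <- matrix(runif(2 * n_lc, -2000, 2000), n_lc, 2)
  bscan_annotation(sample(0:74, 1), bmo, lc,
                   axial_positive_is_posterior = sample(c(TRUE, FALSE), 1))
}

# Exact two-sided signed-rank p by brute-force enumeration of all 2^n sign
# assignments (midranks under ties).  Feasible up to n = 15.
oracle_signed_rank_p <- function(d) {
  d0 <- d[d != 0]
  n <- length(d0)
  stopifnot(n >= 1, n <= 15)
  r <- rank(abs(d0))
  W <- sum(r[d0 > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Exact two-sided rank-sum p by enumeration of all choose(n1+n2, n1) group
# assignments of the midranks.
oracle_rank_sum_p <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  cmb <- utils::combn(length(r), n1)
  Ws <- colSums(matrix(r[cmb], nrow = n1))
  min(1, 2 * min(mean(Ws <= W + 1e-9), mean(Ws >= W - 1e-9)))
}

# Annotation with an anatomically plausible BMO-line tilt (|alpha| bounded),
# for invariance checks whose posterior sign convention references the image
# axial axis and is therefore only stable under moderate tilts.
random_plausible_annotation <- function(max_alpha_deg = 30) {
  alpha <- runif(1, -max_alpha_deg, max_alpha_deg) * pi / 180
  half <- runif(1, 400, 1200)
  mid <- runif(2, -1000, 1000)
  dir <- c(cos(alpha), sin(alpha))
  bmo <- rbind(mid - half * dir, mid + half * dir)
  n_lc <- sample(1:8, 1)
  lc <- matrix(runif(2 * n_lc, -1500, 1500), n_lc, 2)
  bscan_annotation(sample(0:74, 1), bmo, lc)
}

rotate_translate <- function(pts, theta, shift) {
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pts %*% t(rot), 2, shift, `+`)
}

# Minimal cohort data.frame builder for hand-crafted trajectories.
make_cohort_df <- function(subjects, visits, t_months, values,
                           column = "rnfl_G") {
  df <- expand.grid(visit_label = visits, subject_id = subjects,
                    stringsAsFactors = FALSE)[, 2:1]
  df$t_months <- rep(t_months, times = length(subjects))
  df[[column]] <- as.vector(values)
  df
}
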