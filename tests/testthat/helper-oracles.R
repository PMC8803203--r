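# Independent oracles used across the suite.

# Semi-infinite isotropic-scattering plane albedo at normal incidence,
# R = 1 - sqrt(1 - w) * H(1), with Chandrasekhar's H-function solved by
# fixed-point iteration on a midpoint grid. Independent of the MC code path.
semi_infinite_rd_oracle <- function(albedo, n = 2000, iters = 400) {
  mu <- (seq_len(n) - 0.5) / n
  dmu <- 1 / n
  s <- sqrt(1 - albedo)
  H <- rep(1, n)
  for (k in seq_len(iters)) {
    integ <- vapply(mu, function(m) sum(H * mu / (m + mu)) * dmu, 0)
    H <- 1 / (s + (albedo / 2) * integ)
  }
  H1 <- 1 / (s + (albedo / 2) * sum(H * mu / (1 + mu)) * dmu)
  1 - H1 * s
}

# Brute-force pairwise AUC: wins + half-ties over all (pos, neg) pairs.
auc_bruteforce <- function(neg, pos) {
  wins <- outer(pos, neg, ">")
  ties <- outer(pos, neg, "==")
  (sum(wins) + 0.5 * sum(ties)) / (length(pos) * length(neg))
}

# Trapezoidal area under an empirical roc_result (sorted by FPR).
roc_trapezoid_area <- function(roc) {
  o <- order(roc$one_minus_specificity, roc$sensitivity)
  x <- roc$one_minus_specificity[o]
  y <- roc$sensitivity[o]
  sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
}

# Binomial MC standard error of a fraction estimate.
mc_se <- function(p, n) sqrt(p * (1 - p) / n)

skull_truth <- function() default_ground_truth("skull")
skin_truth <- function() default_ground_truth("skin")
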