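# Independent brute-force oracles and small fixture builders. Everything here
# is deliberately naive (per-pixel loops, full enumeration) so the tested
# code paths never stand behind their own checks.

# per-pixel counting oracle for a density distribution (percent per HU 0..79)
oracle_distribution <- function(values) {
  out <- numeric(80)
  for (v in values) out[v + 1L] <- out[v + 1L] + 1
  100 * out / length(values)
}

# counting oracle for a band proportion from raw pixel values
oracle_band_percent <- function(values, lo, hi) {
  n <- 0L
  for (v in values) if (v >= lo && v <= hi) n <- n + 1L
  100 * n / length(values)
}

# exact Mann-Whitney p by enumeration of all C(n, na) group assignments
oracle_mw <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  u_stat <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- u_stat(a, b)
  combos <- utils::combn(n, length(a))
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  # two-sided: distance from the null mean
  mu <- length(a) * length(b) / 2
  list(u = u_obs, p = mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12))
}

# Fisher's exact two-sided p for a 2x2 table by hypergeometric enumeration
oracle_fisher_2x2 <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# confusion-tally oracle at a >= cutoff
oracle_confusion <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(scores)) {
    pos <- scores[i] >= cutoff
    if (pos && labels[i]) tp <- tp + 1L
    if (pos && !labels[i]) fp <- fp + 1L
    if (!pos && !labels[i]) tn <- tn + 1L
    if (!pos && labels[i]) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, tn = tn, fn = fn)
}

# exhaustive cutoff search replicating the selection contract: max Youden J,
# ties to higher specificity, then lower cutoff
oracle_best_cutoff <- function(scores, labels) {
  best <- NULL
  for (cut in sort(unique(scores))) {
    cf <- oracle_confusion(scores, labels, cut)
    sens <- cf["tp"] / (cf["tp"] + cf["fn"])
    spec <- cf["tn"] / (cf["tn"] + cf["fp"])
    j <- sens + spec - 1
    cand <- c(cutoff = cut, sensitivity = unname(sens),
              specificity = unname(spec), j = unname(j))
    if (is.null(best) ||
        cand["j"] > best["j"] + 1e-12 ||
        (abs(cand["j"] - best["j"]) < 1e-12 &&
           (cand["specificity"] > best["specificity"] + 1e-12 ||
              (abs(cand["specificity"] - best["specificity"]) < 1e-12 &&
                 cand["cutoff"] < best["cutoff"])))) {
      best <- cand
    }
  }
  best
}

# small test phantom: full geometry at a reduced grid for speed
small_phantom_spec <- function(seed = 1L, grid = 256L, ...) {
  phantom_spec(grid = grid, seed = seed, ...)
}

# synthetic HU distribution from pixel values drawn on [0, 79]
random_distribution <- function(seed) {
  withr::with_seed(seed, {
    distribution_from_pixels(sample(0:79, 500, replace = TRUE,
                                    prob = stats::dnorm(0:79, 30, 15)))
  })
}
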