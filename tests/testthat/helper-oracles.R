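# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with R/: plain loops and textbook
# formulas only.

# Naive re-implementation of the full plate densitometry chain.
naive_quantify <- function(pixels, rows = 16, cols = 24, band_h = 30,
                           spacing = 60, top_k = 25) {
  cde <- matrix(NA_real_, rows, cols)
  for (r in seq_len(rows)) {
    band <- pixels[((r - 1) * band_h + 1):(r * band_h), , drop = FALSE]
    prof <- numeric(ncol(band))
    for (j in seq_len(ncol(band))) {
      v <- sort(band[, j], decreasing = TRUE)
      prof[j] <- sum(v[1:top_k])
    }
    for (i in seq_len(cols)) {
      win <- prof[((i - 1) * spacing + 1):(i * spacing)]
      central <- sort(win[21:40], decreasing = TRUE)[1:10]
      colony <- (central[5] + central[6]) / 2
      bg <- (min(win[5:20]) + min(win[40:55])) / 2
      cde[r, i] <- colony - bg
    }
  }
  cde
}

# Random plate pixel matrices (integer intensities) for invariance checks.
random_band <- function(width = 240, band_h = 30) {
  matrix(sample.int(5000L, band_h * width, replace = TRUE), band_h, width)
}

random_plate <- function(rows = 4, cols = 6, band_h = 30, spacing = 60) {
  matrix(sample.int(5000L, rows * band_h * cols * spacing, replace = TRUE),
         rows * band_h, cols * spacing)
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# n-subsets of an N-gene universe with K term genes.
enum_hypergeom_upper <- function(k, n, K, N) {
  if (n == 0) return(if (k == 0) 1 else 0)
  subsets <- utils::combn(N, n)
  in_term <- colSums(subsets <= K)   # genes 1..K carry the term
  mean(in_term >= k)
}

# Textbook pooled-variance two-sample t statistic and two-sided p value.
pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# Naive re-scoring of a synthetic screen straight from the emitted tables,
# for precision/recall checks against the package's calls.
naive_rescore <- function(tabs, lg_cut = 0.75) {
  key <- function(d) paste(d$plate, d$row, d$col)
  l0 <- tabs$light[tabs$light$day == 0, ]
  l6 <- tabs$light[tabs$light$day == 6, ]
  d0 <- tabs$dark[tabs$dark$day == 0, ]
  d1 <- tabs$dark[tabs$dark$day == 1, ]
  w <- tabs$layout
  w$ld0 <- l0$cde[match(key(w), key(l0))]
  w$ld6 <- l6$cde[match(key(w), key(l6))]
  w$dd0 <- d0$cde[match(key(w), key(d0))]
  w$dd1 <- d1$cde[match(key(w), key(d1))]
  w$band <- ifelse(w$ld0 >= 121, "high",
                   ifelse(w$ld0 >= 61, "moderate", "discarded"))
  sens <- character(); slow <- character(); resist <- character()
  for (p in unique(w$plate)) {
    for (b in c("moderate", "high")) {
      ctl <- w[w$plate == p & w$band == b & w$control_flag & w$dd1 > 0, ]
      med <- median(ctl$ld6 / ctl$dd1)
      mt <- w[w$plate == p & w$band == b & !w$control_flag, ]
      for (i in seq_len(nrow(mt))) {
        if (mt$dd1[i] / mt$dd0[i] < 1.5) { slow <- c(slow, mt$strain[i]); next }
        cut1 <- if (b == "high") 900 else 400
        lgn <- (mt$ld6[i] / mt$dd1[i]) / med
        if (mt$ld6[i] < cut1 && lgn < lg_cut) sens <- c(sens, mt$strain[i])
        if (mt$ld0[i] >= 61 && mt$ld6[i] > 1642)
          resist <- c(resist, mt$strain[i])
      }
    }
  }
  list(sensitive = sens, slow = slow, resistant = resist)
}

precision_recall <- function(called, truth_set) {
  tp <- length(intersect(called, truth_set))
  c(precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth_set)) tp / length(truth_set) else NA_real_)
}
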