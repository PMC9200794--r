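# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct-sum DFT, positional pattern scans,
# rank-statistic AUC, grid-search leaf minimization.

random_dna <- function(L, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE, prob = probs),
        collapse = "")
}

# O(L^2) direct-sum DFT power spectrum of a (possibly multi-channel) matrix.
dft_power_oracle <- function(channels) {
  channels <- as.matrix(channels)
  L <- nrow(channels)
  P <- numeric(L)
  for (f in 0:(L - 1)) {
    w <- exp(-2i * pi * f * (0:(L - 1)) / L)
    P[f + 1] <- sum(abs(colSums(channels * w))^2)
  }
  P
}

# Exhaustive positional scan: counts of every (left, gap, right) pattern of a
# family, same canonical ordering as the package (gap outer, left then right
# lexicographic).
kgap_oracle <- function(residues, a, b, n) {
  bases <- c("A", "C", "G", "T")
  L <- nchar(residues)
  words <- function(len) {
    if (len == 1) return(bases)
    do.call(paste0, expand.grid(rep(list(bases), len))[
      , rev(seq_len(len)), drop = FALSE])
  }
  lw <- words(a); rw <- words(b)
  out <- numeric(0)
  for (g in seq_len(n)) {
    counts <- matrix(0, length(lw), length(rw), dimnames = list(lw, rw))
    span <- a + g + b
    if (L >= span) {
      for (i in seq_len(L - span + 1)) {
        l <- substring(residues, i, i + a - 1)
        r <- substring(residues, i + a + g, i + span - 1)
        counts[l, r] <- counts[l, r] + 1
      }
    }
    out <- c(out, as.vector(t(counts)))  # left outer, right inner
  }
  out
}

word_count_oracle <- function(residues, K) {
  bases <- c("A", "C", "G", "T")
  out <- numeric(0)
  L <- nchar(residues)
  for (o in seq_len(K)) {
    words <- if (o == 1) bases else
      do.call(paste0, expand.grid(rep(list(bases), o))[
        , rev(seq_len(o)), drop = FALSE])
    counts <- stats::setNames(numeric(length(words)), words)
    if (L >= o)
      for (i in seq_len(L - o + 1)) {
        w <- substring(residues, i, i + o - 1)
        counts[w] <- counts[w] + 1
      }
    out <- c(out, unname(counts))
  }
  out
}

# Mann-Whitney rank-statistic AUC (ties via midranks).
auc_rank_oracle <- function(y, s) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(rank(s)[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive threshold-sweep AUPR with step interpolation.
aupr_sweep_oracle <- function(y, s) {
  thr <- sort(unique(s), decreasing = TRUE)
  prev_rec <- 0; area <- 0
  for (t in thr) {
    pred <- s >= t
    tp <- sum(pred & y == 1)
    rec <- tp / sum(y == 1)
    prec <- tp / sum(pred)
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# 1e-4 grid-search minimizer of the leaf logistic loss on [-4, 4].
leaf_grid_oracle <- function(ytilde, h) {
  grid <- seq(-4, 4, by = 1e-4)
  loss <- vapply(grid, function(v)
    sum(log1p(exp(-ytilde * (h + v)))), numeric(1))
  grid[which.min(loss)]
}

make_two_class <- function(n_pos, n_neg, seed = 1) {
  set.seed(seed)
  fasta_dataset(
    id = c(sprintf("p%03d", seq_len(n_pos)), sprintf("n%03d", seq_len(n_neg))),
    residues = replicate(n_pos + n_neg, random_dna(60)),
    label = rep(c("positive", "negative"), c(n_pos, n_neg)))
}
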