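# Independent oracles used to cross-check the implementation.

# Brute-force log-likelihood ratio for one gene: difference between the
# maximized Poisson log-likelihoods of a saturated model (one rate per
# library) and a pooled model (shared proportion f = sum(x)/sum(N)),
# evaluated term by term with dpois. Independent of r_statistic().
r_stat_bruteforce <- function(x, N) {
  f <- sum(x) / sum(N)
  ll_sat <- sum(dpois(x, lambda = x, log = TRUE))
  ll_pooled <- sum(dpois(x, lambda = N * f, log = TRUE))
  ll_sat - ll_pooled
}

# Naive average-linkage agglomeration: inter-cluster distance is the mean
# of all cross-pair distances in the ORIGINAL distance matrix, recomputed
# from scratch at every step. Returns merge heights and the member sets
# formed, for comparison against hclust-based trees.
avg_linkage_bruteforce <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  members <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- mean(dmat[clusters[[a]], clusters[[b]]])
      if (d < best_d) { best_d <- d; best <- c(a, b) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    heights <- c(heights, best_d)
    members <- c(members, list(merged))
    clusters <- c(clusters[-best], list(merged))
  }
  list(heights = heights, members = members)
}

# Extract (height, member-set) pairs from an hclust object for comparison.
hclust_merges <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    get <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- sort(c(get(hc$merge[k, 1]), get(hc$merge[k, 2])))
  }
  list(heights = hc$height, members = sets)
}

# Full dynamic-programming semi-global alignment (linear gap penalty):
# the shorter sequence is aligned end to end, end gaps on the longer are
# free. Returns identity = matches / alignment columns for the optimal
# alignment. Suited to the substitution-only / containment fixtures used
# in the tests, where linear and affine gap models share the optimum.
dp_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  s <- strsplit(a, "")[[1]]; t <- strsplit(b, "")[[1]]
  ns <- length(s); nt <- length(t)
  D <- matrix(-Inf, ns + 1, nt + 1)
  D[1, ] <- 0                      # free leading gap in the longer
  for (i in seq_len(ns)) D[i + 1, 1] <- i * gap
  for (i in seq_len(ns)) for (j in seq_len(nt)) {
    sub <- if (s[i] == t[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + sub, D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
  }
  jend <- which.max(D[ns + 1, ])   # free trailing gap in the longer
  # traceback counting matches and columns
  i <- ns; j <- jend - 1; matches <- 0; cols <- 0
  while (i > 0) {
    sub <- if (s[i] == t[j]) match else mismatch
    if (j > 0 && D[i + 1, j + 1] == D[i, j] + sub) {
      matches <- matches + (s[i] == t[j]); i <- i - 1; j <- j - 1
    } else if (D[i + 1, j + 1] == D[i, j + 1] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  matches / cols
}

# Small literal count-matrix fixture shared across tests.
toy_count_matrix <- function() {
  count_matrix(
    matrix(c(10, 5, 0, 0, 5, 0), nrow = 3,
           dimnames = list(c("g1", "g2", "g3"), c("liba", "libb"))),
    lib_sizes = c(liba = 1e5, libb = 1e5),
    gene_lengths = c(g1 = 500, g2 = 1000, g3 = 1500))
}

# Write a count matrix fixture to TSV files in a temp dir; returns paths.
write_toy_files <- function(cm, dir = withr::local_tempdir(
                              .local_envir = parent.frame())) {
  paths <- list(counts = file.path(dir, "counts.tsv"),
                lengths = file.path(dir, "lengths.tsv"),
                totals = file.path(dir, "totals.tsv"))
  write_counts(cm, paths$counts, paths$lengths, paths$totals)
  paths
}
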