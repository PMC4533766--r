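# Seeded generators for synthetic atlases, ripening trajectories, and
# sequence sets with planted redundancy; each carries ground-truth labels.

ATLAS_ORGANS <- c("seed", "root", "stem", "leaf", "aerial_bud", "flower",
                  "fruit")
RIPENING_STAGES <- c("pre_climacteric", "climacteric", "post_climacteric")

#' Generate a synthetic organ-atlas count matrix with planted categories
#'
#' Emulates the statistical structure of a seven-organ digital
#' gene-expression atlas. Each gene is assigned a category; its expected
#' read count in library j follows from per-library rates:
#' *ubiquitous* genes have rates proportional to library totals `N_j`
#' (the null of the R statistic), *preferential* genes have their target
#' library's rate elevated `preferential_fold`-fold, *organ-specific*
#' genes place all expected reads in a single library, and *silent* genes
#' have rate zero (true negatives for the expressed mask). Counts are
#' drawn independently per library as `Poisson(expected)`; with
#' `overdispersion > 0` a per-gene gamma multiplier (mean 1, variance
#' `overdispersion`) mixes the Poisson rates.
#'
#' Expected total reads per gene scale with transcript length:
#' `base_depth * L / 1000`, i.e. `base_depth` is the expected number of
#' mapped reads per kilobase of transcript summed over libraries, so a
#' planted gene's expected RPKM does not depend on its length. Gene
#' lengths are uniform on `length_range` (default 200-8600 bp) and
#' per-library totals default to uniform draws on 4.2-6.8 million mapped
#' reads. With the defaults the shortest organ-specific genes carry >= 20
#' expected reads.
#'
#' @param n_genes number of genes (default 20000).
#' @param organs library names (default: the seven-organ atlas).
#' @param library_sizes per-library mapped-read totals; drawn uniformly in
#'   `[4.2e6, 6.8e6]` when NULL.
#' @param fractions named fractions (ubiquitous, preferential,
#'   organ_specific, silent) summing to 1.
#' @param preferential_fold fold elevation of the target library for
#'   preferential genes (>= 1, default 8).
#' @param base_depth expected mapped reads per kilobase of transcript per
#'   gene, summed over libraries (default 100).
#' @param length_range gene-length range in bp (default `c(200, 8600)`).
#' @param overdispersion gamma-mixing variance; 0 (default) gives pure
#'   Poisson sampling.
#' @param seed integer RNG seed; output is a pure function of the
#'   parameters and the seed.
#' @return list with `counts` (a [count_matrix()]), `truth` (data.frame:
#'   `gene_id`, `category`, `target_library`) and `expected` (matrix of
#'   expected counts).
#' @export
gen_atlas <- function(n_genes = 20000, organs = ATLAS_ORGANS,
                      library_sizes = NULL,
                      fractions = c(ubiquitous = 0.85, preferential = 0.05,
                                    organ_specific = 0.05, silent = 0.05),
                      preferential_fold = 8, base_depth = 100,
                      length_range = c(200, 8600), overdispersion = 0,
                      seed = 1) {
  m <- length(organs)
  if (m < 2) stop("need at least 2 libraries")
  req <- c("ubiquitous", "preferential", "organ_specific", "silent")
  if (!setequal(names(fractions), req)) stop("fractions must be named ",
                                             paste(req, collapse = "/"))
  fractions <- fractions[req]
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-12)
    stop("fractions must be nonnegative and sum to 1")
  if (preferential_fold < 1) stop("preferential_fold must be >= 1")
  if (base_depth <= 0 || n_genes < 1) stop("invalid design")

  set.seed(seed)
  if (is.null(library_sizes))
    library_sizes <- round(runif(m, 4.2e6, 6.8e6))
  names(library_sizes) <- organs
  N <- library_sizes

  # exact category counts (largest-remainder partition of n_genes)
  n_cat <- diff(round(cumsum(c(0, fractions)) * n_genes))
  names(n_cat) <- req
  category <- sample(rep(req, n_cat))
  target <- ifelse(category %in% c("preferential", "organ_specific"),
                   sample(organs, n_genes, replace = TRUE), NA_character_)

  lengths <- round(runif(n_genes, length_range[1], length_range[2]))
  depth <- base_depth * lengths / 1000          # expected reads per gene
  pN <- N / sum(N)

  expected <- matrix(0, n_genes, m, dimnames = list(NULL, organs))
  ub <- category == "ubiquitous"
  expected[ub, ] <- outer(depth[ub], pN)
  pr <- category == "preferential"
  if (any(pr)) {
    w <- matrix(N, sum(pr), m, byrow = TRUE)
    ti <- cbind(seq_len(sum(pr)), match(target[pr], organs))
    w[ti] <- w[ti] * preferential_fold
    expected[pr, ] <- depth[pr] * w / rowSums(w)
  }
  sp <- category == "organ_specific"
  if (any(sp))
    expected[cbind(which(sp), match(target[sp], organs))] <- depth[sp]

  lambda <- expected
  if (overdispersion > 0) {
    mult <- rgamma(n_genes, shape = 1 / overdispersion,
                   rate = 1 / overdispersion)
    lambda <- lambda * mult
  }
  counts <- matrix(rpois(n_genes * m, lambda), n_genes, m)
  gene_ids <- sprintf("UN%05d", seq_len(n_genes))
  dimnames(counts) <- list(gene_ids, organs)
  rownames(expected) <- gene_ids

  list(counts = count_matrix(counts, N, setNames(lengths, gene_ids)),
       truth = data.frame(gene_id = gene_ids, category = category,
                          target_library = target,
                          stringsAsFactors = FALSE),
       expected = expected)
}

#' Generate ripening trajectories with planted classes
#'
#' For each of the classes I, II, III-A, III-B, IV-A and IV-B, generates
#' RPKM triples whose noiseless log2 steps match the class definition with
#' step magnitude `delta_steps`; class V genes are flat. Multiplicative
#' log-normal noise of standard deviation `noise_sd` (log2 units) is then
#' applied, so `log2(RPKM + 1)` equals the intended shape plus Gaussian
#' noise exactly.
#'
#' @param n_per_class genes per class (default 500).
#' @param delta_steps log2 step magnitude of the planted shapes; default
#'   twice the classifier's default minimal step `log2(1.5)`.
#' @param noise_sd log2-scale noise standard deviation (default 0.1).
#' @param seed integer RNG seed.
#' @return list with `stages` (genes-by-3 RPKM matrix, stage columns) and
#'   `truth` (data.frame `gene_id`, `class`).
#' @export
gen_ripening <- function(n_per_class = 500, delta_steps = 2 * log2(1.5),
                         noise_sd = 0.1, seed = 1) {
  if (n_per_class < 1 || delta_steps <= 0 || noise_sd < 0)
    stop("invalid parameters")
  set.seed(seed)
  shapes <- list("I"     = c(0, 1, 0),
                 "II"    = c(1, 0, 1),
                 "III-A" = c(0, 1, 2),
                 "III-B" = c(0, 1, 1),
                 "IV-A"  = c(2, 1, 0),
                 "IV-B"  = c(1, 0, 0),
                 "V"     = c(0, 0, 0))
  klass <- rep(names(shapes), each = n_per_class)
  n <- length(klass)
  base <- runif(n, 2, 8)
  v <- base + delta_steps * do.call(rbind, shapes[klass]) +
    rnorm(3 * n, sd = noise_sd)
  stages <- 2^v - 1
  gene_ids <- sprintf("TR%05d", seq_len(n))
  dimnames(stages) <- list(gene_ids, RIPENING_STAGES)
  list(stages = stages,
       truth = data.frame(gene_id = gene_ids,
                          class = factor(klass,
                                         levels = TRAJECTORY_CLASSES),
                          stringsAsFactors = FALSE))
}

#' Generate sequence sets with planted redundancy families
#'
#' Each family is a random parent sequence plus variants obtained by
#' per-base substitution with probability `divergence` and a light random
#' end-trim (0-2 percent per end), so family members are contained in the
#' parent at roughly `1 - divergence` identity. Singletons are unrelated
#' random sequences.
#'
#' @param n_families number of families (default 5).
#' @param family_size sequences per family including the parent
#'   (default 5).
#' @param parent_len parent length in bp (default 1000).
#' @param divergence per-base substitution probability in \\[0, 1\\]
#'   (default 0.02).
#' @param n_singletons number of unrelated sequences (default 5).
#' @param seed integer RNG seed.
#' @return list with `sequences` (a [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame `id`, `family`).
#' @export
gen_sequences <- function(n_families = 5, family_size = 5,
                          parent_len = 1000, divergence = 0.02,
                          n_singletons = 5, seed = 1) {
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  if (n_families < 0 || family_size < 1 || parent_len < 10 ||
      n_singletons < 0) stop("invalid parameters")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(len) paste(sample(bases, len, TRUE), collapse = "")
  mutate <- function(s) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < divergence
    v[hit] <- vapply(v[hit],
                     function(b) sample(setdiff(bases, b), 1), character(1))
    trim <- round(runif(2, 0, 0.02) * length(v))
    paste(v[(1 + trim[1]):(length(v) - trim[2])], collapse = "")
  }
  seqs <- character(0); ids <- character(0); fam <- character(0)
  for (i in seq_len(n_families)) {
    parent <- rand_seq(parent_len)
    members <- c(parent,
                 vapply(seq_len(family_size - 1), function(j) mutate(parent),
                        character(1)))
    seqs <- c(seqs, members)
    ids <- c(ids, sprintf("fam%d_m%d", i, seq_len(family_size)))
    fam <- c(fam, rep(sprintf("fam%d", i), family_size))
  }
  for (k in seq_len(n_singletons)) {
    seqs <- c(seqs, rand_seq(parent_len))
    ids <- c(ids, sprintf("sing%d", k))
    fam <- c(fam, sprintf("singleton%d", k))
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  list(sequences = out,
       truth = data.frame(id = ids, family = fam, stringsAsFactors = FALSE))
}

#' Generate log-expression profiles with two correlated library groups
#'
#' Builds a `log2(RPKM + 1)`-scale profile matrix in which libraries fall
#' into two planted groups (e.g. vegetative-like versus storage-like):
#' every gene has a shared baseline and a group-contrast effect, so
#' within-group correlation exceeds between-group correlation. Used to
#' check that clustering and ordination recover qualitative atlas
#' structure.
#'
#' @param n_genes number of genes (default 2000).
#' @param groups named list of two character vectors of library names.
#' @param effect_size log2 magnitude of the group contrast (default 2).
#' @param noise_sd per-cell Gaussian noise sd in log2 units (default 0.5).
#' @param seed integer RNG seed.
#' @return list with `profiles` (genes-by-libraries matrix) and `groups`.
#' @export
gen_group_profiles <- function(n_genes = 2000,
                               groups = list(
                                 vegetative = c("stem", "leaf", "aerial_bud"),
                                 storage = c("seed", "fruit")),
                               effect_size = 2, noise_sd = 0.5, seed = 1) {
  if (length(groups) != 2) stop("need exactly two library groups")
  libs <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(libs)) stop("library groups must be disjoint")
  set.seed(seed)
  base <- runif(n_genes, 2, 8)
  # half the genes up in group 1, half up in group 2
  updir <- rep(c(1, -1), length.out = n_genes)
  contrast <- ifelse(libs %in% groups[[1]], 0.5, -0.5)
  prof <- outer(base, rep(1, length(libs))) +
    effect_size * outer(updir, contrast) +
    matrix(rnorm(n_genes * length(libs), sd = noise_sd), n_genes)
  prof <- pmax(prof, 0)
  dimnames(prof) <- list(sprintf("G%05d", seq_len(n_genes)), libs)
  list(profiles = prof, groups = groups)
}

#' Generate a complete synthetic study on disk
#'
#' Produces the file set consumed by [run_atlas()]: a count matrix over
#' six organ libraries plus the three ripening-stage libraries (whole-fruit
#' counts split across stages), per-gene lengths, per-library totals, and a
#' truth table. The fruit library of a [gen_atlas()] draw is divided among
#' the stages with per-gene stage weights shaped by a planted trajectory
#' class (most genes flat), so aggregating the stage libraries reproduces
#' the fruit column exactly.
#'
#' @param dir output directory (created if needed).
#' @param n_genes number of genes (default 5000).
#' @param seed integer RNG seed.
#' @param ... further arguments passed to [gen_atlas()].
#' @return list of file paths (`counts`, `lengths`, `totals`, `truth`) and
#'   the `stage_libraries` names.
#' @export
gen_study <- function(dir, n_genes = 5000, seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  at <- gen_atlas(n_genes = n_genes, seed = seed, ...)
  cm <- at$counts
  set.seed(seed + 1L)

  # stage library sizes sum exactly to the fruit total
  w <- runif(3, 0.8, 1.2)
  n_fruit <- cm$lib_sizes[["fruit"]]
  stage_N <- floor(n_fruit * w / sum(w))
  stage_N[3] <- n_fruit - sum(stage_N[1:2])
  names(stage_N) <- RIPENING_STAGES

  # planted trajectory classes shape the per-gene stage allocation
  n <- nrow(cm$counts)
  shapes <- rbind("I" = c(0, 1, 0), "II" = c(1, 0, 1),
                  "III-A" = c(0, 1, 2), "III-B" = c(0, 1, 1),
                  "IV-A" = c(2, 1, 0), "IV-B" = c(1, 0, 0),
                  "V" = c(0, 0, 0))
  klass <- sample(rownames(shapes), n, replace = TRUE,
                  prob = c(rep(0.05, 6), 0.7))
  delta <- 2 * log2(1.5)
  wgene <- 2^(delta * shapes[klass, , drop = FALSE])   # per-read-rate weights
  p <- wgene * matrix(stage_N, n, 3, byrow = TRUE)
  fruit <- cm$counts[, "fruit"]
  stage_counts <- t(vapply(seq_len(n),
                           function(i) rmultinom(1, fruit[i], p[i, ])[, 1],
                           numeric(3)))
  colnames(stage_counts) <- RIPENING_STAGES

  organ_cols <- setdiff(colnames(cm$counts), "fruit")
  counts <- cbind(cm$counts[, organ_cols, drop = FALSE], stage_counts)
  full <- count_matrix(counts, c(cm$lib_sizes[organ_cols], stage_N),
                       cm$gene_lengths)
  truth <- at$truth
  truth$trajectory_class <- klass

  paths <- list(counts = file.path(dir, "counts.tsv"),
                lengths = file.path(dir, "lengths.tsv"),
                totals = file.path(dir, "totals.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_counts(full, paths$counts, paths$lengths, paths$totals)
  write.table(truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  c(paths, list(stage_libraries = RIPENING_STAGES))
}
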