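make_fasta <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fasta",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA reading validates and round-trips", {
  f <- make_fasta(c(">u1 some description", "ACGTacgtn", ">u2", "GGGTTT"))
  s <- read_fasta(f)
  expect_identical(names(s), c("u1", "u2"))
  expect_identical(as.character(s[["u1"]]), "ACGTACGTN")  # upper-cased

  out <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(s, out)
  s2 <- read_fasta(out)
  expect_identical(as.character(s2), as.character(s))
  expect_identical(names(s2), names(s))

  expect_error(read_fasta(make_fasta(c(">u1", "ACGT", ">u1", "GGGG"))),
               "duplicate sequence id")
  expect_error(read_fasta(make_fasta(c(">u1", "ACGT", ">u2", ""))),
               "empty sequence")
  expect_error(read_fasta(make_fasta(c(">u1", "ACRT"))), "illegal character")
  expect_error(read_fasta("no/such.fasta"), "not found")
})

test_that("pair identity and coverage handle containment and divergence", {
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  s300 <- paste(sample(bases, 300, TRUE), collapse = "")
  expect_equal(unname(pair_identity(s300, s300)),
               c(1, 1), tolerance = 1e-12)

  # exact prefix: full identity and coverage for the shorter
  expect_equal(unname(pair_identity(substr(s300, 1, 285), s300)),
               c(1, 1), tolerance = 1e-12)

  # 200-bp pair differing at 20 evenly spaced positions: identity 0.90,
  # confirmed against the independent full-DP oracle
  a <- sample(bases, 200, TRUE)
  b <- a
  idx <- seq(5, 200, by = 10)
  b[idx] <- vapply(a[idx], function(x) sample(setdiff(bases, x), 1),
                   character(1))
  pid <- pair_identity(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(unname(pid["identity"]), 0.90, tolerance = 1e-12)
  expect_equal(unname(pid["identity"]),
               dp_identity(paste(a, collapse = ""),
                           paste(b, collapse = "")),
               tolerance = 1e-12)

  # identity is symmetric for equal-length sequences
  x <- paste(sample(bases, 150, TRUE), collapse = "")
  y <- paste(sample(bases, 150, TRUE), collapse = "")
  expect_equal(pair_identity(x, y)["identity"],
               pair_identity(y, x)["identity"], tolerance = 1e-12)

  # N columns count as mismatches
  expect_lt(pair_identity("ACGTNNNNAC", "ACGTACGTAC")["identity"], 1)
  expect_error(pair_identity("", "ACGT"), "empty")
})

test_that("dedup collapses redundant pairs and keeps divergent ones", {
  set.seed(78)
  bases <- c("A", "C", "G", "T")
  s <- paste(sample(bases, 400, TRUE), collapse = "")
  same <- Biostrings::DNAStringSet(c(u1 = s, u2 = s))
  dd <- dedup(same)
  expect_equal(length(dd$kept), 1L)
  expect_identical(sort(dd$clusters[[1]]), c("u1", "u2"))

  # ~90 % identity is below the strict > 0.95 rule: both kept
  v <- strsplit(s, "")[[1]]
  idx <- seq(1, 400, by = 10)
  v[idx] <- vapply(v[idx], function(x) sample(setdiff(bases, x), 1),
                   character(1))
  pair90 <- Biostrings::DNAStringSet(c(u1 = s,
                                       u2 = paste(v, collapse = "")))
  expect_equal(length(dedup(pair90)$kept), 2L)

  expect_error(dedup(same, min_identity = 0), "\\(0, 1\\]")
  expect_error(dedup(same, min_coverage = 1.2), "\\(0, 1\\]")
})

test_that("dedup on planted families is correct, idempotent, and oracle-clean", {
  gs <- gen_sequences(n_families = 1, family_size = 6, parent_len = 1000,
                      divergence = 0.02, n_singletons = 3, seed = 5)
  dd <- dedup(gs$sequences)
  # one representative per family plus the three unrelated sequences
  expect_equal(length(dd$kept), 4L)

  # clusters partition the input
  members <- sort(unlist(dd$clusters, use.names = FALSE))
  expect_identical(members, sort(names(gs$sequences)))

  # family members all cluster together under the truth labels
  fam_ids <- gs$truth$id[gs$truth$family == "fam1"]
  fam_cluster <- dd$clusters[[which(vapply(dd$clusters,
                                           function(cl) fam_ids[1] %in% cl,
                                           logical(1)))]]
  expect_identical(sort(fam_cluster), sort(fam_ids))

  # idempotence: running dedup on the kept set changes nothing
  dd2 <- dedup(dd$kept)
  expect_identical(names(dd2$kept), names(dd$kept))

  # all-pairs oracle: no kept pair still satisfies the redundancy rule
  kept <- dd$kept
  for (i in seq_along(kept)) for (j in seq_along(kept)) {
    if (i >= j) next
    pid <- pair_identity(kept[[i]], kept[[j]])
    expect_false(pid["identity"] > 0.95 && pid["coverage"] >= 0.95)
  }
})

test_that("length filter keeps >= min_len in order; metrics match hand values", {
  s <- Biostrings::DNAStringSet(c(
    a = strrep("A", 199), b = strrep("C", 200), c = strrep("G", 1000)))
  expect_identical(names(length_filter(s)), c("b", "c"))
  expect_identical(names(length_filter(s, min_len = 1)), c("a", "b", "c"))
  expect_equal(length(length_filter(Biostrings::DNAStringSet(), 200)), 0L)
  expect_error(length_filter(s, min_len = 0), ">= 1")

  m <- assembly_metrics(Biostrings::DNAStringSet(c(
    x = strrep("A", 1000), y = strrep("C", 500), z = strrep("G", 500))))
  expect_equal(m$n_total, 3)
  expect_equal(m$n_ge_1kb, 1)
  expect_equal(m$mean_length, 2000 / 3)
  expect_equal(m$max_length, 1000)
  expect_equal(m$n50, 1000)

  single <- assembly_metrics(Biostrings::DNAStringSet(c(s1 = strrep("T", 321))))
  expect_true(all(c(single$mean_length, single$max_length,
                    single$n50) == 321))
  expect_error(assembly_metrics(Biostrings::DNAStringSet()), "empty")

  # cluster and metrics writers emit readable text
  out <- withr::local_tempfile()
  write_metrics(m, out)
  expect_true(any(grepl("n50: 1000", readLines(out))))
  cl <- withr::local_tempfile()
  write_clusters(list(rep1 = c("rep1", "m2")), cl)
  tab <- read.delim(cl)
  expect_identical(tab$member, c("rep1", "m2"))
})
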