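test_that("trajectory classification follows the class definitions", {
  cls <- function(x) as.character(classify_trajectory(x)$class)
  expect_identical(cls(c(5, 50, 5)), "I")      # climacteric peak
  expect_identical(cls(c(50, 5, 50)), "II")    # climacteric trough
  expect_identical(cls(c(1, 5, 25)), "III-A")  # continuous rise
  expect_identical(cls(c(1, 10, 10)), "III-B") # rise then plateau
  expect_identical(cls(c(25, 5, 1)), "IV-A")   # continuous fall
  expect_identical(cls(c(10, 1, 1)), "IV-B")   # fall then plateau
  expect_identical(cls(c(7, 7, 7)), "V")       # flat
  expect_error(classify_trajectory(c(-1, 2, 3)), "negative")
  expect_error(classify_trajectory(c(1, 2, 3), delta = 0), "positive")
})

test_that("classification is total and exclusive for any delta", {
  set.seed(31)
  stages <- matrix(runif(300 * 3, 0, 100), ncol = 3)
  for (delta in c(0.1, log2(1.5), 2)) {
    k <- classify_trajectory(stages, delta = delta)$class
    expect_false(any(is.na(k)))
    expect_true(all(k %in% c("I", "II", "III-A", "III-B", "IV-A", "IV-B",
                             "V")))
  }
})

test_that("stage reversal swaps III-A and IV-A and fixes I and II", {
  set.seed(32)
  stages <- matrix(runif(400 * 3, 0, 200), ncol = 3)
  k_fwd <- as.character(classify_trajectory(stages)$class)
  k_rev <- as.character(classify_trajectory(stages[, 3:1])$class)
  # a climacteric peak/trough is reversal-symmetric; continuous rise and
  # fall exchange
  swap <- c("I" = "I", "II" = "II", "III-A" = "IV-A", "IV-A" = "III-A")
  core <- k_fwd %in% names(swap)
  expect_gt(sum(k_fwd == "III-A"), 0)          # the case is exercised
  expect_identical(k_rev[core], unname(swap[k_fwd[core]]))
  # plateau sub-classes reverse into the no-change band, i.e. class V
  expect_true(all(k_rev[k_fwd %in% c("III-B", "IV-B")] == "V"))
  # reversal is an involution on the classification
  k_back <- as.character(classify_trajectory(stages[, 3:1][, 3:1])$class)
  expect_identical(k_back, k_fwd)
})

test_that("monotone triples with both steps >= delta are always III-A", {
  set.seed(33)
  delta <- log2(1.5)
  v1 <- runif(50, 0, 5)
  v2 <- v1 + delta + runif(50, 0, 3)
  v3 <- v2 + delta + runif(50, 0, 3)
  stages <- 2^cbind(v1, v2, v3) - 1
  expect_true(all(classify_trajectory(stages)$class == "III-A"))
})

test_that("average-linkage clustering matches hand cases and the brute-force oracle", {
  # identical profiles merge at height 0; anticorrelated at height 2
  prof <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(4, 3, 2, 1))
  tree <- hcluster(prof, axis = "libraries")
  hc <- tree$hclust
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  first <- sort(hc$labels[-hc$merge[1, ]])
  expect_identical(first, c("a", "b"))
  expect_equal(hc$height[2], 2, tolerance = 1e-12)

  # random profiles against the naive recompute-everything oracle
  set.seed(44)
  for (rep in 1:5) {
    m <- matrix(rnorm(6 * 10), nrow = 6)
    rownames(m) <- paste0("it", 1:6)
    dmat <- as.matrix(1 - cor(t(m)))
    got <- hclust_merges(hcluster(m, axis = "genes")$hclust)
    want <- avg_linkage_bruteforce(dmat)
    expect_equal(got$heights, want$heights, tolerance = 1e-10)
    expect_identical(got$members, want$members)
  }
})

test_that("duplicated profiles all merge at height zero first", {
  set.seed(45)
  base <- rnorm(8)
  m <- rbind(d1 = base, d2 = base, d3 = base,
             other1 = rnorm(8), other2 = rnorm(8))
  hc <- hcluster(m, axis = "genes")$hclust
  expect_true(all(hc$height[1:2] < 1e-12))
  merged3 <- hclust_merges(hc)$members[[2]]
  expect_identical(sort(rownames(m)[merged3]), c("d1", "d2", "d3"))
})

test_that("constant profiles are dropped with a warning; too few items error", {
  m <- rbind(flat = rep(3, 5), a = rnorm(5), b = rnorm(5))
  expect_warning(tree <- hcluster(m, axis = "genes"), "constant")
  expect_identical(sort(tree$labels), c("a", "b"))
  expect_error(suppressWarnings(hcluster(rbind(rep(1, 4), rnorm(4)),
                                         axis = "genes")),
               "fewer than 2")
  # newick serialization covers all leaves
  nwk <- to_newick(tree)
  expect_true(grepl("^\\(", nwk) && grepl("a", nwk) && grepl("b", nwk))
})

test_that("PCA explains all variance, reconstructs the data, separates groups", {
  set.seed(55)
  # rank-1 case: two observations, one nonzero component
  two <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("l1", "l2")))
  p2 <- atlas_pca(two)
  expect_equal(p2$explained[1], 1, tolerance = 1e-12)

  prof <- matrix(rnorm(40 * 5), ncol = 5,
                 dimnames = list(NULL, paste0("lib", 1:5)))
  p <- atlas_pca(prof)
  expect_equal(sum(p$explained), 1, tolerance = 1e-12)
  # scores %*% t(loadings) reconstructs the centered data
  recon <- p$scores %*% t(p$loadings)
  centered <- sweep(t(prof), 2, p$center)
  expect_lt(max(abs(recon - centered)), 1e-8)
  # sign convention: the largest-magnitude loading entry is positive
  for (k in seq_len(ncol(p$loadings))) {
    w <- p$loadings[, k]
    expect_gte(w[which.max(abs(w))], 0)
  }

  # an exact two-group mean shift lands the groups on opposite PC1 signs
  shift <- outer(rep(c(2, -2), each = 20), c(1, 1, -1, -1, -1) / 2)
  pg <- atlas_pca(prof / 10 + shift)
  s1 <- pg$scores[, 1]
  expect_true(all(sign(s1[1:2]) == sign(s1[1])))
  expect_true(all(sign(s1[3:5]) == -sign(s1[1])))

  expect_error(atlas_pca(matrix(1, 4, 3)), "degenerate")
})

test_that("trajectory agreement fractions behave on constructed inputs", {
  set.seed(66)
  stages <- matrix(runif(60, 0, 100), ncol = 3)
  rownames(stages) <- paste0("g", 1:20)
  a <- classify_trajectory(stages)
  expect_equal(agreement(a, a)$class_agreement, 1.0)
  expect_equal(agreement(a, a)$direction_agreement, 1.0)

  # row order must not matter: calls are matched by gene id
  b <- a[rev(seq_len(nrow(a))), ]
  expect_equal(agreement(a, b)$class_agreement, 1.0)

  # half the genes altered to a guaranteed different class
  c2 <- classify_trajectory(stages)
  flip <- 1:10
  lv <- levels(c2$class)
  c2$class[flip] <- factor(lv[(as.integer(c2$class[flip]) %% 7) + 1],
                           levels = lv)
  expect_equal(agreement(a, c2)$class_agreement, 0.5)

  expect_error(agreement(a, a[-1, ]), "mismatched gene sets")
})
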