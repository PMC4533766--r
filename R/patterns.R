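# Ripening trajectory classification (classes I-V), hierarchical clustering
# of log-expression profiles, PCA of the organ atlas, and pattern agreement.

TRAJECTORY_CLASSES <- c("I", "II", "III-A", "III-B", "IV-A", "IV-B", "V")

#' Classify three-stage ripening trajectories into classes I-V
#'
#' Each gene's RPKM triple over (pre-climacteric, climacteric,
#' post-climacteric) is transformed to `v = log2(RPKM + 1)` and the two
#' stage-to-stage steps `d1 = v2 - v1`, `d2 = v3 - v2` are compared against
#' a minimal-change step `delta`:
#'
#' * **I**: peak at the climacteric stage (`d1 >= delta`, `d2 <= -delta`)
#' * **II**: trough at the climacteric stage (`d1 <= -delta`, `d2 >= delta`)
#' * **III-A**: continuous increase (`d1 >= delta`, `d2 >= delta`)
#' * **III-B**: increase at the climacteric stage then plateau
#'   (`d1 >= delta`, `|d2| < delta`)
#' * **IV-A**: continuous decrease (`d1 <= -delta`, `d2 <= -delta`)
#' * **IV-B**: decrease at the climacteric stage then plateau
#'   (`d1 <= -delta`, `|d2| < delta`)
#' * **V**: everything else
#'
#' The rule is total and exclusive: every nonnegative triple receives
#' exactly one class for any `delta > 0`.
#'
#' @param stages numeric length-3 vector or a genes-by-3 matrix of RPKM
#'   values ordered (pre-climacteric, climacteric, post-climacteric).
#' @param delta minimal log2 change counted as a step; default
#'   `log2(1.5)`, i.e. a 1.5-fold change.
#' @return data.frame with columns `gene_id`, `rpkm_pre`, `rpkm_cli`,
#'   `rpkm_post`, `d1`, `d2`, `class` (factor with levels I..V).
#' @examples
#' classify_trajectory(c(5, 50, 5))$class    # I: climacteric peak
#' classify_trajectory(c(1, 5, 25))$class    # III-A: continuous rise
#' @export
classify_trajectory <- function(stages, delta = log2(1.5)) {
  if (is.null(dim(stages))) stages <- matrix(stages, nrow = 1)
  stages <- as.matrix(stages)
  if (ncol(stages) != 3) stop("stages must have exactly 3 columns")
  if (any(stages < 0)) stop("negative stage value")
  if (delta <= 0) stop("delta must be positive")
  v <- log2(stages + 1)
  d1 <- v[, 2] - v[, 1]
  d2 <- v[, 3] - v[, 2]
  klass <- rep("V", nrow(stages))
  up1 <- d1 >= delta
  dn1 <- d1 <= -delta
  klass[up1 & d2 <= -delta] <- "I"
  klass[up1 & d2 >= delta] <- "III-A"
  klass[up1 & abs(d2) < delta] <- "III-B"
  klass[dn1 & d2 >= delta] <- "II"
  klass[dn1 & d2 <= -delta] <- "IV-A"
  klass[dn1 & abs(d2) < delta] <- "IV-B"
  ids <- rownames(stages)
  if (is.null(ids)) ids <- paste0("gene", seq_len(nrow(stages)))
  data.frame(gene_id = ids,
             rpkm_pre = stages[, 1], rpkm_cli = stages[, 2],
             rpkm_post = stages[, 3],
             d1 = d1, d2 = d2,
             class = factor(klass, levels = TRAJECTORY_CLASSES),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with distance `1 - Pearson correlation` and
#' unweighted average linkage (UPGMA), the standard view of how organ
#' libraries (or genes) group by expression profile. Items with zero
#' variance carry no correlation signal and are dropped with a warning.
#'
#' @param profiles genes-by-libraries matrix, conventionally of
#'   `log2(RPKM + 1)` values.
#' @param axis cluster `"genes"` (rows) or `"libraries"` (columns).
#' @return An object of class `linkage_tree` wrapping the
#'   [stats::hclust()] result; see [to_newick()] for serialization.
#' @export
hcluster <- function(profiles, axis = c("genes", "libraries")) {
  axis <- match.arg(axis)
  items <- if (axis == "libraries") t(profiles) else profiles
  items <- as.matrix(items)
  keep <- apply(items, 1, function(z) stats::var(z) > 0)
  if (any(!keep))
    warning(sum(!keep), " constant profile(s) dropped from clustering: ",
            paste(utils::head(rownames(items)[!keep], 5), collapse = ", "))
  items <- items[keep, , drop = FALSE]
  if (nrow(items) < 2) stop("fewer than 2 clusterable items")
  d <- as.dist(1 - cor(t(items)))
  hc <- hclust(d, method = "average")
  structure(list(hclust = hc, labels = hc$labels,
                 axis = axis, n_dropped = sum(!keep)),
            class = "linkage_tree")
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("linkage_tree (average linkage, 1 - Pearson):",
      length(x$labels), x$axis, "\n")
  invisible(x)
}

#' Serialize a linkage tree to Newick
#'
#' Converts the dendrogram to a phylogeny with [ape::as.phylo()]
#' (ultrametric: leaf-to-node depth equals half the merge height) and
#' writes Newick text.
#'
#' @param tree a [hcluster()] result.
#' @param path optional output file; when omitted the Newick string is
#'   returned.
#' @export
to_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "linkage_tree"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(tree)
}

#' Principal component analysis of the organ atlas
#'
#' Column-centered PCA with libraries as observations (rows of `t(profiles)`)
#' and genes as variables. For determinism across linear-algebra backends,
#' each loading vector is oriented so that its largest-magnitude element is
#' positive. Explained-variance fractions sum to one, and scores times
#' transposed loadings reconstruct the centered data.
#'
#' @param profiles genes-by-libraries matrix, conventionally
#'   `log2(RPKM + 1)`.
#' @return list with `scores` (libraries x components), `loadings`
#'   (genes x components), `explained` (variance fractions), `center`.
#' @export
atlas_pca <- function(profiles) {
  x <- t(as.matrix(profiles))
  if (nrow(x) < 2) stop("need at least 2 observations (libraries)")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  if (sum(p$sdev^2) == 0) stop("degenerate all-constant input")
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    w <- p$rotation[, k]
    sign(w[which.max(abs(w))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(p$x, 2, flip, "*")
  loadings <- sweep(p$rotation, 2, flip, "*")
  list(scores = scores, loadings = loadings,
       explained = p$sdev^2 / sum(p$sdev^2), center = p$center)
}

#' Agreement between two sets of trajectory calls
#'
#' Compares two classifications of the same genes (e.g. sequencing-derived
#' versus an independent assay): the fraction with identical class and the
#' fraction whose step-direction patterns `(sign(d1), sign(d2))` match.
#'
#' @param traj_a,traj_b [classify_trajectory()] results over the same gene
#'   set.
#' @return list with `class_agreement` and `direction_agreement`
#'   fractions.
#' @export
agreement <- function(traj_a, traj_b) {
  if (!setequal(traj_a$gene_id, traj_b$gene_id) ||
      nrow(traj_a) != nrow(traj_b))
    stop("mismatched gene sets")
  b <- traj_b[match(traj_a$gene_id, traj_b$gene_id), ]
  list(
    class_agreement = mean(as.character(traj_a$class) ==
                             as.character(b$class)),
    direction_agreement = mean(sign(traj_a$d1) == sign(b$d1) &
                                 sign(traj_a$d2) == sign(b$d2))
  )
}
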