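# Count-matrix container, TSV I/O, library aggregation, RPKM normalization.

#' Construct a validated count matrix
#'
#' Bundles a genes-by-libraries matrix of mapped-read counts with the
#' per-library totals of mapped reads (`lib_sizes`, the RPKM denominators)
#' and per-gene transcript lengths in bp. Library totals are totals of reads
#' mapped to the unigene set, not raw sequenced reads; column sums of the
#' matrix may fall short of them (multi/ambiguously mapping reads) but can
#' never exceed them.
#'
#' @param counts numeric matrix of nonnegative integer counts; rownames are
#'   gene ids, colnames are library names.
#' @param lib_sizes numeric vector of per-library mapped-read totals, named
#'   by library or in column order.
#' @param gene_lengths numeric vector of per-gene lengths (bp), named by
#'   gene or in row order.
#' @return An object of class `count_matrix`: a list with elements
#'   `counts`, `lib_sizes`, `gene_lengths`.
#' @examples
#' cm <- count_matrix(
#'   matrix(c(10, 5, 0, 0, 5, 0), nrow = 3,
#'          dimnames = list(c("g1", "g2", "g3"), c("root", "flower"))),
#'   lib_sizes = c(root = 1e6, flower = 1e6),
#'   gene_lengths = c(g1 = 500, g2 = 1000, g3 = 1500)
#' )
#' rpkm(cm)
#' @export
count_matrix <- function(counts, lib_sizes, gene_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and library names as colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate library name")
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numbers")
  if (any(counts < 0))
    stop("negative count")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer count")
  counts <- round(counts)

  lib_sizes <- .align_named(lib_sizes, colnames(counts), "lib_sizes")
  if (any(lib_sizes < 1))
    stop("total_mapped_reads must be >= 1 for every library")
  gene_lengths <- .align_named(gene_lengths, rownames(counts), "gene_lengths")
  if (any(gene_lengths < 1))
    stop("gene lengths must be >= 1 bp")

  cs <- colSums(counts)
  bad <- cs > lib_sizes
  if (any(bad))
    stop("column sum exceeds declared mapped-read total for library: ",
         paste(colnames(counts)[bad], collapse = ", "))

  structure(list(counts = counts, lib_sizes = lib_sizes,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

# match a possibly-named vector against reference names, preserving ref order
.align_named <- function(x, ref, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(ref, names(x))
    if (length(missing))
      stop("missing ", what, " entry for: ", paste(missing, collapse = ", "))
    x <- x[ref]
  } else {
    if (length(x) != length(ref))
      stop(what, " has length ", length(x), ", expected ", length(ref))
    names(x) <- ref
  }
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numbers")
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "libraries\n")
  cat("libraries:", paste(colnames(x$counts), collapse = ", "), "\n")
  cat("mapped-read totals:",
      paste(format(x$lib_sizes, big.mark = ","), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix, gene lengths and library totals from TSV files
#'
#' The count file has a header row `gene_id<TAB>lib1<TAB>...` and one gene
#' per row with integer cells; the lengths file maps `gene_id<TAB>length_bp`;
#' the totals file maps `library<TAB>mapped_reads`. Row and column order of
#' the count file is preserved (no re-sorting), so downstream clustering
#' input is reproducible.
#'
#' @param path count-matrix TSV.
#' @param lengths_path gene-length TSV.
#' @param totals_path per-library mapped-read totals TSV.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, lengths_path, totals_path) {
  for (f in c(path, lengths_path, totals_path))
    if (!file.exists(f)) stop("input file not found: ", f)
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("count file needs a gene_id column and >= 1 library")
  gene_ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric count cell in ", path)
  rownames(counts) <- gene_ids

  len <- read.delim(lengths_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  lengths <- setNames(as.numeric(len[[2]]), as.character(len[[1]]))
  tot <- read.delim(totals_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  totals <- setNames(as.numeric(tot[[2]]), as.character(tot[[1]]))

  missing_len <- setdiff(gene_ids, names(lengths))
  if (length(missing_len))
    stop("gene present in counts but absent from lengths: ",
         paste(utils::head(missing_len, 5), collapse = ", "))
  count_matrix(counts, totals, lengths[gene_ids])
}

#' Write a count matrix (plus lengths and totals) to TSV files
#'
#' Inverse of [read_counts()]; integer matrices round-trip bit-identically.
#'
#' @param cm a [count_matrix()].
#' @inheritParams read_counts
#' @export
write_counts <- function(cm, path, lengths_path, totals_path) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(cm$gene_lengths),
                         length_bp = as.integer(cm$gene_lengths)),
              lengths_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(library = names(cm$lib_sizes),
                         mapped_reads = format(cm$lib_sizes, scientific = FALSE,
                                               trim = TRUE)),
              totals_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cm)
}

#' Aggregate a group of libraries into one
#'
#' Replaces the grouped columns with a single column whose counts are the
#' elementwise sum and whose mapped-read total is the sum of totals, as when
#' whole-fruit expression is taken as the total of the reads of the
#' pre-climacteric, climacteric and post-climacteric stage libraries. The
#' aggregate takes the position of the first grouped column; other columns
#' are untouched. Total counts and total library sizes are conserved.
#'
#' @param cm a [count_matrix()].
#' @param group character vector of library names to merge.
#' @param new_name name for the merged library.
#' @return A [count_matrix()] with `ncol - length(group) + 1` libraries.
#' @export
aggregate_libraries <- function(cm, group, new_name) {
  stopifnot(inherits(cm, "count_matrix"))
  libs <- colnames(cm$counts)
  unknown <- setdiff(group, libs)
  if (length(unknown))
    stop("unknown library name: ", paste(unknown, collapse = ", "))
  keep <- setdiff(libs, group)
  if (new_name %in% keep)
    stop("new_name '", new_name, "' collides with a retained library")
  idx <- match(group, libs)
  merged <- rowSums(cm$counts[, idx, drop = FALSE])
  # aggregate takes the position of the first grouped column
  new_order <- libs
  new_order[min(idx)] <- new_name
  new_order <- new_order[!(new_order %in% group)]
  counts <- cbind(cm$counts[, keep, drop = FALSE],
                  matrix(merged, ncol = 1, dimnames = list(NULL, new_name)))
  sizes <- c(cm$lib_sizes[keep], setNames(sum(cm$lib_sizes[group]), new_name))
  count_matrix(counts[, new_order, drop = FALSE], sizes[new_order],
               cm$gene_lengths)
}

# internal: keep only the named libraries (order as given)
subset_libraries <- function(cm, libs) {
  unknown <- setdiff(libs, colnames(cm$counts))
  if (length(unknown))
    stop("unknown library name: ", paste(unknown, collapse = ", "))
  count_matrix(cm$counts[, libs, drop = FALSE], cm$lib_sizes[libs],
               cm$gene_lengths)
}

#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `RPKM_ij = 1e9 * c_ij / (N_j * L_i)` with `N_j` the library's mapped-read
#' total and `L_i` the gene length in bp. Zero counts map to exactly zero;
#' no pseudocount is added at this stage (pseudocounts appear only in the
#' log transform used for clustering and trajectory classification).
#'
#' @param cm a [count_matrix()].
#' @return An object of class `rpkm_matrix`: list with `values` (matrix of
#'   RPKM), `lib_sizes` and `gene_lengths`.
#' @examples
#' # 100 reads on a 2 kb transcript in a 5e6-read library -> RPKM 10
#' cm <- count_matrix(matrix(100, 1, 1, dimnames = list("g", "lib")),
#'                    5e6, 2000)
#' rpkm(cm)$values
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  v <- 1e9 * sweep(cm$counts, 2, cm$lib_sizes, "/") / cm$gene_lengths
  structure(list(values = v, lib_sizes = cm$lib_sizes,
                 gene_lengths = cm$gene_lengths),
            class = "rpkm_matrix")
}

#' @export
print.rpkm_matrix <- function(x, ...) {
  cat("rpkm_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "libraries\n")
  invisible(x)
}

#' Write an RPKM matrix as TSV
#'
#' @param rm an [rpkm()] result.
#' @param path output TSV path; values are written with at least six
#'   significant digits.
#' @export
write_rpkm <- function(rm, path) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  tab <- data.frame(gene_id = rownames(rm$values),
                    signif(rm$values, 10), check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rm)
}

#' Expressed-gene mask
#'
#' A gene is called expressed when its RPKM reaches `threshold` in at least
#' one library, separating expressed genes from background.
#'
#' @param rm an [rpkm()] result.
#' @param threshold nonnegative RPKM cutoff (default 5).
#' @return Named logical vector over genes.
#' @export
expressed_mask <- function(rm, threshold = 5) {
  stopifnot(inherits(rm, "rpkm_matrix"))
  if (threshold < 0) stop("threshold must be nonnegative")
  apply(rm$values, 1, max) >= threshold
}
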