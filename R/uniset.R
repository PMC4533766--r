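# Unigene-set construction: FASTA I/O, pairwise identity/coverage,
# redundancy elimination (95/95 rule), length filtering, assembly metrics.

#' Read a DNA FASTA file into a validated sequence set
#'
#' Sequence ids are the first whitespace-delimited token of each header.
#' Sequences are stored upper-case and restricted to the alphabet
#' `A, C, G, T, N`; duplicate ids, empty sequences and other characters are
#' rejected.
#'
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] with unique names.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  validate_sequences(x)
}

# shared validation for read and generated sequence sets
validate_sequences <- function(x) {
  if (length(x) == 0) return(x)
  if (anyDuplicated(names(x)))
    stop("duplicate sequence id: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  if (any(Biostrings::width(x) == 0)) stop("empty sequence")
  chr <- toupper(as.character(x))
  if (any(grepl("[^ACGTN]", chr)))
    stop("illegal character in sequence (alphabet is A/C/G/T/N)")
  out <- Biostrings::DNAStringSet(chr)
  names(out) <- names(x)
  out
}

#' Write a sequence set as FASTA
#'
#' Lines are wrapped at 80 columns; a [read_fasta()] round-trip preserves
#' ids, order and sequence content.
#'
#' @param x a [Biostrings::DNAStringSet].
#' @param path output file.
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(x)
}

#' Pairwise identity and coverage of two contigs
#'
#' Semi-globally aligns the shorter sequence against the longer (the
#' shorter is aligned end-to-end; end gaps on the longer are free), the
#' containment geometry relevant for redundancy between assembled contigs.
#' Identity is matching columns over all alignment columns, with any column
#' involving `N` counted as a mismatch (conservative). Coverage is the
#' aligned span of the shorter sequence over its length.
#'
#' @param a,b DNA sequences (character or [Biostrings::DNAString]).
#' @return Named numeric vector `c(identity =, coverage =)`.
#' @examples
#' pair_identity("ACGTACGT", "ACGTACGT")       # identity 1, coverage 1
#' @export
pair_identity <- function(a, b) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty input sequence")
  # canonical argument order keeps the result symmetric for equal lengths
  if (nchar(a) < nchar(b) || (nchar(a) == nchar(b) && a <= b)) {
    shorter <- a; longer <- b
  } else { shorter <- b; longer <- a }
  aln <- Biostrings::pairwiseAlignment(
    pattern = shorter, subject = longer, type = "global-local",
    substitutionMatrix = .nuc_score_matrix(),
    gapOpening = 5, gapExtension = 2)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  plain <- c("A", "C", "G", "T")
  matches <- sum(pa == sa & pa %in% plain)
  c(identity = matches / length(pa),
    coverage = sum(pa != "-") / nchar(shorter))
}

.nuc_score_matrix <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5, 5, dimnames = list(b, b))
  diag(m) <- 1
  m["N", "N"] <- -1   # N never counts as a match
  m
}

#' Eliminate redundant sequences (greedy longest-first clustering)
#'
#' Implements the redundancy rule for unigene-set construction: a sequence
#' is redundant when it has identity greater than `min_identity` over a
#' region covering at least `min_coverage` of the (shorter) sequence
#' length. Sequences are visited longest-first (ties keep input order);
#' each joins the cluster of the first kept representative it is redundant
#' with, otherwise it becomes a new representative. The result is
#' idempotent, and no kept pair satisfies the redundancy rule.
#'
#' @param x a [Biostrings::DNAStringSet].
#' @param min_identity redundancy identity threshold in (0, 1], exceeded
#'   strictly (default 0.95).
#' @param min_coverage minimum aligned fraction of the shorter sequence in
#'   (0, 1] (default 0.95).
#' @return list with `kept` (representatives, length order) and `clusters`
#'   (named list: representative -> member ids, representative included).
#' @export
dedup <- function(x, min_identity = 0.95, min_coverage = 0.95) {
  x <- validate_sequences(x)
  for (th in c(min_identity, min_coverage))
    if (th <= 0 || th > 1) stop("thresholds must lie in (0, 1]")
  ord <- order(-Biostrings::width(x))          # stable: ties keep input order
  reps <- character(0)
  clusters <- list()
  for (i in ord) {
    id <- names(x)[i]
    joined <- FALSE
    for (r in reps) {
      pid <- pair_identity(x[[id]], x[[r]])
      if (pid["identity"] > min_identity && pid["coverage"] >= min_coverage) {
        clusters[[r]] <- c(clusters[[r]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      clusters[[id]] <- id
    }
  }
  list(kept = x[reps], clusters = clusters)
}

#' Write redundancy clusters as TSV
#'
#' One `representative<TAB>member` row per sequence.
#'
#' @param clusters the `clusters` element of a [dedup()] result.
#' @param path output TSV.
#' @export
write_clusters <- function(clusters, path) {
  tab <- data.frame(
    representative = rep(names(clusters), lengths(clusters)),
    member = unlist(clusters, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(clusters)
}

#' Filter sequences by minimum length
#'
#' @param x a [Biostrings::DNAStringSet].
#' @param min_len minimum length in bp kept (default 200).
#' @return The subset with `width >= min_len`, order preserved.
#' @export
length_filter <- function(x, min_len = 200) {
  if (min_len < 1) stop("min_len must be >= 1")
  x[Biostrings::width(x) >= min_len]
}

#' Assembly summary metrics
#'
#' The standard metrics used to compare assemblies: sequence count, number
#' of contigs of at least 1 kb, mean and maximum length, and N50 (the
#' length at which the cumulative length of sequences sorted descending
#' first reaches half the total).
#'
#' @param x a non-empty [Biostrings::DNAStringSet].
#' @return list `n_total`, `n_ge_1kb`, `mean_length`, `max_length`, `n50`.
#' @export
assembly_metrics <- function(x) {
  if (length(x) == 0) stop("empty sequence set")
  w <- sort(Biostrings::width(x), decreasing = TRUE)
  list(n_total = length(w),
       n_ge_1kb = sum(w >= 1000),
       mean_length = mean(w),
       max_length = max(w),
       n50 = w[which(cumsum(w) >= sum(w) / 2)[1]])
}

#' Write assembly metrics as a key:value report and JSON
#'
#' @param metrics an [assembly_metrics()] result.
#' @param path text report path; a sibling `.json` file is written too.
#' @export
write_metrics <- function(metrics, path) {
  writeLines(paste0(names(metrics), ": ",
                    vapply(metrics, format, character(1))), path)
  jsonlite::write_json(metrics, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(metrics)
}
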