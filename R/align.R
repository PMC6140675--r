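# Optimal local protein alignment with Karlin-Altschul statistics: the
# in-house stand-in for blastp. No heuristic seeding; every query-subject
# pair is aligned exhaustively, which is exact and fast enough at the
# database sizes this pipeline targets.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.blosum62_x <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[.AA20, .AA20]
  # X (unknown residue, e.g. from N-containing codons) scores the matrix
  # minimum against everything, so it can never drive a hit
  m <- rbind(cbind(m, X = min(m)), X = min(m))
  m["X", ] <- min(m); m[, "X"] <- min(m)
  m
}

#' Protein scoring scheme
#'
#' Bundles a substitution matrix, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw alignment scores into
#' bitscores. The defaults are the blastp gapped defaults: BLOSUM62, gap
#' open 11, gap extend 1, lambda = 0.267 nats per score unit, K = 0.041.
#'
#' @param matrix `"BLOSUM62"` or a symmetric numeric matrix with amino-acid
#'   dimnames (an `X` row/column is added if absent, scoring the matrix
#'   minimum).
#' @param gap_open,gap_extend Positive gap penalties; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param lambda,K Karlin-Altschul parameters (both positive).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  if (is.character(matrix)) {
    if (!identical(toupper(matrix), "BLOSUM62"))
      stop("only BLOSUM62 is built in; pass a matrix for anything else")
    matrix <- .blosum62_x()
  } else {
    stopifnot(is.matrix(matrix), isSymmetric(unname(matrix)))
    if (!"X" %in% rownames(matrix)) {
      matrix <- rbind(cbind(matrix, X = min(matrix)), X = min(matrix))
      matrix["X", "X"] <- min(matrix)
    }
  }
  stopifnot(gap_open > 0, gap_extend > 0, lambda > 0, K > 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "Scoring scheme: %dx%d matrix, gap open %g / extend %g, lambda %g, K %g\n",
    nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend, x$lambda, x$K))
  invisible(x)
}

.encode_aa <- function(seq, scheme) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, rownames(scheme$matrix))
  if (anyNA(idx))
    stop("sequence contains residues outside the scoring matrix: ",
         paste(unique(chars[is.na(idx)]), collapse = ", "))
  idx - 1L
}

#' Smith-Waterman local alignment
#'
#' Maximal-scoring local alignment under affine gap penalties (Gotoh
#' algorithm) with a deterministic traceback (diagonal preferred over up
#' over left on ties). A pair with no positively scoring alignment returns
#' a hit with raw score 0 and an empty alignment.
#'
#' @param query,subject Non-empty peptide strings over the 20 standard
#'   residues plus `X`.
#' @param scheme A [scoring_scheme()].
#' @param query_id,subject_id Identifiers carried into the hit.
#' @return An `alignment_hit`: list with `query_id`, `subject_id`,
#'   `raw_score`, `bitscore`, `pct_identity`, `match_length`, `query_span`
#'   and `subject_span` (0-based half-open), and the gapped `aligned_query` /
#'   `aligned_subject` strings. `evalue` is `NA` until a database size is
#'   known (see [evalue()] and [query_db()]).
#' @export
#' @examples
#' s <- scoring_scheme()
#' smith_waterman("HEAGAWGHEE", "PAWHEAE", s)
smith_waterman <- function(query, subject, scheme = scoring_scheme(),
                           query_id = "query", subject_id = "subject") {
  stopifnot(is.character(query), is.character(subject))
  if (nchar(query) == 0L || nchar(subject) == 0L)
    stop("query and subject must be non-empty")
  qi <- .encode_aa(query, scheme)
  si <- .encode_aa(subject, scheme)
  res <- .sw_align_cpp(qi, si, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend)
  resn <- rownames(scheme$matrix)
  gapped <- function(v) paste(ifelse(v < 0, "-", resn[v + 1L]), collapse = "")
  aq <- gapped(res$q_aln); as_ <- gapped(res$s_aln)
  hit <- list(query_id = query_id, subject_id = subject_id,
              raw_score = res$score,
              bitscore = bitscore(res$score, scheme),
              evalue = NA_real_,
              pct_identity = if (nchar(aq)) percent_identity(aq, as_) else NA_real_,
              match_length = nchar(aq),
              query_span = c(res$q_start, res$q_end),
              subject_span = c(res$s_start, res$s_end),
              aligned_query = aq, aligned_subject = as_)
  structure(hit, class = "alignment_hit")
}

#' @export
print.alignment_hit <- function(x, ...) {
  cat(sprintf("%s vs %s: raw %g, bits %.1f, id %.1f%% over %d cols%s\n",
              x$query_id, x$subject_id, x$raw_score, x$bitscore,
              x$pct_identity, x$match_length,
              if (is.na(x$evalue)) "" else sprintf(", E = %.2g", x$evalue)))
  if (x$match_length > 0) {
    cat(" ", x$aligned_query, "\n ", x$aligned_subject, "\n", sep = "")
  }
  invisible(x)
}

#' Bitscore from a raw alignment score
#'
#' `S' = (lambda * S - ln K) / ln 2`. Bitscores are comparable across
#' databases of different sizes, which is why the reciprocal screen compares
#' them rather than E-values.
#'
#' @param raw_score Raw score in substitution-matrix units (>= 0).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return Bitscore in bits.
#' @export
bitscore <- function(raw_score, scheme = scoring_scheme()) {
  stopifnot(all(raw_score >= 0))
  (scheme$lambda * raw_score - log(scheme$K)) / log(2)
}

#' E-value of a bitscore in a database search
#'
#' `E = m * n * 2^(-S')` with `m` the query length and `n` the total residue
#' count of the searched database. No edge-length or composition correction
#' is applied, so values track but do not exactly reproduce NCBI BLAST.
#'
#' @param bits Bitscore.
#' @param query_len Query length in residues (> 0).
#' @param db_residues Total residues in the database (> 0).
#' @return Expected number of chance hits at this score or better.
#' @export
evalue <- function(bits, query_len, db_residues) {
  stopifnot(query_len > 0, db_residues > 0)
  query_len * db_residues * 2^(-bits)
}

#' Percent identity of a gapped alignment
#'
#' 100 times the number of identical columns over all alignment columns,
#' gap columns included in the denominator.
#'
#' @param aligned_query,aligned_subject Equal-length gapped strings, or pass
#'   an `alignment_hit` as the first argument.
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' percent_identity("MK-T", "MKAT")  # 75
percent_identity <- function(aligned_query, aligned_subject) {
  if (inherits(aligned_query, "alignment_hit")) {
    h <- aligned_query
    aligned_query <- h$aligned_query
    aligned_subject <- h$aligned_subject
  }
  if (nchar(aligned_query) != nchar(aligned_subject))
    stop("aligned strings must have equal length")
  a <- strsplit(aligned_query, "", fixed = TRUE)[[1]]
  b <- strsplit(aligned_subject, "", fixed = TRUE)[[1]]
  100 * sum(a == b & a != "-") / length(a)
}
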