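# ORF prediction from assembled transcripts.
#
# Purely structural ORF calling (no coding-likelihood scoring): six-frame
# translation under the standard genetic code, ATG starts, with completeness
# classes mirroring Transdecoder's complete / 5'-partial / 3'-partial /
# internal vocabulary. "Mature" downstream means completeness == "complete"
# (start and stop codon both present).

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement a nucleotide string
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @return The reverse complement.
#' @export
revcomp <- function(seq) {
  .check_nt(seq)
  if (nchar(seq) == 0L) return("")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  paste(rev(unname(.COMPLEMENT[chars])), collapse = "")
}

.check_nt <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains characters outside {A,C,G,T,N}")
  invisible(seq)
}

#' Translate a nucleotide sequence
#'
#' Standard genetic code (translation table 1). Codons containing `N`
#' translate to `X`; a trailing partial codon is dropped. Stop codons are
#' rendered as `*`.
#'
#' @param seq Nucleotide string over `{A,C,G,T,N}`.
#' @param strand `"+"` or `"-"`; `"-"` translates the reverse complement.
#' @param frame Frame offset 0, 1 or 2 on the chosen strand.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_dna("ATGAAATTTTAT")  # "MKFY"
translate_dna <- function(seq, strand = "+", frame = 0L) {
  .check_nt(seq)
  stopifnot(strand %in% c("+", "-"), frame %in% 0:2)
  if (strand == "-") seq <- revcomp(seq)
  seq <- substr(seq, frame + 1L, nchar(seq))
  n_codon <- nchar(seq) %/% 3L
  if (n_codon == 0L) return("")
  starts <- seq_len(n_codon) * 3L - 2L
  codons <- substring(seq, starts, starts + 2L)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # any codon containing N
  paste(aa, collapse = "")
}

#' Predict open reading frames
#'
#' Scans both strands and all three frames of a transcript. Within each
#' frame, a complete ORF runs from the first ATG of a stop-delimited segment
#' to that stop; segments touching a frame end without the corresponding
#' start or stop are reported as `five_prime_partial`, `three_prime_partial`
#' or `internal`. Peptides shorter than `min_len` amino acids are dropped
#' (default 5, low enough to catch short luciferin-precursor peptides).
#'
#' Coordinates are 0-based half-open nucleotide offsets on the reported
#' strand (i.e. on the reverse complement for `-` ORFs) and include the stop
#' codon when one is present.
#'
#' @param id Transcript identifier.
#' @param seq Transcript nucleotide string over `{A,C,G,T,N}`.
#' @param min_len Minimum peptide length in amino acids (>= 1).
#' @param cluster_id Optional read-cluster label carried through to the
#'   output.
#' @return Data frame with columns `transcript_id`, `cluster_id`, `start`,
#'   `end`, `strand`, `frame`, `peptide`, `completeness`, ordered by strand
#'   (`+` first) then start coordinate.
#' @export
#' @examples
#' find_orfs("t1", "ATGGCTGCTGCTGCTTAA")  # one complete 5-aa ORF "MAAAA"
find_orfs <- function(id, seq, min_len = 5L, cluster_id = NA_character_) {
  .check_nt(seq)
  stopifnot(nchar(seq) > 0L, min_len >= 1L)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      pep <- translate_dna(s, "+", frame)
      n_aa <- nchar(pep)
      if (n_aa == 0L) next
      aa <- strsplit(pep, "", fixed = TRUE)[[1]]
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)         # codon index where segment begins
      seg_stop <- c(stops, NA_integer_)      # codon index of terminating stop
      for (k in seq_along(seg_start)) {
        a <- seg_start[k]; z <- seg_stop[k]
        seg_end <- if (is.na(z)) n_aa else z - 1L   # last coding codon
        if (seg_end < a) next
        seg_aa <- aa[a:seg_end]
        m_rel <- match("M", seg_aa)
        has_stop <- !is.na(z)
        at_5p <- a == 1L
        if (has_stop) {
          if (!is.na(m_rel)) {
            first <- a + m_rel - 1L; completeness <- "complete"
          } else if (at_5p) {
            first <- a; completeness <- "five_prime_partial"
          } else next
          last_nt <- z * 3L                  # stop codon included
        } else {
          if (!is.na(m_rel)) {
            first <- a + m_rel - 1L; completeness <- "three_prime_partial"
          } else if (at_5p) {
            first <- a; completeness <- "internal"
          } else next
          last_nt <- seg_end * 3L
        }
        pep_out <- paste(aa[first:seg_end], collapse = "")
        if (nchar(pep_out) < min_len) next
        rows[[length(rows) + 1L]] <- data.frame(
          transcript_id = id, cluster_id = cluster_id,
          start = frame + (first - 1L) * 3L, end = frame + last_nt,
          strand = strand, frame = frame, peptide = pep_out,
          completeness = completeness, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(transcript_id = character(), cluster_id = character(),
                      start = integer(), end = integer(), strand = character(),
                      frame = integer(), peptide = character(),
                      completeness = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$strand, c("+", "-")), out$start, out$frame), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict ORFs for a set of transcripts
#'
#' @param transcripts Data frame with columns `id`, `seq` and optionally
#'   `cluster_id`, or a named character vector of sequences.
#' @param min_len Minimum peptide length in amino acids.
#' @return Combined ORF data frame (see [find_orfs()]).
#' @export
find_orfs_all <- function(transcripts, min_len = 5L) {
  transcripts <- as_transcripts(transcripts)
  out <- lapply(seq_len(nrow(transcripts)), function(i)
    find_orfs(transcripts$id[i], transcripts$seq[i], min_len,
              transcripts$cluster_id[i]))
  res <- do.call(rbind, out)
  if (is.null(res)) find_orfs("x", "AAA", min_len)[0, ] else res
}

#' Coerce transcripts to the canonical data frame
#'
#' @param x Data frame with `id`/`seq` (+ optional `cluster_id`), or a named
#'   character vector of nucleotide sequences.
#' @return Data frame with columns `id`, `seq`, `cluster_id`.
#' @export
as_transcripts <- function(x) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("transcript vector must be named by id")
    x <- data.frame(id = names(x), seq = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq") %in% names(x)))
  if (anyDuplicated(x$id)) stop("transcript ids must be unique")
  if (any(nchar(x$seq) == 0L)) stop("transcript sequences must be non-empty")
  if (is.null(x$cluster_id)) x$cluster_id <- NA_character_
  x <- x[c("id", "seq", "cluster_id")]
  rownames(x) <- NULL
  x
}

#' Read transcripts from a FASTA file
#'
#' Headers of the form `id cluster=<label>` populate `cluster_id`.
#'
#' @param path FASTA file of nucleotide sequences.
#' @return Transcript data frame (see [as_transcripts()]).
#' @export
read_transcripts <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  cl <- ifelse(grepl("cluster=", headers),
               sub("^.*cluster=(\\S+).*$", "\\1", headers), NA_character_)
  as_transcripts(data.frame(id = unname(ids), seq = unname(as.character(x)),
                            cluster_id = unname(cl), stringsAsFactors = FALSE))
}

#' Write transcripts to FASTA
#'
#' @param transcripts Transcript data frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcripts <- function(transcripts, path) {
  transcripts <- as_transcripts(transcripts)
  x <- Biostrings::DNAStringSet(transcripts$seq)
  names(x) <- ifelse(is.na(transcripts$cluster_id), transcripts$id,
                     paste0(transcripts$id, " cluster=", transcripts$cluster_id))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Single longest ORF per read cluster
#'
#' Keeps, for each distinct cluster label, the ORF with the longest peptide;
#' ties are broken by lexicographically smallest transcript id, then smallest
#' start coordinate.
#'
#' @param orfs ORF data frame (see [find_orfs()]); every row must carry a
#'   non-missing `cluster_id`.
#' @return ORF data frame with exactly one row per cluster.
#' @export
longest_per_cluster <- function(orfs) {
  if (nrow(orfs) == 0L) return(orfs)
  if (any(is.na(orfs$cluster_id)))
    stop("every ORF must have a cluster_id")
  ord <- order(orfs$cluster_id, -nchar(orfs$peptide), orfs$transcript_id,
               orfs$start)
  orfs <- orfs[ord, , drop = FALSE]
  out <- orfs[!duplicated(orfs$cluster_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write predicted peptides to FASTA
#'
#' Headers follow `<transcript_id>|<start>-<end>|<strand><frame>|<completeness>`.
#'
#' @param orfs ORF data frame.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path) {
  x <- Biostrings::AAStringSet(orfs$peptide)
  names(x) <- orf_id(orfs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Canonical ORF identifiers
#'
#' @param orfs ORF data frame.
#' @return Character vector `<transcript_id>|<start>-<end>|<strand><frame>|<completeness>`.
#' @export
orf_id <- function(orfs) {
  sprintf("%s|%d-%d|%s%d|%s", orfs$transcript_id, orfs$start, orfs$end,
          orfs$strand, orfs$frame, orfs$completeness)
}
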