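# C-terminal FYY screen. Coelenterazine is hypothesised to arise by
# cyclization of a Phe-Tyr-Tyr tripeptide, so complete ("mature": start and
# stop codon both present) predicted proteins ending in exactly F,Y,Y are
# putative luciferin-precursor candidates. Matching is literal and
# case-insensitive; no substitutions are tolerated.

#' Is an ORF mature?
#'
#' A mature ORF is one predicted with both a start and a stop codon, i.e.
#' completeness class `"complete"`.
#'
#' @param orfs ORF data frame (see [find_orfs()]).
#' @return Logical vector, one element per ORF.
#' @export
is_mature <- function(orfs) {
  orfs$completeness == "complete"
}

#' C-terminal FYY candidates among predicted ORFs
#'
#' Returns exactly those mature ORFs whose final three residues (immediately
#' preceding the stop codon) are F, Y, Y in order.
#'
#' @param orfs ORF data frame (see [find_orfs()]).
#' @return An `fyy_candidates` data frame: the matching ORF rows plus
#'   `orf_ref` and `cterm3` columns.
#' @export
#' @examples
#' orfs <- find_orfs("t1", "ATGGCTGGGTTTTATTATTAA")  # peptide "MAGFYY"
#' find_cterm_fyy(orfs)
find_cterm_fyy <- function(orfs) {
  pep <- toupper(orfs$peptide)
  n <- nchar(pep)
  hit <- is_mature(orfs) & n >= 3L & substr(pep, n - 2L, n) == "FYY"
  out <- orfs[hit, , drop = FALSE]
  out$orf_ref <- orf_id(out)
  out$cterm3 <- substr(toupper(out$peptide), nchar(out$peptide) - 2L,
                       nchar(out$peptide))
  rownames(out) <- NULL
  structure(out, class = c("fyy_candidates", "data.frame"))
}

#' @export
print.fyy_candidates <- function(x, ...) {
  cat(sprintf("%d mature ORF(s) with C-terminal FYY\n", nrow(x)))
  if (nrow(x)) print.data.frame(x[c("orf_ref", "peptide")])
  invisible(x)
}

#' Cross-reference FYY candidates with screen results
#'
#' Annotates each FYY candidate with its reciprocal-screen outcome (if the
#' candidate was screened), so a report can state whether FYY transcripts
#' match known oxidoreductases or have no database match at all.
#'
#' @param candidates An `fyy_candidates` data frame.
#' @param screen A `screen_result` data frame (may be empty).
#' @return The candidates with `screened`, `local_db`, `local_accession` and
#'   `retained` columns added (`NA` where the candidate produced no hit).
#' @export
annotate_fyy <- function(candidates, screen) {
  idx <- match(candidates$orf_ref, screen$orf_ref)
  candidates$screened <- !is.na(idx)
  candidates$local_db <- screen$local_db[idx]
  candidates$local_accession <- screen$local_accession[idx]
  candidates$retained <- screen$retained[idx]
  candidates
}
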