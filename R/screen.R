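# Reciprocal bitscore-comparison homology screen. Candidate ORFs are queried
# against small curated local databases (luciferases, photoproteins,
# luciferin-synthesis proteins); candidates with a passing local hit are
# re-queried against a large curated reference database, and retained only
# when the local bitscore is equal to or higher than the best reference
# bitscore. Bitscores (not E-values) are compared because they are
# insensitive to database size.

#' Read a protein database from FASTA
#'
#' @param path Protein FASTA file; the accession is the header up to the
#'   first whitespace.
#' @return Named character vector of peptide sequences.
#' @export
read_protein_db <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a protein database to FASTA
#'
#' @param db Named character vector of peptide sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_db <- function(db, path) {
  x <- Biostrings::AAStringSet(db)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Best database hit for one query peptide
#'
#' Aligns the query against every database entry and returns the single hit
#' with maximal bitscore whose E-value passes the cutoff, or `NULL` if none
#' does. Ties on bitscore are broken by lower E-value, then lexicographic
#' subject accession.
#'
#' @param peptide Query peptide string.
#' @param db Named character vector of database peptides (non-empty).
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff Maximum E-value for a reportable hit; `Inf` disables the
#'   cutoff (used for the reference side of the reciprocal screen).
#' @return An `alignment_hit` with `evalue` filled in, or `NULL`.
#' @export
query_db <- function(peptide, db, scheme = scoring_scheme(),
                     e_cutoff = 1e-5) {
  if (length(db) == 0L) stop("database is empty")
  if (is.null(names(db)) || any(!nzchar(names(db))))
    stop("database entries must be named by accession")
  n_res <- sum(nchar(db))
  hits <- lapply(names(db), function(acc) {
    h <- smith_waterman(peptide, db[[acc]], scheme,
                        query_id = "query", subject_id = acc)
    h$evalue <- evalue(h$bitscore, nchar(peptide), n_res)
    h
  })
  ok <- vapply(hits, function(h) h$evalue <= e_cutoff, logical(1))
  hits <- hits[ok]
  if (!length(hits)) return(NULL)
  bits <- vapply(hits, `[[`, numeric(1), "bitscore")
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  acc <- vapply(hits, `[[`, character(1), "subject_id")
  hits[[order(-bits, ev, acc)[1]]]
}

#' Reciprocal bitscore screen of ORFs against local databases
#'
#' For every ORF x local-database pair with a local hit passing the E-value
#' cutoff, finds the best reference-database hit (no E-value cutoff on the
#' reference side) and retains the candidate iff the local bitscore is equal
#' to or higher than the reference bitscore (or there is no reference hit at
#' all). Rejected candidates are kept in the output together with their
#' winning reference match, so negative results (e.g. photoprotein
#' candidates that better match calmodulin) are reportable.
#'
#' @param orfs ORF data frame (see [find_orfs()]).
#' @param local_dbs Named list of local protein databases (each a named
#'   character vector), e.g. `list(luciferase = ..., photoprotein = ...,
#'   luciferin_ipns = ...)`.
#' @param reference_db Curated reference database (named character vector,
#'   non-empty).
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff E-value cutoff applied to the local search (default 1e-5).
#' @param reference_e_cutoff E-value cutoff for the reference search;
#'   default `Inf` (any reference hit may outscore a local one).
#' @return A `screen_result` data frame, sorted by database then descending
#'   local bitscore, with columns `orf_ref`, `local_db`, `local_accession`,
#'   `local_bitscore`, `local_evalue`, `pct_identity`, `match_length`,
#'   `reference_accession`, `reference_bitscore`, `retained`.
#' @export
reciprocal_screen <- function(orfs, local_dbs, reference_db,
                              scheme = scoring_scheme(), e_cutoff = 1e-5,
                              reference_e_cutoff = Inf) {
  if (length(reference_db) == 0L) stop("reference database is empty")
  if (is.null(names(local_dbs))) stop("local_dbs must be a named list")
  ids <- orf_id(orfs)
  rows <- list()
  for (db_name in names(local_dbs)) {
    for (i in seq_len(nrow(orfs))) {
      local_hit <- query_db(orfs$peptide[i], local_dbs[[db_name]], scheme,
                            e_cutoff)
      if (is.null(local_hit)) next
      ref_hit <- query_db(orfs$peptide[i], reference_db, scheme,
                          reference_e_cutoff)
      retained <- is.null(ref_hit) ||
        local_hit$bitscore >= ref_hit$bitscore
      rows[[length(rows) + 1L]] <- data.frame(
        orf_ref = ids[i], local_db = db_name,
        local_accession = local_hit$subject_id,
        local_bitscore = local_hit$bitscore,
        local_evalue = local_hit$evalue,
        pct_identity = local_hit$pct_identity,
        match_length = local_hit$match_length,
        reference_accession = if (is.null(ref_hit)) NA_character_
                              else ref_hit$subject_id,
        reference_bitscore = if (is.null(ref_hit)) NA_real_
                             else ref_hit$bitscore,
        retained = retained, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    orf_ref = character(), local_db = character(),
    local_accession = character(), local_bitscore = numeric(),
    local_evalue = numeric(), pct_identity = numeric(),
    match_length = integer(), reference_accession = character(),
    reference_bitscore = numeric(), retained = logical(),
    stringsAsFactors = FALSE)
  out <- out[order(match(out$local_db, names(local_dbs)),
                   -out$local_bitscore), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("screen_result", "data.frame"))
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Reciprocal screen: %d candidate hit(s), %d retained\n",
              nrow(x), sum(x$retained)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}

#' Report table of retained homologs
#'
#' Formats the retained screen results in the conventional published schema:
#' Taxon, GenBank accession, Percent identity, Matching length, E-value
#' (scientific notation, 2 significant figures) and Bitscore.
#'
#' @param results A `screen_result` (see [reciprocal_screen()]).
#' @param taxon_map Named character vector mapping accession to taxon; an
#'   unmapped accession is reported as its own taxon, with a warning.
#' @return Data frame with columns `taxon`, `accession`, `pct_identity`,
#'   `match_length`, `evalue`, `bitscore`.
#' @export
report_table <- function(results, taxon_map = character()) {
  kept <- results[results$retained, , drop = FALSE]
  taxon <- unname(taxon_map[kept$local_accession])
  if (anyNA(taxon) && nrow(kept)) {
    missing_acc <- unique(kept$local_accession[is.na(taxon)])
    warning("no taxon mapping for accession(s): ",
            paste(missing_acc, collapse = ", "),
            "; using the accession as the taxon")
    taxon[is.na(taxon)] <- kept$local_accession[is.na(taxon)]
  }
  data.frame(
    taxon = taxon, accession = kept$local_accession,
    pct_identity = round(kept$pct_identity, 1),
    match_length = kept$match_length,
    evalue = sprintf("%.1e", signif(kept$local_evalue, 2)),
    bitscore = round(kept$local_bitscore, 1),
    stringsAsFactors = FALSE)
}
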