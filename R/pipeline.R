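# End-to-end orchestration: ORF prediction -> reciprocal homology screen ->
# FYY motif scan -> isotope-label MS detection -> COI delimitation, driven by
# a single config, with a checksummed output manifest for reproducibility.

#' Pipeline run configuration
#'
#' Collects input paths, cutoffs and the seed for [run_all()]. Any input
#' path may be `NULL`; stages whose inputs are missing are skipped with a
#' logged notice.
#'
#' @param out_dir Output directory (created; must not already contain a
#'   manifest, outputs are write-once per run directory).
#' @param transcripts Path to a transcript FASTA.
#' @param local_dbs Named character vector of local protein database FASTA
#'   paths (e.g. `c(luciferase = ..., photoprotein = ..., luciferin_ipns =
#'   ...)`).
#' @param reference_db Path to the curated reference protein FASTA.
#' @param peaklist Path to a centroided peak-list TSV.
#' @param coi_alignment Path to an aligned COI FASTA.
#' @param taxon_map Optional named character vector accession -> taxon for
#'   the report table.
#' @param min_aa Minimum ORF length (aa).
#' @param e_cutoff Local-search E-value cutoff.
#' @param ppm EIC extraction window half-width (ppm).
#' @param coi_cutoff Species-delimitation distance cutoff.
#' @param compound Compound to search in the peak list (see
#'   [compound_table()]).
#' @param labels 13C label counts to test for the compound.
#' @param standard_rt Retention time of the authentic standard (min), or
#'   `NA`.
#' @param seed Integer seed recorded in the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, transcripts = NULL, local_dbs = NULL,
                       reference_db = NULL, peaklist = NULL,
                       coi_alignment = NULL, taxon_map = character(),
                       min_aa = 5L, e_cutoff = 1e-5, ppm = 10,
                       coi_cutoff = 0.03, compound = "coelenteramine",
                       labels = c(0, 8, 9), standard_rt = NA, seed = 1L) {
  stopifnot(min_aa > 0, e_cutoff > 0, ppm > 0, coi_cutoff > 0)
  paths <- c(transcripts = transcripts, reference_db = reference_db,
             peaklist = peaklist, coi_alignment = coi_alignment, local_dbs)
  missing_paths <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing_paths))
    stop("input file(s) not found: ",
         paste(unlist(missing_paths), collapse = ", "))
  structure(list(out_dir = out_dir, transcripts = transcripts,
                 local_dbs = local_dbs, reference_db = reference_db,
                 peaklist = peaklist, coi_alignment = coi_alignment,
                 taxon_map = taxon_map, min_aa = min_aa,
                 e_cutoff = e_cutoff, ppm = ppm, coi_cutoff = coi_cutoff,
                 compound = compound, labels = labels,
                 standard_rt = standard_rt, seed = seed),
            class = "run_config")
}

.log_line <- function(stage, level, msg, quiet) {
  if (!quiet)
    message(sprintf("%s\t%s\t%s\t%s",
                    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, level,
                    msg))
}

#' Run the full pipeline
#'
#' Executes the stages whose inputs the config provides, in order: ORF
#' prediction, reciprocal homology screen, FYY motif scan, isotope-label MS
#' detection, COI delimitation. Each stage writes its outputs under the run
#' directory; a manifest with MD5 checksums is written last. Identical
#' config and seed yield byte-identical outputs.
#'
#' @param cfg A [run_config()].
#' @param quiet Suppress log lines.
#' @return Invisibly, a list of stage results plus the `manifest` data
#'   frame (`file`, `md5`).
#' @export
run_all <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.exists(file.path(cfg$out_dir, "manifest.tsv")))
    stop("run directory already contains a manifest; outputs are write-once")
  res <- list()
  outputs <- character()
  emit <- function(obj, fname, writer) {
    path <- file.path(cfg$out_dir, fname)
    writer(obj, path)
    outputs <<- c(outputs, path)
    path
  }
  write_tsv <- function(df, path)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)

  orfs <- NULL
  if (!is.null(cfg$transcripts)) {
    .log_line("orf", "INFO", paste("predicting ORFs from", cfg$transcripts),
              quiet)
    transcripts <- read_transcripts(cfg$transcripts)
    orfs <- find_orfs_all(transcripts, min_len = cfg$min_aa)
    res$orfs <- orfs
    emit(cbind(orf_ref = orf_id(orfs), orfs[setdiff(names(orfs), "seq")]),
         "orfs.tsv", write_tsv)
    emit(orfs, "orfs.fasta", write_orf_fasta)
    .log_line("orf", "INFO", sprintf("%d ORFs predicted (min %d aa)",
                                     nrow(orfs), cfg$min_aa), quiet)
  } else .log_line("orf", "NOTICE", "no transcripts supplied; skipped", quiet)

  if (!is.null(orfs) && !is.null(cfg$local_dbs) &&
      !is.null(cfg$reference_db)) {
    .log_line("screen", "INFO", "running reciprocal bitscore screen", quiet)
    local_dbs <- lapply(cfg$local_dbs, read_protein_db)
    reference_db <- read_protein_db(cfg$reference_db)
    screen <- reciprocal_screen(orfs, local_dbs, reference_db,
                                e_cutoff = cfg$e_cutoff)
    res$screen <- screen
    emit(as.data.frame(screen), "screen_all.tsv", write_tsv)
    emit(report_table(screen, cfg$taxon_map), "screen_retained.tsv",
         write_tsv)
    emit(as.data.frame(screen[!screen$retained, , drop = FALSE]),
         "screen_rejected.tsv", write_tsv)
    .log_line("screen", "INFO",
              sprintf("%d candidate(s), %d retained", nrow(screen),
                      sum(screen$retained)), quiet)
  } else .log_line("screen", "NOTICE",
                   "transcripts and/or databases missing; skipped", quiet)

  if (!is.null(orfs)) {
    fyy <- find_cterm_fyy(orfs)
    if (!is.null(res$screen)) fyy <- annotate_fyy(fyy, res$screen)
    res$fyy <- fyy
    emit(as.data.frame(fyy)[setdiff(names(fyy), "seq")], "fyy.tsv",
         write_tsv)
    if (nrow(fyy)) emit(fyy, "fyy.fasta", write_orf_fasta)
    .log_line("motif", "INFO",
              sprintf("%d mature C-terminal FYY candidate(s)", nrow(fyy)),
              quiet)
  }

  if (!is.null(cfg$peaklist)) {
    .log_line("isoms", "INFO", paste("screening peak list", cfg$peaklist),
              quiet)
    pl <- read_peaklist(cfg$peaklist)
    rep <- label_report(pl, cfg$compound, cfg$labels,
                        standard_rt = cfg$standard_rt, tol_ppm = cfg$ppm)
    res$isoms <- rep
    emit(rep, "isotope_detection.tsv", write_tsv)
    .log_line("isoms", "INFO",
              sprintf("%d/%d ion(s) detected", sum(rep$detected), nrow(rep)),
              quiet)
  } else .log_line("isoms", "NOTICE", "no peak list supplied; skipped", quiet)

  if (!is.null(cfg$coi_alignment)) {
    .log_line("coi", "INFO", paste("COI delimitation on", cfg$coi_alignment),
              quiet)
    aln <- read_coi_alignment(cfg$coi_alignment)
    m <- distance_matrix(aln)
    clusters <- threshold_clusters(m, cfg$coi_cutoff)
    res$coi <- list(distances = m, clusters = clusters)
    emit(m, "coi_distances.tsv", write_distance_matrix)
    cl_df <- data.frame(
      taxon = unlist(clusters),
      cluster = rep(seq_along(clusters), lengths(clusters)))
    emit(cl_df, "coi_clusters.tsv", write_tsv)
    if (length(aln) >= 3) {
      res$coi$tree <- nj_tree(m)
      emit(res$coi$tree, "coi_nj.nwk", function(tr, p) write_newick(tr, p))
    }
    .log_line("coi", "INFO",
              sprintf("%d taxa -> %d cluster(s) at cutoff %g", length(aln),
                      length(clusters), cfg$coi_cutoff), quiet)
  } else .log_line("coi", "NOTICE", "no COI alignment supplied; skipped",
                   quiet)

  manifest <- data.frame(
    file = basename(outputs),
    md5 = unname(tools::md5sum(outputs)), stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  res$manifest <- manifest
  .log_line("pipeline", "INFO",
            sprintf("run complete: %d output file(s)", nrow(manifest)),
            quiet)
  invisible(res)
}
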