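# Independent oracles and small fixture builders shared across tests.
# These are written against the documented semantics, not against the
# package internals, so they can catch implementation defects.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

random_transcript <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# --- independent affine-gap local alignment (score-only Gotoh, pure R) ----
# A gap of length L costs open + L * extend. Returns the optimal local score.
oracle_sw_score <- function(q, s, mat, open, extend) {
  qv <- strsplit(q, "", fixed = TRUE)[[1]]
  sv <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(qv); m <- length(sv)
  NEG <- -1e18
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                              Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                              Iy[i + 1, j] - extend)
      sub <- mat[qv[i], sv[j]]
      M[i + 1, j + 1] <- max(0, M[i, j] + sub, Ix[i, j] + sub,
                             Iy[i, j] + sub)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# --- brute-force ORF enumeration --------------------------------------
# Works directly on codon triplets: within each strand x frame, segments are
# delimited by stop codons; a stop-terminated segment yields a complete ORF
# from its first ATG (or a 5'-partial if it abuts the frame start with no
# ATG); the stopless tail yields a 3'-partial from its first ATG (or an
# internal ORF when the whole frame is stopless and startless).
oracle_orfs <- function(id, seq, min_len = 5L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rc <- function(x) paste(rev(unname(comp[strsplit(x, "")[[1]]])),
                          collapse = "")
  gc_tab <- Biostrings::GENETIC_CODE
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (frame in 0:2) {
      body <- substr(s, frame + 1L, nchar(s))
      k <- nchar(body) %/% 3L
      if (k == 0L) next
      codons <- substring(body, 3L * seq_len(k) - 2L, 3L * seq_len(k))
      aa <- unname(gc_tab[codons])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      stops <- which(is_stop)
      bounds <- c(0L, stops)
      for (b in seq_along(bounds)) {
        lo <- bounds[b] + 1L
        hi <- if (b <= length(stops)) stops[b] - 1L else k
        terminated <- b <= length(stops)
        if (hi < lo) next
        atg <- which(codons[lo:hi] == "ATG")
        if (length(atg)) {
          first <- lo + atg[1] - 1L
          cls <- if (terminated) "complete" else "three_prime_partial"
        } else if (lo == 1L) {
          first <- 1L
          cls <- if (terminated) "five_prime_partial" else "internal"
        } else next
        pep <- paste(aa[first:hi], collapse = "")
        if (nchar(pep) < min_len) next
        last_codon <- if (terminated) stops[b] else hi
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = id, start = frame + (first - 1L) * 3L,
          end = frame + last_codon * 3L, strand = strand, frame = frame,
          peptide = pep, completeness = cls, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(transcript_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), peptide = character(),
                      completeness = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$strand, c("+", "-")), res$start, res$frame), ]
  rownames(res) <- NULL
  res
}

# --- fixture bundle on disk for pipeline tests ------------------------
make_fixture_bundle <- function(dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  luc <- random_proteins(2, seed = seed + 100, len_range = c(120L, 160L),
                         prefix = "LUC")
  photo <- random_proteins(2, seed = seed + 200, len_range = c(120L, 160L),
                           prefix = "PHO")
  ipns <- random_proteins(2, seed = seed + 300, len_range = c(120L, 160L),
                          prefix = "IPN")
  ref <- random_proteins(8, seed = seed + 400, prefix = "SP")
  fyy_prot <- paste0(substr(random_proteins(1, seed = seed + 500,
                                            len_range = c(60L, 60L))[[1]],
                            1, 57), "FYY")
  plants <- list(
    plant_spec(names(luc)[1], luc[[1]], 0.97, mature = TRUE, cluster = "c1"),
    plant_spec(names(luc)[2], luc[[2]], 0.62, mature = TRUE, cluster = "c2"),
    plant_spec("FYY1", fyy_prot, 1.0, mature = TRUE, cluster = "c3"))
  tx <- gen_transcriptome(plants, n_decoys = 4, seed = seed)
  write_transcripts(tx$transcripts, file.path(dir, "transcripts.fasta"))
  write_protein_db(luc, file.path(dir, "luciferase.fasta"))
  write_protein_db(photo, file.path(dir, "photoprotein.fasta"))
  write_protein_db(ipns, file.path(dir, "luciferin_ipns.fasta"))
  write_protein_db(ref, file.path(dir, "reference.fasta"))
  planted_peaks <- data.frame(mz = c(labeled_mz("C17H15N3O", 8),
                                     labeled_mz("C17H15N3O", 9)),
                              rt_min = c(14.4, 14.4),
                              intensity = c(1e5, 2e4))
  pk <- gen_peaklist(planted_peaks, ppm_jitter = 2, noise_peaks = 30,
                     seed = seed)
  write_peaklist(pk$peaklist, file.path(dir, "peaks.tsv"))
  coi <- gen_coi_alignment(c(4L, 3L), within_div = 0.01, between_div = 0.13,
                           length = 600L, seed = seed)
  aln <- Biostrings::DNAStringSet(coi$alignment)
  Biostrings::writeXStringSet(aln, file.path(dir, "coi.fasta"))
  taxon_map <- stats::setNames(
    rep(c("Metridia sp.", "Photoprotein sp.", "IPNS sp."), each = 2),
    c(names(luc), names(photo), names(ipns)))
  list(dir = dir, tx = tx, peaks = pk, coi = coi,
       dbs = list(luciferase = luc, photoprotein = photo,
                  luciferin_ipns = ipns), ref = ref, taxon_map = taxon_map)
}
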