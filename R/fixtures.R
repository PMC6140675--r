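# Seeded synthetic-data generators with ground truth. These replace the
# study-scale inputs (raw sequencing reads, the LC-MS run, GenBank barcode
# sets) with small, fully controlled stand-ins so every pipeline stage can
# be tested round-trip against a known truth table.

.AA_CODONS <- split(names(Biostrings::GENETIC_CODE),
                    unname(Biostrings::GENETIC_CODE))

# Draw one integer uniformly from a closed range; safe when the range
# collapses to a single value (unlike sample(n, 1)).
.sample_range <- function(rng) {
  if (rng[1] >= rng[2]) return(as.integer(rng[1]))
  sample(rng[1]:rng[2], 1L)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Mutate a peptide to a target identity
#'
#' Substitutes residues at positions chosen without replacement so that the
#' fraction of positions equal to the input is the closest achievable to
#' `target_identity`. Substitutions are drawn uniformly from the 19
#' alternative standard residues; no stop symbols can be introduced.
#'
#' @param seq Non-empty peptide string over the 20 standard residues.
#' @param target_identity Fraction in `(0, 1]`.
#' @param seed Integer seed (required for reproducibility).
#' @param protect_ends If `TRUE`, the first and last residues are never
#'   substituted (when enough interior positions exist), so that a local
#'   re-alignment of the mutant against the source spans the full length
#'   instead of trimming mismatched termini. Used by [gen_transcriptome()].
#' @return Peptide string of the same length as `seq`.
#' @export
#' @examples
#' mutate_protein("MKTAYLQ", 4 / 7, seed = 1)
mutate_protein <- function(seq, target_identity, seed, protect_ends = FALSE) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) stop("seq must be non-empty")
  if (target_identity <= 0 || target_identity > 1)
    stop("target_identity must be in (0, 1]")
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(chars %in% .AA20))
    stop("seq must use the 20 standard residues")
  L <- length(chars)
  k <- round(L * (1 - target_identity))
  if (k == 0L) return(seq)
  candidates <- if (protect_ends && L - 2L >= k) 2:(L - 1L) else seq_len(L)
  with_seed(seed, {
    pos <- candidates[sample.int(length(candidates), k)]
    for (p in pos) {
      alternatives <- setdiff(.AA20, chars[p])
      chars[p] <- sample(alternatives, 1L)
    }
  })
  paste(chars, collapse = "")
}

#' Plant specification for the transcriptome generator
#'
#' @param name Accession/name of the source protein (goes in the truth
#'   table).
#' @param protein Source peptide string.
#' @param identity Target identity fraction in `(0, 1]` between the embedded
#'   ORF and the source.
#' @param mature If `TRUE` the embedded ORF carries a start and a stop codon
#'   (completeness `"complete"`); otherwise the stop codon is omitted and
#'   the ORF runs to the transcript end (`"three_prime_partial"`).
#' @param cluster Read-cluster label for the transcript.
#' @return A `plant_spec` list.
#' @export
plant_spec <- function(name, protein, identity = 1, mature = TRUE,
                       cluster = NULL) {
  if (identity <= 0 || identity > 1)
    stop("identity must be in (0, 1]")
  structure(list(name = name, protein = protein, identity = identity,
                 mature = mature, cluster = cluster), class = "plant_spec")
}

# Random nucleotide string avoiding the trinucleotide ATG anywhere (so
# planted starts stay the first in-frame start of their segment).
.random_utr <- function(len) {
  if (len <= 0L) return("")
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

# Reverse-translate a peptide choosing codons uniformly at random.
.random_codons <- function(peptide) {
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  vapply(aa, function(a) {
    codons <- .AA_CODONS[[a]]
    codons[sample.int(length(codons), 1L)]
  }, character(1), USE.NAMES = FALSE)
}

#' Generate a synthetic transcriptome with planted homologs
#'
#' Emits transcripts in which mutated copies of known source proteins are
#' embedded as ORFs at controlled identity, surrounded by start-codon-free
#' UTRs, plus i.i.d. random decoy transcripts. The returned truth table
#' records every plant, so downstream screens can be scored against it.
#'
#' @param plants List of [plant_spec()] objects (may be empty).
#' @param n_decoys Number of random decoy transcripts.
#' @param seed Integer seed; identical seeds and arguments give identical
#'   output.
#' @param decoy_len_range Length range (nt) for decoy transcripts.
#' @param utr_len_range Length range (nt) for the flanking UTRs of planted
#'   transcripts.
#' @return List with `transcripts` (data frame: `id`, `seq`, `cluster_id`)
#'   and `truth` (list with `planted_homologs` data frame — `transcript_id`,
#'   `db_accession`, `target_identity`, `planted_peptide`, `mature` — and
#'   `planted_fyy_ids`, the ids of transcripts whose planted mature peptide
#'   ends in FYY).
#' @export
gen_transcriptome <- function(plants = list(), n_decoys = 0, seed = 1,
                              decoy_len_range = c(300L, 600L),
                              utr_len_range = c(20L, 60L)) {
  stopifnot(n_decoys >= 0)
  for (p in plants) {
    if (!inherits(p, "plant_spec")) stop("plants must be plant_spec objects")
  }
  with_seed(seed, {
    rows <- list(); truth_rows <- list(); fyy <- character()
    for (i in seq_along(plants)) {
      p <- plants[[i]]
      pep <- mutate_protein(p$protein, p$identity,
                            seed = sample.int(.Machine$integer.max, 1L),
                            protect_ends = TRUE)
      codons <- .random_codons(pep)
      # guarantee the embedded ORF starts at an ATG: peptides not starting
      # with M get one prepended (M is coded by ATG only)
      orf_pep <- pep
      if (substr(pep, 1L, 1L) != "M") {
        codons <- c("ATG", codons)
        orf_pep <- paste0("M", pep)
      }
      utr5 <- .random_utr(.sample_range(utr_len_range))
      if (p$mature) {
        body <- paste0(paste(codons, collapse = ""), "TAA")
        utr3 <- .random_utr(.sample_range(utr_len_range))
        seq <- paste0(utr5, body, utr3)
      } else {
        # no stop codon: ORF runs to the transcript end (3'-partial)
        seq <- paste0(utr5, paste(codons, collapse = ""))
      }
      id <- sprintf("plant_%03d", i)
      cluster <- if (is.null(p$cluster)) id else p$cluster
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, seq = seq, cluster_id = cluster, stringsAsFactors = FALSE)
      truth_rows[[length(truth_rows) + 1L]] <- data.frame(
        transcript_id = id, db_accession = p$name,
        target_identity = p$identity, planted_peptide = orf_pep,
        mature = p$mature, stringsAsFactors = FALSE)
      if (p$mature && grepl("FYY$", orf_pep)) fyy <- c(fyy, id)
    }
    for (i in seq_len(n_decoys)) {
      len <- .sample_range(decoy_len_range)
      id <- sprintf("decoy_%03d", i)
      rows[[length(rows) + 1L]] <- data.frame(
        id = id,
        seq = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    collapse = ""),
        cluster_id = id, stringsAsFactors = FALSE)
    }
    transcripts <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = character(), seq = character(),
                 cluster_id = character(), stringsAsFactors = FALSE)
    truth <- list(
      planted_homologs = if (length(truth_rows)) do.call(rbind, truth_rows)
        else data.frame(transcript_id = character(),
                        db_accession = character(),
                        target_identity = numeric(),
                        planted_peptide = character(), mature = logical(),
                        stringsAsFactors = FALSE),
      planted_fyy_ids = fyy)
    list(transcripts = transcripts, truth = truth)
  })
}

#' Generate random unrelated proteins
#'
#' I.i.d. uniform residues; useful as decoy database entries or as an
#' unrelated reference database.
#'
#' @param n Number of proteins.
#' @param seed Integer seed.
#' @param len_range Length range in residues.
#' @param prefix Accession prefix.
#' @return Named character vector of peptides.
#' @export
random_proteins <- function(n, seed = 1, len_range = c(80L, 200L),
                            prefix = "RND") {
  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      len <- .sample_range(len_range)
      # first residue M so entries look like real proteins
      paste(c("M", sample(.AA20, len - 1L, replace = TRUE)), collapse = "")
    }, character(1))
    names(out) <- sprintf("%s%05d", prefix, seq_len(n))
    out
  })
}

#' Generate a synthetic centroided peak list
#'
#' Each planted ion traces a Gaussian chromatographic profile (apex at its
#' retention time, configurable width) across a regular scan grid; observed
#' m/z values are displaced from the planted value by at most `ppm_jitter`.
#' Noise peaks are scattered uniformly over the scan grid and m/z range but
#' never within `3 * ppm_jitter` of a planted m/z.
#'
#' @param planted Data frame with columns `mz`, `rt_min`, `intensity`
#'   (apex intensity, > 0); may have zero rows.
#' @param ppm_jitter Maximum |m/z| displacement in ppm (>= 0).
#' @param noise_peaks Number of noise peaks.
#' @param seed Integer seed.
#' @param rt_range Retention-time range (min) of the scan grid.
#' @param scan_dt Scan spacing (min).
#' @param peak_sd Chromatographic peak width (sd, min).
#' @param mz_range m/z range for noise peaks.
#' @return List with `peaklist` (a [as_peaklist()] object) and `truth`
#'   (the planted table plus the scan grid parameters).
#' @export
gen_peaklist <- function(planted, ppm_jitter = 2, noise_peaks = 0, seed = 1,
                         rt_range = c(0, 20), scan_dt = 0.05, peak_sd = 0.2,
                         mz_range = c(100, 1000)) {
  stopifnot(ppm_jitter >= 0, noise_peaks >= 0, peak_sd > 0, scan_dt > 0)
  if (nrow(planted) > 0) {
    stopifnot(all(c("mz", "rt_min", "intensity") %in% names(planted)))
    if (any(planted$intensity <= 0)) stop("planted intensities must be > 0")
    if (any(planted$rt_min < 0)) stop("retention times must be non-negative")
  }
  rt_grid <- seq(rt_range[1], rt_range[2], by = scan_dt)
  with_seed(seed, {
    peaks <- list()
    if (nrow(planted) == 0L && noise_peaks == 0L) {
      pl <- as_peaklist(data.frame(scan_index = integer(),
                                   rt_min = numeric(), mz = numeric(),
                                   intensity = numeric()))
      return(list(peaklist = pl,
                  truth = list(planted = planted, rt_grid = rt_grid,
                               ppm_jitter = ppm_jitter, peak_sd = peak_sd)))
    }
    for (i in seq_len(nrow(planted))) {
      rt0 <- planted$rt_min[i]
      scans <- which(abs(rt_grid - rt0) <= 4 * peak_sd)
      for (sc in scans) {
        z <- (rt_grid[sc] - rt0) / peak_sd
        jit <- if (ppm_jitter > 0) stats::runif(1, -ppm_jitter, ppm_jitter)
               else 0
        peaks[[length(peaks) + 1L]] <- data.frame(
          scan_index = sc, rt_min = rt_grid[sc],
          mz = planted$mz[i] * (1 + jit * 1e-6),
          intensity = planted$intensity[i] * exp(-z^2 / 2))
      }
    }
    n_noise <- 0L
    while (n_noise < noise_peaks) {
      mz <- stats::runif(1, mz_range[1], mz_range[2])
      if (nrow(planted) > 0 &&
          any(abs(mz - planted$mz) / planted$mz * 1e6 <
              3 * ppm_jitter)) next
      sc <- sample.int(length(rt_grid), 1L)
      peaks[[length(peaks) + 1L]] <- data.frame(
        scan_index = sc, rt_min = rt_grid[sc], mz = mz,
        intensity = stats::runif(1, 10, 1000))
      n_noise <- n_noise + 1L
    }
    pl <- as_peaklist(do.call(rbind, peaks))
    list(peaklist = pl,
         truth = list(planted = planted, rt_grid = rt_grid,
                      ppm_jitter = ppm_jitter, peak_sd = peak_sd))
  })
}

#' Generate a synthetic COI alignment with planted species structure
#'
#' Simulates ungapped barcode alignments under a simple substitution scheme:
#' species ancestors diverge from a common root at disjoint dedicated sites
#' (so the planted between-species p-distance is controlled tightly) and
#' individuals accumulate uniform within-species substitutions on top.
#'
#' @param species_sizes Integer vector: number of sequences per species.
#' @param within_div Target mean within-species p-distance (`0 <= within <
#'   between`).
#' @param between_div Target between-species p-distance (`<= 0.75`).
#' @param length Alignment length in nt (> 0).
#' @param seed Integer seed.
#' @return List with `alignment` (named character vector of aligned rows)
#'   and `truth` (list with `clade_assignments`, a named character vector
#'   taxon -> species label, plus the target divergences).
#' @export
gen_coi_alignment <- function(species_sizes, within_div = 0.01,
                              between_div = 0.13, length = 600L, seed = 1) {
  stopifnot(length > 0, all(species_sizes >= 1))
  if (within_div < 0 || between_div > 0.75)
    stop("divergences must satisfy 0 <= within < between <= 0.75")
  if (within_div >= between_div)
    stop("within_div must be smaller than between_div")
  n_sp <- base::length(species_sizes)
  # disjoint between-species sites: each species ancestor mutates k_b
  # dedicated sites, so two ancestors differ at 2 * k_b sites; individual
  # within-species mutations add ~within_div on top of the split
  k_b <- round(length * (between_div - within_div) / 2)
  m_w <- round(length * within_div / 2)
  if (n_sp * k_b > length)
    stop("alignment too short for the requested between-species divergence")
  nt <- c("A", "C", "G", "T")
  mutate_sites <- function(chars, sites) {
    for (s in sites) chars[s] <- sample(setdiff(nt, chars[s]), 1L)
    chars
  }
  with_seed(seed, {
    root <- sample(nt, length, replace = TRUE)
    site_pool <- if (k_b > 0) sample.int(length, n_sp * k_b) else integer()
    aln <- character(); who <- character(); labels <- character()
    for (sp in seq_len(n_sp)) {
      anc <- root
      if (k_b > 0) {
        own <- site_pool[((sp - 1L) * k_b + 1L):(sp * k_b)]
        anc <- mutate_sites(anc, own)
      }
      for (ind in seq_len(species_sizes[sp])) {
        chars <- anc
        if (m_w > 0) chars <- mutate_sites(chars, sample.int(length, m_w))
        taxon <- sprintf("sp%d_%02d", sp, ind)
        aln <- c(aln, paste(chars, collapse = ""))
        who <- c(who, taxon)
        labels <- c(labels, sprintf("species_%d", sp))
      }
    }
    names(aln) <- who
    list(alignment = aln,
         truth = list(clade_assignments = stats::setNames(labels, who),
                      within_div = within_div, between_div = between_div))
  })
}
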