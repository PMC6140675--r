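# Synthetic-data generators and their ground truth.

test_that("mutate_protein hits the closest achievable identity exactly", {
  expect_equal(mutate_protein("MKT", 1.0, seed = 1), "MKT")
  out <- mutate_protein("MKTAYLQ", 4 / 7, seed = 1)
  expect_equal(nchar(out), 7)
  matches <- sum(strsplit(out, "")[[1]] == strsplit("MKTAYLQ", "")[[1]])
  expect_equal(matches, 4)
  expect_error(mutate_protein("M", 0.0, seed = 1), "target_identity")
  expect_error(mutate_protein("", 0.5, seed = 1), "non-empty")
  expect_error(mutate_protein("MKT", 1.2, seed = 1), "target_identity")
  # never introduces stops and is reproducible
  set.seed(1)
  for (i in 1:20) {
    p <- random_peptide(sample(10:80, 1))
    idy <- runif(1, 0.3, 1)
    m1 <- mutate_protein(p, idy, seed = i)
    expect_false(grepl("*", m1, fixed = TRUE))
    expect_identical(m1, mutate_protein(p, idy, seed = i))
    realized <- mean(strsplit(m1, "")[[1]] == strsplit(p, "")[[1]])
    expect_lte(abs(realized - idy), 0.5 / nchar(p) + 1e-9)
  }
})

test_that("empty generator calls yield empty outputs", {
  tx <- gen_transcriptome(list(), n_decoys = 0, seed = 1)
  expect_equal(nrow(tx$transcripts), 0)
  expect_equal(nrow(tx$truth$planted_homologs), 0)
  g <- gen_peaklist(data.frame(mz = numeric(), rt_min = numeric(),
                               intensity = numeric()),
                    ppm_jitter = 2, noise_peaks = 0, seed = 1)
  expect_equal(nrow(g$peaklist), 0)
})

test_that("identity-1 mature plants embed the source protein verbatim", {
  src <- random_proteins(1, seed = 41, len_range = c(60L, 60L))[[1]]
  tx <- gen_transcriptome(list(plant_spec("SRC", src, 1.0, mature = TRUE)),
                          n_decoys = 0, seed = 3)
  orfs <- find_orfs_all(tx$transcripts)
  planted <- orfs[orfs$completeness == "complete" &
                    orfs$peptide == src, , drop = FALSE]
  expect_equal(nrow(planted), 1)
  # start codon and stop codon flank the source protein
  seq <- tx$transcripts$seq[1]
  span <- substr(seq, planted$start + 1, planted$end)
  expect_equal(substr(span, 1, 3), "ATG")
  expect_true(substr(span, nchar(span) - 2, nchar(span)) %in%
                c("TAA", "TAG", "TGA"))
})

test_that("planted identity round-trips through alignment within 2 points", {
  src <- random_proteins(1, seed = 42, len_range = c(124L, 124L))[[1]]
  tx <- gen_transcriptome(list(plant_spec("AAG54096", src, 0.62,
                                          mature = TRUE)),
                          n_decoys = 0, seed = 7)
  orfs <- find_orfs_all(tx$transcripts)
  truth_pep <- tx$truth$planted_homologs$planted_peptide[1]
  planted <- orfs[orfs$completeness == "complete" &
                    orfs$peptide == truth_pep, , drop = FALSE]
  expect_equal(nrow(planted), 1)
  hit <- smith_waterman(planted$peptide[1], src)
  expect_gte(hit$pct_identity, 60)
  expect_lte(hit$pct_identity, 64)
})

test_that("plant specs validate their identity fraction", {
  expect_error(plant_spec("A", "MKT", identity = 0), "identity")
  expect_error(plant_spec("A", "MKT", identity = 1.01), "identity")
})

test_that("generators are deterministic in the seed", {
  src <- random_proteins(1, seed = 2)[[1]]
  mk_tx <- function() gen_transcriptome(
    list(plant_spec("P", src, 0.8)), n_decoys = 3, seed = 10)
  expect_identical(mk_tx(), mk_tx())
  expect_false(identical(
    mk_tx(),
    gen_transcriptome(list(plant_spec("P", src, 0.8)), n_decoys = 3,
                      seed = 11)))
  mk_pk <- function(s) gen_peaklist(
    data.frame(mz = 300, rt_min = 5, intensity = 100), 2, 10, seed = s)
  expect_identical(mk_pk(4), mk_pk(4))
  mk_coi <- function(s) gen_coi_alignment(c(3, 3), 0.01, 0.13, 600, seed = s)
  expect_identical(mk_coi(6), mk_coi(6))
  # byte-identical files from identical seeds
  f1 <- tempfile(); f2 <- tempfile()
  write_transcripts(mk_tx()$transcripts, f1)
  write_transcripts(mk_tx()$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("peak-list jitter bounds and noise separation hold", {
  planted <- data.frame(mz = c(286.1556, 500.25), rt_min = c(14.4, 8),
                        intensity = c(1e5, 2e4))
  g <- gen_peaklist(planted, ppm_jitter = 2, noise_peaks = 100, seed = 13)
  pl <- g$peaklist
  for (i in 1:2) {
    ppm_off <- abs(pl$mz - planted$mz[i]) / planted$mz[i] * 1e6
    near <- ppm_off <= 2
    # every planted peak within +/- jitter; a Gaussian profile has > 1 scan
    expect_gt(sum(near), 5)
    # nothing (noise) in the 2-6 ppm annulus: separation is 3 x jitter
    expect_equal(sum(ppm_off > 2 & ppm_off <= 6), 0)
  }
  # zero jitter: observed m/z equals the planted value exactly
  g0 <- gen_peaklist(planted[1, ], ppm_jitter = 0, noise_peaks = 0, seed = 1)
  expect_true(all(g0$peaklist$mz == planted$mz[1]))
  expect_error(
    gen_peaklist(data.frame(mz = 300, rt_min = 1, intensity = -5),
                 2, 0, seed = 1), "> 0")
})

test_that("COI generator controls within- and between-species divergence", {
  # one species, zero within-divergence: all rows identical
  g0 <- gen_coi_alignment(4L, within_div = 0, between_div = 0.1,
                          length = 300L, seed = 2)
  expect_equal(length(unique(g0$alignment)), 1)

  # two singletons at 12.6%: the single distance lands within 10% relative
  g1 <- gen_coi_alignment(c(1L, 1L), within_div = 0.01, between_div = 0.126,
                          length = 600L, seed = 3)
  d <- p_distance(g1$alignment[[1]], g1$alignment[[2]])
  expect_gte(d, 0.113)
  expect_lte(d, 0.139)

  # realized means across a populated fixture
  g2 <- gen_coi_alignment(c(6L, 6L), within_div = 0.02, between_div = 0.13,
                          length = 800L, seed = 4)
  m <- distance_matrix(g2$alignment)
  lab <- g2$truth$clade_assignments[rownames(m)]
  same <- outer(lab, lab, "==") & upper.tri(m)
  diff_sp <- outer(lab, lab, "!=") & upper.tri(m)
  expect_lte(abs(mean(m[same]) - 0.02) / 0.02, 0.2)
  expect_lte(abs(mean(m[diff_sp]) - 0.13) / 0.13, 0.1)

  expect_error(gen_coi_alignment(c(2, 2), 0.13, 0.13, 600, 1), "smaller")
  expect_error(gen_coi_alignment(c(2, 2), 0.2, 0.8, 600, 1), "0.75")
})

test_that("planted homologs round-trip through the reciprocal screen", {
  src <- random_proteins(2, seed = 51, len_range = c(100L, 140L))
  plants <- list(plant_spec(names(src)[1], src[[1]], 0.97),
                 plant_spec(names(src)[2], src[[2]], 0.62))
  tx <- gen_transcriptome(plants, n_decoys = 3, seed = 19)
  orfs <- find_orfs_all(tx$transcripts)
  res <- reciprocal_screen(orfs, list(luciferase = src),
                           random_proteins(6, seed = 52, prefix = "SP"))
  kept <- res[res$retained, ]
  expect_setequal(unique(kept$local_accession), names(src))
  # recovered identities sit within 2 points of the planted targets
  for (i in 1:2) {
    row <- kept[kept$local_accession == names(src)[i], ][1, ]
    expect_lte(abs(row$pct_identity - 100 * plants[[i]]$identity), 2.5)
  }
})
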