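# Reciprocal bitscore-comparison screen.

scheme <- scoring_scheme()

test_that("query_db returns the top passing hit or nothing", {
  db <- random_proteins(3, seed = 21, len_range = c(60L, 90L))
  # query identical to one entry: that entry wins at 100% identity
  h <- query_db(db[[2]], db, scheme)
  expect_equal(h$subject_id, names(db)[2])
  expect_equal(h$pct_identity, 100)
  expect_true(h$evalue <= 1e-5)
  # short random query: nothing passes the cutoff
  expect_null(query_db("MKTAYL", db, scheme))
  expect_error(query_db("MKTAYL", character(0), scheme), "empty")
})

test_that("planted homolog is recovered from among decoys", {
  src <- random_proteins(1, seed = 33, len_range = c(144L, 144L))[[1]]
  mut <- mutate_protein(src, 0.97, seed = 8)
  db <- c(random_proteins(50, seed = 44, prefix = "DEC"),
          BAL63033 = src)
  h <- query_db(mut, db, scheme)
  expect_equal(h$subject_id, "BAL63033")
  expect_gt(h$pct_identity, 90)
})

test_that("retention rule: local bitscore equal or higher than reference", {
  src <- random_proteins(1, seed = 3, len_range = c(100L, 100L))[[1]]
  orfs <- data.frame(transcript_id = "t1", cluster_id = "c1", start = 0L,
                     end = 303L, strand = "+", frame = 0L, peptide = src,
                     completeness = "complete", stringsAsFactors = FALSE)
  # reference contains the identical protein: equal bitscores -> retained
  res_eq <- reciprocal_screen(orfs, list(luciferase = c(LOC1 = src)),
                              c(REF1 = src), scheme)
  expect_true(res_eq$retained)
  expect_equal(res_eq$local_bitscore, res_eq$reference_bitscore)
  # reference strictly better (local db holds a degraded copy) -> rejected
  weak <- mutate_protein(src, 0.6, seed = 5)
  res_lt <- reciprocal_screen(orfs, list(luciferase = c(LOC1 = weak)),
                              c(REF1 = src), scheme)
  expect_false(res_lt$retained)
  # unrelated reference -> local wins -> retained
  res_gt <- reciprocal_screen(orfs, list(luciferase = c(LOC1 = src)),
                              random_proteins(5, seed = 6, prefix = "SP"),
                              scheme)
  expect_true(res_gt$retained)
})

test_that("rejected candidates are reported with their reference winner", {
  src <- random_proteins(1, seed = 71, len_range = c(120L, 120L))[[1]]
  orfs <- data.frame(transcript_id = "t1", cluster_id = "c1", start = 0L,
                     end = 363L, strand = "+", frame = 0L, peptide = src,
                     completeness = "complete", stringsAsFactors = FALSE)
  weak <- mutate_protein(src, 0.65, seed = 2)
  res <- reciprocal_screen(orfs, list(photoprotein = c(CALM1 = weak)),
                           c(CALM_REF = src), scheme)
  expect_equal(nrow(res), 1)
  expect_false(res$retained)
  expect_equal(res$reference_accession, "CALM_REF")
  expect_gt(res$reference_bitscore, res$local_bitscore)
})

test_that("every reported candidate passes the local E-value cutoff", {
  b <- make_fixture_bundle(tempfile("bundle"), seed = 5)
  orfs <- find_orfs_all(b$tx$transcripts)
  res <- reciprocal_screen(orfs, b$dbs, b$ref, scheme)
  expect_true(all(res$local_evalue <= 1e-5))
})

test_that("retention is monotone in the local bitscore", {
  # raising the local score by making the local copy better can only keep
  # or gain retention, never lose it
  src <- random_proteins(1, seed = 12, len_range = c(100L, 100L))[[1]]
  orfs <- data.frame(transcript_id = "t1", cluster_id = "c1", start = 0L,
                     end = 303L, strand = "+", frame = 0L, peptide = src,
                     completeness = "complete", stringsAsFactors = FALSE)
  ref <- c(REF1 = mutate_protein(src, 0.8, seed = 1))
  retained <- vapply(c(0.7, 0.8, 0.9, 1.0), function(idy) {
    local <- c(LOC1 = mutate_protein(src, idy, seed = 3))
    reciprocal_screen(orfs, list(luciferase = local), ref, scheme)$retained
  }, logical(1))
  expect_true(all(diff(as.integer(retained)) >= 0))
})

test_that("report table follows the published schema", {
  empty <- reciprocal_screen(
    data.frame(transcript_id = character(), cluster_id = character(),
               start = integer(), end = integer(), strand = character(),
               frame = integer(), peptide = character(),
               completeness = character(), stringsAsFactors = FALSE),
    list(luciferase = c(L1 = "MKTAYLQWHEMKTAYLQWHE")),
    c(R1 = "MWHEAGAWGHEEMWHEAGAW"), scheme)
  tab0 <- report_table(empty)
  expect_equal(nrow(tab0), 0)
  expect_equal(names(tab0), c("taxon", "accession", "pct_identity",
                              "match_length", "evalue", "bitscore"))

  src <- random_proteins(1, seed = 61, len_range = c(144L, 144L))[[1]]
  orfs <- data.frame(transcript_id = "t1", cluster_id = "c1", start = 0L,
                     end = 435L, strand = "+", frame = 0L,
                     peptide = mutate_protein(src, 0.97, seed = 1),
                     completeness = "complete", stringsAsFactors = FALSE)
  res <- reciprocal_screen(orfs, list(luciferase = c(BAL63033 = src)),
                           random_proteins(4, seed = 9, prefix = "SP"),
                           scheme)
  tab <- report_table(res, c(BAL63033 = "Metridia okhotensis"))
  expect_equal(tab$taxon, "Metridia okhotensis")
  expect_equal(tab$accession, "BAL63033")
  expect_equal(tab$match_length, 144)
  expect_gt(tab$pct_identity, 94)
  expect_match(tab$evalue, "^[0-9]\\.[0-9]e-[0-9]+$")  # 2 significant figures
  # unmapped accession falls back to the accession with a warning
  expect_warning(tab2 <- report_table(res), "no taxon mapping")
  expect_equal(tab2$taxon, "BAL63033")
})
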