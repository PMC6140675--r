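# COI p-distances, threshold delimitation, neighbor joining.

test_that("p-distance counts mismatches over comparable sites only", {
  expect_equal(p_distance("ACGT", "ACGT"), 0)
  expect_equal(p_distance("ACGT", "ACGA"), 0.25)
  expect_equal(p_distance("AC-T", "ACGT"), 0)     # gap site excluded
  expect_equal(p_distance("ACNT", "ACGT"), 0)     # N site excluded
  expect_equal(p_distance("A--T", "AC-T"), 0)     # 2 comparable, 0 mismatch
  expect_error(p_distance("----", "ACGT"), "no comparable")
  expect_error(p_distance("ACG", "ACGT"), "equal length")
})

test_that("p-distance is invariant under joint column permutation", {
  set.seed(23)
  for (i in 1:20) {
    len <- sample(20:100, 1)
    a <- random_transcript(len)
    b <- random_transcript(len)
    perm <- sample(len)
    ap <- paste(strsplit(a, "")[[1]][perm], collapse = "")
    bp <- paste(strsplit(b, "")[[1]][perm], collapse = "")
    expect_equal(p_distance(a, b), p_distance(ap, bp))
  }
})

test_that("distance matrix equals hand-counted toy values", {
  aln <- c(s1 = "ACGTACGT", s2 = "ACGTACGA", s3 = "TCGTACGA")
  m <- distance_matrix(aln)
  want <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0) / 8, 3, 3,
                 dimnames = list(names(aln), names(aln)))
  expect_equal(m, want)
  expect_equal(distance_matrix(c(a = "ACGT", b = "ACGT")),
               matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
})

test_that("complete deletion drops every gapped column first", {
  aln <- c(s1 = "AC-TACGT", s2 = "ACGTACGA", s3 = "ACGTACGG")
  mp <- distance_matrix(aln, deletion = "pairwise")
  mc <- distance_matrix(aln, deletion = "complete")
  # pairwise: s2 vs s3 uses all 8 columns; complete: only 7 everywhere
  expect_equal(mp["s2", "s3"], 1 / 8)
  expect_equal(mc["s2", "s3"], 1 / 7)
})

test_that("group_range reports min and max cross-group distances", {
  g <- gen_coi_alignment(c(3L, 3L), within_div = 0.01, between_div = 0.13,
                         length = 600L, seed = 8)
  m <- distance_matrix(g$alignment)
  lab <- g$truth$clade_assignments
  A <- names(lab)[lab == "species_1"]
  B <- names(lab)[lab == "species_2"]
  r <- group_range(m, A, B)
  expect_lte(r[["min"]], r[["max"]])
  expect_gte(r[["min"]], 0.117 - 0.02)
  expect_lte(r[["max"]], 0.143 + 0.02)
  # singleton groups return that single distance twice
  r1 <- group_range(m, A[1], B[1])
  expect_equal(r1[["min"]], r1[["max"]])
  expect_equal(r1[["min"]], m[A[1], B[1]])
  expect_error(group_range(m, A, c(B, A[1])), "disjoint")
  expect_error(group_range(m, character(0), B), "non-empty")
})

test_that("threshold clustering follows single-linkage semantics", {
  m <- matrix(c(0, 0.02, 0.04,
                0.02, 0, 0.02,
                0.04, 0.02, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # chain a-b 2%, b-c 2%, a-c 4%: one cluster at 3%
  expect_equal(threshold_clusters(m, 0.03), list(c("a", "b", "c")))
  # all pairwise above the cutoff: singletons
  expect_equal(threshold_clusters(m, 0.01), list("a", "b", "c"))
  # boundary is closed
  expect_equal(length(threshold_clusters(m, 0.02)), 1)
  # extreme cutoffs
  expect_equal(length(threshold_clusters(m, 0.999)), 1)
})

test_that("planted species are recovered at the 3% cutoff", {
  g <- gen_coi_alignment(c(4L, 5L), within_div = 0.01, between_div = 0.13,
                         length = 600L, seed = 10)
  m <- distance_matrix(g$alignment)
  cl <- threshold_clusters(m, 0.03)
  expect_equal(length(cl), 2)
  lab <- g$truth$clade_assignments
  got <- lapply(cl, function(x) unique(unname(lab[x])))
  expect_true(all(lengths(got) == 1))
})

test_that("neighbor joining recovers a known additive 4-taxon tree", {
  # tree ((a:2,b:3):1,(c:4,d:5)) with internal branch 1
  taxa <- c("a", "b", "c", "d")
  m <- matrix(0, 4, 4, dimnames = list(taxa, taxa))
  m["a", "b"] <- m["b", "a"] <- 2 + 3
  m["a", "c"] <- m["c", "a"] <- 2 + 1 + 4
  m["a", "d"] <- m["d", "a"] <- 2 + 1 + 5
  m["b", "c"] <- m["c", "b"] <- 3 + 1 + 4
  m["b", "d"] <- m["d", "b"] <- 3 + 1 + 5
  m["c", "d"] <- m["d", "c"] <- 4 + 5
  m <- m / 20  # scale into [0, 1]
  tree <- nj_tree(m)
  expect_s3_class(tree, "phylo")
  # additive metric: path lengths in the tree reproduce the input exactly
  cp <- ape::cophenetic.phylo(tree)[taxa, taxa]
  expect_equal(cp, m, tolerance = 1e-10)
  expect_error(nj_tree(m[1:2, 1:2]), "at least 3")
})

test_that("ultrametric 3-taxon distances resolve with correct lengths", {
  taxa <- c("x", "y", "z")
  m <- matrix(c(0, 0.2, 0.4, 0.2, 0, 0.4, 0.4, 0.4, 0), 3, 3,
              dimnames = list(taxa, taxa))
  tree <- nj_tree(m)
  cp <- ape::cophenetic.phylo(tree)[taxa, taxa]
  expect_equal(cp, m, tolerance = 1e-10)
})

test_that("fixture clades are monophyletic in the NJ tree", {
  g <- gen_coi_alignment(c(4L, 4L), within_div = 0.01, between_div = 0.13,
                         length = 600L, seed = 12)
  m <- distance_matrix(g$alignment)
  tree <- nj_tree(m)
  lab <- g$truth$clade_assignments
  for (sp in unique(lab)) {
    members <- names(lab)[lab == sp]
    expect_true(ape::is.monophyletic(tree, members))
  }
})

test_that("misidentified sequences are flagged by nearest-label distance", {
  g <- gen_coi_alignment(c(4L, 4L), within_div = 0.01, between_div = 0.13,
                         length = 600L, seed = 14)
  m <- distance_matrix(g$alignment)
  lab <- g$truth$clade_assignments
  # mislabel one species_1 individual as species_2 (a la HM045328)
  lab_wrong <- lab
  lab_wrong["sp1_01"] <- "species_2"
  flags <- flag_misidentified(m, lab_wrong)
  expect_true(flags$flagged[flags$taxon == "sp1_01"])
  expect_equal(sum(flags$flagged), 1)
  # correct labels: nothing flagged
  expect_equal(sum(flag_misidentified(m, lab)$flagged), 0)
})

test_that("alignment FASTA reader enforces equal lengths and labels", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), path)
  aln <- read_coi_alignment(path)
  expect_equal(aln, c(a = "ACGT", b = "ACGA"))
  writeLines(c(">a", "ACGT", ">b", "ACG"), path)
  expect_error(read_coi_alignment(path), "same length")
})
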