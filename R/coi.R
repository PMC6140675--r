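# COI barcode distances and threshold-based species delimitation.
#
# Distances are uncorrected p-distances (the barcoding convention) with
# pairwise deletion of gaps/N by default; ~3% divergence is the customary
# crustacean species cutoff. A neighbor-joining tree is provided as a
# desk-scale distance-based visualization; it is not a maximum-likelihood
# phylogeny and makes no claim to replace one.

#' Read an aligned COI FASTA
#'
#' @param path Aligned nucleotide FASTA; all rows must be the same length.
#' @return Named character vector of aligned rows (uppercase).
#' @export
read_coi_alignment <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  .check_alignment(out)
  out
}

.check_alignment <- function(aln) {
  stopifnot(is.character(aln), length(aln) >= 1L)
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment rows must carry unique taxon labels")
  if (length(unique(nchar(aln))) != 1L)
    stop("alignment rows must all have the same length")
  bad <- grepl("[^ACGTN-]", aln)
  if (any(bad))
    stop("alignment contains characters outside {A,C,G,T,N,-}: ",
         paste(names(aln)[bad], collapse = ", "))
  invisible(aln)
}

#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of mismatching comparable sites, where a site is comparable
#' iff both characters are in `{A,C,G,T}` (pairwise deletion of gaps and N).
#'
#' @param a,b Equal-length aligned nucleotide strings.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")  # 0.25
#' p_distance("AC-T", "ACGT")  # 0   (gap site excluded)
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("rows must have equal length")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  nt <- c("A", "C", "G", "T")
  comparable <- av %in% nt & bv %in% nt
  n <- sum(comparable)
  if (n == 0L)
    stop("no comparable sites: p-distance undefined")
  sum(av[comparable] != bv[comparable]) / n
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln Named character vector of equal-length aligned rows (>= 2),
#'   e.g. from [read_coi_alignment()].
#' @param deletion `"pairwise"` (default) drops non-ACGT sites per pair;
#'   `"complete"` drops every column containing a gap or N in any row before
#'   computing distances.
#' @return Symmetric numeric matrix with taxon dimnames; zero diagonal.
#' @export
distance_matrix <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  .check_alignment(aln)
  if (length(aln) < 2L) stop("need at least 2 sequences")
  if (deletion == "complete") {
    mat <- do.call(rbind, strsplit(toupper(aln), "", fixed = TRUE))
    keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
    if (!any(keep)) stop("no comparable sites: p-distance undefined")
    aln <- stats::setNames(apply(mat[, keep, drop = FALSE], 1, paste,
                                 collapse = ""), names(aln))
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(aln[[i]], aln[[j]])
    }
  }
  d
}

.check_dist <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m),
            !is.null(rownames(m)), identical(rownames(m), colnames(m)))
  stopifnot(all(abs(m - t(m)) < 1e-12), all(diag(m) == 0),
            all(m >= 0), all(m <= 1))
  invisible(m)
}

#' Distance range between two groups of taxa
#'
#' Minimum and maximum pairwise distance over all cross-group pairs, the
#' form in which interspecies COI divergence is conventionally reported
#' (e.g. "10.1-14.6%").
#'
#' @param m Distance matrix with taxon dimnames.
#' @param groupA,groupB Disjoint, non-empty character vectors of taxon
#'   labels present in `m`.
#' @return Named numeric vector `c(min = ..., max = ...)`.
#' @export
group_range <- function(m, groupA, groupB) {
  .check_dist(m)
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("groups must be non-empty")
  if (length(intersect(groupA, groupB)))
    stop("groups must be disjoint")
  missing_taxa <- setdiff(c(groupA, groupB), rownames(m))
  if (length(missing_taxa))
    stop("taxa not in matrix: ", paste(missing_taxa, collapse = ", "))
  cross <- m[groupA, groupB, drop = FALSE]
  c(min = min(cross), max = max(cross))
}

#' Threshold clustering of taxa (single linkage)
#'
#' Partitions taxa into the connected components of the graph joining every
#' pair at distance <= `cutoff` (single-linkage semantics; the boundary is
#' closed). At the conventional ~3% COI cutoff the clusters are putative
#' species.
#'
#' @param m Distance matrix with taxon dimnames.
#' @param cutoff Distance threshold in `(0, 1)`; default 0.03.
#' @return List of character vectors (clusters), each sorted, ordered by
#'   their smallest member label.
#' @export
threshold_clusters <- function(m, cutoff = 0.03) {
  .check_dist(m)
  stopifnot(cutoff > 0, cutoff < 1)
  taxa <- rownames(m)
  n <- length(taxa)
  # union-find over pairs within the cutoff
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (m[i, j] <= cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(taxa, roots)
  comps <- lapply(comps, sort)
  comps <- comps[order(vapply(comps, `[`, character(1), 1))]
  names(comps) <- NULL
  comps
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration; negative branch lengths are
#' clamped to zero. Offered as a quick distance-based tree for inspection of
#' clade structure, explicitly not a substitute for model-based phylogenetic
#' reconstruction.
#'
#' @param m Distance matrix with taxon dimnames (>= 3 taxa).
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(m) {
  .check_dist(m)
  if (nrow(m) < 3L) stop("neighbor joining needs at least 3 taxa")
  tree <- ape::nj(stats::as.dist(m))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree An [ape::phylo] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Flag putatively misidentified sequences
#'
#' A labelled sequence whose nearest species (by mean distance to all
#' sequences carrying each other label) differs from its own label is
#' flagged — the distance-based analogue of spotting a GenBank record that
#' nests inside the wrong species' clade.
#'
#' @param m Distance matrix with taxon dimnames.
#' @param labels Named character vector mapping every taxon in `m` to a
#'   species label.
#' @return Data frame with columns `taxon`, `label`, `nearest_label`,
#'   `mean_dist_own`, `mean_dist_nearest`, `flagged`.
#' @export
flag_misidentified <- function(m, labels) {
  .check_dist(m)
  taxa <- rownames(m)
  if (!all(taxa %in% names(labels)))
    stop("labels must cover every taxon in the matrix")
  labels <- labels[taxa]
  species <- sort(unique(labels))
  rows <- lapply(taxa, function(tx) {
    mean_by <- vapply(species, function(sp) {
      members <- setdiff(taxa[labels == sp], tx)
      if (!length(members)) return(NA_real_)
      mean(m[tx, members])
    }, numeric(1))
    nearest <- species[which.min(mean_by)]
    data.frame(taxon = tx, label = unname(labels[tx]),
               nearest_label = nearest,
               mean_dist_own = unname(mean_by[labels[tx]]),
               mean_dist_nearest = unname(mean_by[nearest]),
               flagged = !is.na(nearest) && nearest != labels[tx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a distance matrix as PHYLIP-style square TSV
#'
#' @param m Distance matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  .check_dist(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i], sprintf("%.6f", m[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}
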