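# Exact-mass arithmetic for 13C-labelled coelenterazine-pathway ions and
# EIC-based detection in centroided peak lists.

# Monoisotopic atomic masses (Da). 12C is exactly 12 by definition of the dalton.
.ATOMIC_MASS <- c(
  C = 12,
  H = 1.00782503,
  N = 14.0030740,
  O = 15.9949146,
  S = 31.9720707,
  P = 30.9737615
)
.MASS_13C <- 13.0033548
.MASS_PROTON <- 1.00727646

#' Compound table for the coelenterazine pathway
#'
#' Molecular formulas of the compounds tracked by the isotope-labelling
#' analysis: coelenterazine (the luciferin itself) and coelenteramine (its
#' degradation product, whose detection with carbon labels evidences de novo
#' luciferin synthesis).
#'
#' @return A data frame with columns `compound` and `formula`.
#' @export
#' @examples
#' compound_table()
compound_table <- function() {
  data.frame(
    compound = c("coelenteramine", "coelenterazine"),
    formula = c("C17H15N3O", "C26H21N3O3"),
    stringsAsFactors = FALSE
  )
}

#' Parse a molecular formula
#'
#' Converts a Hill-style formula string such as `"C17H15N3O"` into a named
#' integer vector of element counts.
#'
#' @param formula A formula string, or an already-named numeric vector of
#'   counts (returned unchanged after validation).
#' @return Named integer vector of element counts.
#' @export
#' @examples
#' parse_formula("C17H15N3O")
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(!nzchar(names(formula))))
      stop("element counts must be named")
    counts <- formula
  } else {
    stopifnot(is.character(formula), length(formula) == 1L)
    if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
      stop("malformed molecular formula: ", formula)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
    tokens <- regmatches(formula, list(m))[[1]]
    elems <- sub("[0-9]+$", "", tokens)
    nums <- sub("^[A-Z][a-z]?", "", tokens)
    counts <- ifelse(nzchar(nums), as.numeric(nums), 1)
    names(counts) <- elems
    counts <- tapply(counts, names(counts), sum)
    counts <- stats::setNames(as.vector(counts), names(counts))
  }
  if (any(counts < 0)) stop("element counts must be non-negative")
  counts <- counts[counts > 0]
  if (length(counts) == 0L) stop("formula contains no atoms")
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum of element counts times monoisotopic atomic masses (all atoms in their
#' lightest stable isotope; 12C = 12 Da exactly).
#'
#' @param formula Formula string or named count vector (see [parse_formula()]).
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass("C17H15N3O")
monoisotopic_mass <- function(formula) {
  counts <- parse_formula(formula)
  unknown <- setdiff(names(counts), names(.ATOMIC_MASS))
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(counts * .ATOMIC_MASS[names(counts)])
}

#' Theoretical m/z of a 13C-labelled protonated ion
#'
#' Replaces `n_13C` of the formula's carbons with 13C and protonates
#' (`[M+H]+`, charge +1). The label position never affects the value: each
#' substitution shifts the mass by exactly 13.0033548 - 12 Da.
#'
#' @param formula Formula string or named count vector.
#' @param n_13C Number of carbon atoms carrying the 13C label.
#' @param charge Ion charge; only +1 (singly protonated) is supported.
#' @return m/z in Th.
#' @export
#' @examples
#' labeled_mz("C17H15N3O", 8)  # 13C8-coelenteramine [M+H]+
#' labeled_mz("C17H15N3O", 9)  # 13C9-coelenteramine [M+H]+
labeled_mz <- function(formula, n_13C = 0, charge = 1L) {
  counts <- parse_formula(formula)
  stopifnot(length(n_13C) == 1L, n_13C >= 0, n_13C == round(n_13C))
  if (charge != 1L) stop("only singly protonated ions are supported")
  n_carbon <- if ("C" %in% names(counts)) counts[["C"]] else 0
  if (n_13C > n_carbon)
    stop("n_13C (", n_13C, ") exceeds carbon count (", n_carbon, ")")
  (monoisotopic_mass(counts) + n_13C * (.MASS_13C - 12) + .MASS_PROTON) / 1
}

#' Relative mass error in parts per million
#'
#' @param observed Observed m/z (Th).
#' @param theoretical Theoretical m/z (Th); must be positive.
#' @return Absolute relative deviation in ppm (unrounded; reports
#'   conventionally round to 1 decimal place).
#' @export
#' @examples
#' round(ppm_error(286.1561, 286.1556), 1)
ppm_error <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  abs(observed - theoretical) / theoretical * 1e6
}

#' Read a centroided peak list
#'
#' Reads the simple tab-separated peak-list format with columns
#' `scan_index`, `rt_min`, `mz`, `intensity` (one row per centroided peak).
#'
#' @param path Path to a TSV file.
#' @return A `peaklist` object (data frame of peaks, ordered by scan).
#' @export
read_peaklist <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  as_peaklist(df)
}

#' Coerce a data frame to a peak list
#'
#' @param df Data frame with columns `scan_index`, `rt_min`, `mz`, `intensity`.
#' @return A `peaklist` object.
#' @export
as_peaklist <- function(df) {
  need <- c("scan_index", "rt_min", "mz", "intensity")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("peak list lacks column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[need]
  if (any(df$intensity < 0)) stop("intensities must be non-negative")
  df <- df[order(df$scan_index, df$mz), , drop = FALSE]
  rt_by_scan <- tapply(df$rt_min, df$scan_index, unique)
  if (any(lengths(rt_by_scan) != 1L))
    stop("a scan_index maps to more than one rt_min")
  rt <- unlist(rt_by_scan)
  if (is.unsorted(rt[order(as.numeric(names(rt)))]))
    stop("rt_min must be non-decreasing in scan_index")
  rownames(df) <- NULL
  structure(df, class = c("peaklist", "data.frame"))
}

#' Write a peak list to TSV
#'
#' @param pl A `peaklist`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path) {
  utils::write.table(as.data.frame(pl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("Centroided peak list: %d peaks over %d scans (rt %.2f-%.2f min)\n",
              nrow(x), length(unique(x$scan_index)),
              if (nrow(x)) min(x$rt_min) else NA, if (nrow(x)) max(x$rt_min) else NA))
  invisible(x)
}

# Scan table (one row per scan) of a peak list; empty peak list -> 0 rows.
.scans <- function(pl) {
  if (nrow(pl) == 0L)
    return(data.frame(scan_index = integer(), rt_min = numeric()))
  u <- !duplicated(pl$scan_index)
  out <- data.frame(scan_index = pl$scan_index[u], rt_min = pl$rt_min[u])
  out[order(out$scan_index), , drop = FALSE]
}

#' Extracted ion chromatogram
#'
#' Per scan, sums the intensities of peaks whose m/z lies within a closed
#' relative window of `tol_ppm` around `target_mz`; scans with no matching
#' peak contribute zero.
#'
#' @param pl A `peaklist`.
#' @param target_mz Target m/z (Th).
#' @param tol_ppm Half-width of the extraction window in ppm (default 10,
#'   the conventional Q-TOF window).
#' @return An `eic` object: data frame with one row per scan (`scan_index`,
#'   `rt_min`, `intensity`), plus attributes `target_mz` and `tol_ppm`.
#' @export
extract_eic <- function(pl, target_mz, tol_ppm = 10) {
  stopifnot(inherits(pl, "peaklist"), target_mz > 0, tol_ppm > 0)
  sc <- .scans(pl)
  # closed window; tiny absolute slack so an exactly-boundary peak is never
  # lost to floating-point rounding of the ppm ratio
  inside <- abs(pl$mz - target_mz) / target_mz * 1e6 <= tol_ppm + 1e-9
  sums <- tapply(pl$intensity[inside], factor(pl$scan_index[inside],
                                              levels = sc$scan_index), sum)
  sc$intensity <- as.numeric(ifelse(is.na(sums), 0, sums))
  structure(sc, target_mz = target_mz, tol_ppm = tol_ppm,
            class = c("eic", "data.frame"))
}

#' @export
print.eic <- function(x, ...) {
  cat(sprintf("EIC for m/z %.4f (+/- %g ppm): %d scans, max intensity %.3g\n",
              attr(x, "target_mz"), attr(x, "tol_ppm"), nrow(x),
              if (nrow(x)) max(x$intensity) else NA))
  invisible(x)
}

#' Detect a labelled ion in a peak list
#'
#' Extracts the EIC of the ion's theoretical m/z, finds the apex, computes
#' the mass error at the apex (intensity-weighted mean observed m/z within
#' the window at the apex scan vs. the theoretical value) and checks whether
#' the apex retention time matches a reference standard.
#'
#' @param pl A `peaklist`.
#' @param formula Molecular formula of the neutral compound.
#' @param n_13C Number of 13C labels carried by the ion.
#' @param standard_rt Retention time (min) of the authentic standard, or `NA`
#'   to skip the retention-time comparison.
#' @param rt_tol Retention-time tolerance (min) for the standard match.
#' @param tol_ppm Extraction window half-width (ppm).
#' @param compound Optional compound name for the report.
#' @return An `ion_detection` list: `detected`, `theoretical_mz`, `apex_rt`,
#'   `apex_intensity`, `area`, `observed_mz`, `ppm_error`, `rt_match`.
#' @export
detect_labeled_ion <- function(pl, formula, n_13C = 0, standard_rt = NA,
                               rt_tol = 0.2, tol_ppm = 10, compound = NULL) {
  stopifnot(rt_tol > 0)
  target <- labeled_mz(formula, n_13C)
  eic <- extract_eic(pl, target, tol_ppm)
  out <- list(compound = compound, formula = formula, n_13C = n_13C,
              theoretical_mz = target, tol_ppm = tol_ppm,
              detected = FALSE, apex_rt = NA_real_, apex_intensity = NA_real_,
              area = NA_real_, observed_mz = NA_real_, ppm_error = NA_real_,
              rt_match = NA)
  if (nrow(eic) == 0L || all(eic$intensity == 0)) {
    return(structure(out, class = "ion_detection"))
  }
  apex <- which.max(eic$intensity)
  out$detected <- TRUE
  out$apex_rt <- eic$rt_min[apex]
  out$apex_intensity <- eic$intensity[apex]
  # trapezoidal area over retention time
  if (nrow(eic) > 1L) {
    dt <- diff(eic$rt_min)
    out$area <- sum(dt * (utils::head(eic$intensity, -1) +
                            utils::tail(eic$intensity, -1)) / 2)
  } else {
    out$area <- eic$intensity
  }
  in_apex <- pl$scan_index == eic$scan_index[apex] &
    abs(pl$mz - target) / target * 1e6 <= tol_ppm + 1e-9
  out$observed_mz <- sum(pl$mz[in_apex] * pl$intensity[in_apex]) /
    sum(pl$intensity[in_apex])
  out$ppm_error <- ppm_error(out$observed_mz, target)
  if (!is.na(standard_rt))
    out$rt_match <- abs(out$apex_rt - standard_rt) <= rt_tol
  structure(out, class = "ion_detection")
}

#' @export
print.ion_detection <- function(x, ...) {
  label <- if (x$n_13C > 0) sprintf("13C%d-", x$n_13C) else ""
  name <- if (!is.null(x$compound)) x$compound else x$formula
  if (!x$detected) {
    cat(sprintf("%s%s [M+H]+ m/z %.4f: not detected\n",
                label, name, x$theoretical_mz))
  } else {
    cat(sprintf(
      "%s%s [M+H]+ m/z %.4f: apex %.2f min, observed m/z %.4f (%.1f ppm error)%s\n",
      label, name, x$theoretical_mz, x$apex_rt, x$observed_mz,
      round(x$ppm_error, 1),
      if (is.na(x$rt_match)) "" else
        if (x$rt_match) ", retention time matches standard"
        else ", retention time does NOT match standard"))
  }
  invisible(x)
}

#' Isotope-label detection report for a set of label counts
#'
#' Runs [detect_labeled_ion()] for each requested label count of one compound
#' and assembles a tabular report, including absent-compound (not detected)
#' rows.
#'
#' @param pl A `peaklist`.
#' @param compound Compound name present in [compound_table()], or a formula
#'   string.
#' @param labels Integer vector of 13C label counts to test.
#' @param standard_rt,rt_tol,tol_ppm See [detect_labeled_ion()].
#' @return Data frame with one row per label count.
#' @export
label_report <- function(pl, compound, labels = c(0, 8, 9), standard_rt = NA,
                         rt_tol = 0.2, tol_ppm = 10) {
  tab <- compound_table()
  if (compound %in% tab$compound) {
    formula <- tab$formula[match(compound, tab$compound)]
    name <- compound
  } else {
    formula <- compound
    name <- compound
  }
  rows <- lapply(labels, function(k) {
    d <- detect_labeled_ion(pl, formula, k, standard_rt, rt_tol, tol_ppm,
                            compound = name)
    data.frame(compound = name, formula = formula, n_13C = k,
               theoretical_mz = d$theoretical_mz, detected = d$detected,
               apex_rt = d$apex_rt, apex_intensity = d$apex_intensity,
               area = d$area, observed_mz = d$observed_mz,
               ppm_error = round(d$ppm_error, 1), rt_match = d$rt_match)
  })
  do.call(rbind, rows)
}
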