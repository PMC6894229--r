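#' Reading and writing pipeline tables
#'
#' All interchange formats are plain CSV: spectra (first column `ppm`,
#' stored descending by NMR convention, one column per sample), metabolite
#' quantification tables (`sample_id` plus one column per metabolite),
#' metadata, metabolite libraries (one row per peak) and threshold sets.
#' Readers validate their schema and reject malformed files instead of
#' silently coercing.
#'
#' @name pipeline-io
NULL

#' Write a set of spectra to CSV
#'
#' @param spectra Named list of [nmr_spectrum()] objects sharing one axis.
#' @param path Output file.
#' @export
write_spectra_csv <- function(spectra, path) {
  ppm <- spectra[[1]]$ppm
  for (s in spectra) {
    if (!isTRUE(all.equal(s$ppm, ppm))) {
      stop("all spectra must share the same ppm axis")
    }
  }
  o <- order(ppm, decreasing = TRUE)
  tab <- data.frame(ppm = ppm[o], check.names = FALSE)
  for (s in spectra) tab[[s$sample_id]] <- s$intensity[o]
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a set of spectra from CSV
#'
#' @param path CSV with a `ppm` first column (strictly monotone) and one
#'   intensity column per sample.
#' @return Named list of [nmr_spectrum()] objects.
#' @export
read_spectra_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] != "ppm") stop("first column must be 'ppm'")
  if (ncol(tab) < 2) stop("no sample columns found")
  ids <- names(tab)[-1]
  if (anyDuplicated(ids)) stop("duplicated sample columns")
  d <- diff(tab$ppm)
  if (!(all(d > 0) || all(d < 0))) {
    stop("ppm axis must be strictly monotone")
  }
  out <- lapply(ids, function(id) nmr_spectrum(tab$ppm, tab[[id]], id))
  names(out) <- ids
  out
}

#' Write / read a quantification table
#'
#' @param quant Samples x metabolites matrix with sample-id row names.
#' @param path CSV path.
#' @export
write_quant_csv <- function(quant, path) {
  tab <- data.frame(sample_id = rownames(quant), as.data.frame(quant),
                    check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_quant_csv
#' @export
read_quant_csv <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (names(tab)[1] != "sample_id") stop("first column must be 'sample_id'")
  if (anyDuplicated(names(tab)[-1])) {
    stop("duplicated metabolite columns")
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample ids")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric quantification values")
  rownames(m) <- tab$sample_id
  m
}

#' Write / read a metabolite library
#'
#' @param library Metabolite library data frame (one row per peak).
#' @param path CSV path.
#' @export
write_library_csv <- function(library, path) {
  validate_library(library)
  utils::write.csv(library, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library_csv
#' @export
read_library_csv <- function(path) {
  validate_library(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read a sample metadata table
#'
#' @param metadata Data frame with a `sample_id` column.
#' @param path CSV path.
#' @export
write_metadata_csv <- function(metadata, path) {
  if (!"sample_id" %in% names(metadata)) stop("metadata needs 'sample_id'")
  utils::write.csv(metadata, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab)) stop("metadata needs 'sample_id'")
  if (anyDuplicated(tab$sample_id)) stop("duplicated sample ids")
  tab
}

#' Default dichotomization thresholds
#'
#' The published ROC-derived and clinical cutoffs used by the survival
#' analyses: serum lactate 56.9 and pyruvate 12.5 (arbitrary integral
#' units), preoperative insulin 18.3 IU and C-peptide 1.22 nM, tissue
#' glutathione 1.09 (log10 scale), and the proliferation cutoffs MAI 10,
#' PPH3 13, Ki67 15 and 30.  Dichotomization is `value >= cutoff` = high.
#'
#' @return Named numeric vector of cutoffs.
#' @export
default_thresholds <- function() {
  c(s_lactate = 56.9, s_pyruvate = 12.5, insulin = 18.3, cpeptide = 1.22,
    t_glutathione = 1.09, mai = 10, pph3 = 13, ki67_15 = 15, ki67_30 = 30)
}
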