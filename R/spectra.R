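#' Spectra collection on a shared wavelength axis
#'
#' A `spectra_set` holds a numeric matrix of per-sample spectra (rows =
#' samples, columns = wavelengths on a strictly increasing integer 1-nm grid)
#' together with a processing-state tag. Raw values are relative reflectance
#' (unitless, >= 0); after Savitzky-Golay differentiation values are per-nm
#' derivatives. Values above 1 (specular glare) are admitted with a warning
#' rather than clipped, since clipping would bias the SNV transform.
#'
#' @param matrix numeric matrix, n_samples x n_wavelengths.
#' @param wavelengths integer vector of nm positions, strictly increasing,
#'   uniform 1-nm spacing.
#' @param sample_ids unique character identifiers, one per row.
#' @param state processing state, one of `"raw"`, `"jump_corrected"`,
#'   `"snv"`, `"first_derivative"`.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(matrix, wavelengths, sample_ids,
                        state = c("raw", "jump_corrected", "snv",
                                  "first_derivative")) {
  state <- match.arg(state)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  wavelengths <- as.numeric(wavelengths)
  sample_ids <- as.character(sample_ids)

  if (nrow(matrix) < 1L) stop("spectra_set needs at least one sample")
  if (length(wavelengths) != ncol(matrix))
    stop("length(wavelengths) must equal ncol(matrix)")
  if (length(sample_ids) != nrow(matrix))
    stop("length(sample_ids) must equal nrow(matrix)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (any(!is.finite(wavelengths)) || is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be finite and strictly increasing")
  if (any(wavelengths != round(wavelengths)))
    stop("wavelengths must be integer nm")
  steps <- diff(wavelengths)
  if (length(steps) && any(steps != steps[1L]))
    stop("non-uniform wavelength grid (spacing must be constant)")
  if (!all(is.finite(matrix)))
    stop("spectral values must be finite")
  if (state %in% c("raw", "jump_corrected")) {
    if (any(matrix < 0)) stop("raw reflectance values must be >= 0")
    if (any(matrix > 1))
      warning("reflectance values > 1 present (specular glare?); kept unclipped")
  }

  dimnames(matrix) <- list(sample_ids, as.character(wavelengths))
  structure(list(matrix = matrix, wavelengths = wavelengths,
                 sample_ids = sample_ids, state = state),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d bands [%g-%g nm], state = %s\n",
              nrow(x$matrix), ncol(x$matrix),
              min(x$wavelengths), max(x$wavelengths), x$state))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$matrix)

# replace matrix/axis keeping invariants checked
set_replace <- function(set, matrix = set$matrix, wavelengths = set$wavelengths,
                        sample_ids = set$sample_ids, state = set$state) {
  spectra_set(matrix, wavelengths, sample_ids, state)
}

#' Subset a spectra_set by sample
#'
#' @param set a `spectra_set`.
#' @param idx logical, integer or character (sample id) index.
#' @return A `spectra_set` with the selected rows.
#' @export
subset_samples <- function(set, idx) {
  stopifnot(inherits(set, "spectra_set"))
  if (is.character(idx)) idx <- match(idx, set$sample_ids)
  m <- set$matrix[idx, , drop = FALSE]
  spectra_set(m, set$wavelengths, set$sample_ids[idx], set$state)
}

#' Validate a sample metadata table
#'
#' Sample records carry the per-leaf trait and isotope metadata: `sample_id`,
#' `species`, `leaf_type` (young/mature/stressed), optional `treatment`
#' (label enrichment, permil: 0/10/20; greenhouse design only), `delta15N`
#' (permil vs AIR), `n_content` (% dry mass, > 0), `gwc` (g water / g dry
#' mass, >= 0), `sla` (leaf area per dry mass, > 0) and optional
#' `distance_to_canopy` (m; field design only).
#'
#' @param records a data.frame of sample records.
#' @return The validated data.frame (invisibly unchanged).
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "species", "leaf_type", "delta15N",
            "n_content", "gwc", "sla")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$sample_id))
    stop("duplicate sample_id in metadata")
  bad_type <- setdiff(unique(as.character(records$leaf_type)),
                      c("young", "mature", "stressed", NA))
  if (length(bad_type))
    stop("unknown leaf_type: ", paste(bad_type, collapse = ", "))
  if (any(records$n_content <= 0, na.rm = TRUE)) stop("n_content must be > 0")
  if (any(records$gwc < 0, na.rm = TRUE)) stop("gwc must be >= 0")
  if (any(records$sla <= 0, na.rm = TRUE)) stop("sla must be > 0")
  if ("treatment" %in% names(records)) {
    tr <- records$treatment[!is.na(records$treatment)]
    if (length(tr) && !all(tr %in% c(0, 10, 20)))
      stop("treatment must be one of 0, 10, 20 (permil enrichment)")
  }
  invisible(records)
}

#' Read a wide spectral table and its metadata
#'
#' The spectra file is a wide CSV: first column `sample_id`, remaining column
#' headers integer wavelengths in nm. An optional leading comment line
#' `# state: <tag>` records the processing state. The metadata CSV is keyed
#' by `sample_id`. Samples present in exactly one of the two files are
#' reported (message) and dropped; the join never invents records.
#'
#' @param path spectra CSV path.
#' @param metadata_path metadata CSV path.
#' @return A list with elements `spectra` (a [spectra_set]), `records`
#'   (data.frame, row order matching the set) and `orphans` (dropped ids).
#' @export
read_spectra_table <- function(path, metadata_path) {
  header <- readLines(path, n = 1L)
  state <- "raw"
  if (startsWith(header, "#")) {
    m <- regmatches(header, regexec("#\\s*state:\\s*(\\S+)", header))[[1L]]
    if (length(m) == 2L) state <- m[2L]
  }
  tab <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                         colClasses = "character")
  if (names(tab)[1L] != "sample_id")
    stop("first column of spectra table must be 'sample_id'")
  wl_chr <- names(tab)[-1L]
  wl <- suppressWarnings(as.numeric(wl_chr))
  if (any(is.na(wl)))
    stop("non-numeric wavelength header: ",
         paste(wl_chr[is.na(wl)], collapse = ", "))
  if (any(wl != round(wl)))
    stop("non-integer wavelength header on the 1-nm grid: ",
         paste(wl_chr[wl != round(wl)], collapse = ", "))
  ids <- tab$sample_id
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s'",
                 ids[bad[1L]], wl_chr[bad[2L]]))
  }
  set <- spectra_set(num, wl, ids, state = state)

  records <- utils::read.csv(metadata_path, check.names = FALSE)
  validate_records(records)

  common <- intersect(set$sample_ids, records$sample_id)
  orphans <- union(setdiff(set$sample_ids, common),
                   setdiff(records$sample_id, common))
  if (length(orphans))
    message("dropping ", length(orphans),
            " sample(s) present in only one file: ",
            paste(orphans, collapse = ", "))
  if (!length(common)) stop("no samples shared between spectra and metadata")
  set <- subset_samples(set, common)
  records <- records[match(common, records$sample_id), , drop = FALSE]
  rownames(records) <- NULL
  list(spectra = set, records = records, orphans = orphans)
}

#' Write a spectra_set and its metadata to CSV
#'
#' Values are printed at full double precision (`%.17g`) so that
#' `read_spectra_table(write_spectra_table(x))` round-trips bit-for-bit.
#' The processing state is recorded in a leading `# state:` comment line.
#'
#' @param set a [spectra_set].
#' @param records matching metadata data.frame.
#' @param path output spectra CSV path.
#' @param metadata_path output metadata CSV path.
#' @return Invisibly, the two paths.
#' @export
write_spectra_table <- function(set, records, path,
                                metadata_path = sub("\\.csv$", "_metadata.csv",
                                                    path)) {
  stopifnot(inherits(set, "spectra_set"))
  if (nrow(set$matrix) == 0L) stop("refusing to write an empty spectra_set")
  validate_records(records)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# state: %s", set$state), con)
  writeLines(paste(c("sample_id", set$wavelengths), collapse = ","), con)
  for (i in seq_len(nrow(set$matrix))) {
    writeLines(paste(c(set$sample_ids[i],
                       sprintf("%.17g", set$matrix[i, ])), collapse = ","),
               con)
  }
  utils::write.csv(records, metadata_path, row.names = FALSE)
  invisible(c(path, metadata_path))
}

#' Exclude unlabeled mature leaves of one species
#'
#' In a labeling design, leaves that failed to incorporate label must be
#' dropped so that leaf age cannot proxy for the isotope signal: this removes
#' every sample of the given species whose leaf type is `mature`.
#'
#' @param set a [spectra_set].
#' @param records matching metadata data.frame.
#' @param species_label species whose mature leaves are excluded.
#' @return list with `spectra`, `records` (filtered) and `count_removed`.
#' @export
exclude_unlabeled_mature <- function(set, records, species_label) {
  stopifnot(inherits(set, "spectra_set"))
  validate_records(records)
  if (!species_label %in% records$species) {
    warning("species '", species_label, "' not present; nothing removed")
    return(list(spectra = set, records = records, count_removed = 0L))
  }
  drop <- records$species == species_label & records$leaf_type == "mature"
  n_rm <- sum(drop)
  if (n_rm == nrow(records)) stop("filter would remove every sample")
  keep_ids <- records$sample_id[!drop]
  set <- subset_samples(set, match(keep_ids, set$sample_ids))
  records <- records[!drop, , drop = FALSE]
  rownames(records) <- NULL
  list(spectra = set, records = records, count_removed = n_rm)
}
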