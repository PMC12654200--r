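#' Read a wide-format spectra CSV
#'
#' The exchange format is a comma-separated, UTF-8 table whose header is
#' exactly `donor_id,replicate_id,group,<nu1>,<nu2>,...` with the remaining
#' column names numeric wavenumbers in strictly ascending order; each data
#' row is one spectrum.
#'
#' @param path Path to a CSV file.
#' @return A [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("donor_id", "replicate_id", "group")
  if (ncol(df) < 5L || !identical(names(df)[1:3], need))
    stop("header must begin donor_id,replicate_id,group followed by wavenumbers",
         call. = FALSE)
  grid <- suppressWarnings(as.numeric(names(df)[-(1:3)]))
  if (anyNA(grid))
    stop("non-numeric wavenumber column name in header", call. = FALSE)
  if (any(diff(grid) <= 0))
    stop("wavenumber columns are not strictly ascending", call. = FALSE)
  raw <- as.matrix(df[, -(1:3), drop = FALSE])
  mat <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric absorbance at row %d, wavenumber %s",
                 bad[1L], names(df)[-(1:3)][bad[2L]]), call. = FALSE)
  }
  key <- paste(df$donor_id, df$replicate_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop(sprintf("duplicate (donor_id, replicate_id): %s",
                 gsub("\r", "/", d)), call. = FALSE)
  }
  spectra_set(grid, mat, df[, 1:3])
}

#' Write a spectra set as wide-format CSV
#'
#' Inverse of [read_spectra_csv()]: wavenumber column names are printed with
#' at most 4 decimals; absorbance values at full double precision so that a
#' write/read round trip reproduces the matrix to better than 1e-12.
#'
#' @param set A [spectra_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  hdr <- c("donor_id", "replicate_id", "group",
           formatC(set$grid, format = "fg", digits = 4, drop0trailing = TRUE))
  body <- cbind(set$meta$donor_id, set$meta$replicate_id, set$meta$group,
                matrix(formatC(set$matrix, format = "g", digits = 17),
                       nrow = nrow(set$matrix)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con)
  writeLines(apply(body, 1L, paste, collapse = ","), con)
  invisible(path)
}
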