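#' Read and write beta matrices as TSV
#'
#' The on-disk convention is a TSV whose first column `probe_id` holds probe
#' IDs and whose remaining columns are samples; values are methylation
#' fractions in \[0, 1\].
#'
#' @param path File path.
#' @param betas Probes x samples numeric matrix with dimnames.
#' @return `read_beta_matrix()`: the matrix; `write_beta_matrix()`: `path`,
#'   invisibly.
#' @export
read_beta_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), .default = readr::col_double()
  ))
  if (!"probe_id" %in% names(tbl)) {
    stop_dnamtraj("beta TSV must have a probe_id first column.",
                  class = "dnamtraj_format_error")
  }
  m <- as.matrix(tbl[setdiff(names(tbl), "probe_id")])
  rownames(m) <- tbl$probe_id
  check_beta_matrix(m)
  m
}

#' @rdname read_beta_matrix
#' @export
write_beta_matrix <- function(betas, path) {
  check_beta_matrix(betas)
  tbl <- tibble::as_tibble(betas, rownames = "probe_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' Read a sample sheet CSV/TSV
#'
#' Expects at least sample_id, participant_id, tissue, day and age columns;
#' derives `time_bin` if absent.
#'
#' @param path File path (.csv or .tsv by extension).
#' @return Tibble.
#' @export
read_sample_sheet <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  sheet <- reader(path, show_col_types = FALSE)
  need <- c("sample_id", "participant_id", "tissue", "day", "age")
  missing <- setdiff(need, names(sheet))
  if (length(missing)) {
    stop_dnamtraj(paste0("sample sheet lacks column(s): ",
                         paste(missing, collapse = ", ")),
                  class = "dnamtraj_format_error")
  }
  if (!"time_bin" %in% names(sheet)) {
    sheet$time_bin <- assign_time_bin(sheet$day)
  }
  sheet
}
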