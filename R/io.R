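#' Read and write trajectory and kick-table CSV files
#'
#' Trajectory files carry columns `time_s`, `fish_id`, `x_mm`, `y_mm`
#' (50 Hz by default); kick tables carry `t_s`, `fish_id`, `x_mm`,
#' `y_mm`, `phi_rad`, `dphi_rad`, `v_peak_mm_s`, `l_mm`, `tau_s`,
#' `r_w_mm`, `theta_w_rad` and, for two-fish records, `d_mm`,
#' `psi_rad`, `dphi_pair_rad`. Files are plain comma-separated text
#' with a mandatory header row and `.` as decimal mark.
#'
#' @param path File path.
#' @param data Tibble to write.
#' @param radius_mm Arena radius (mm), stored only as an attribute on
#'   read for downstream defaults.
#' @return `read_*` return tibbles; `write_*` return `data` invisibly.
#' @name kick_io
NULL

#' @rdname kick_io
#' @export
read_trajectory <- function(path, radius_mm = NULL) {
  out <- read_csv_file(path)
  need_cols(out, c("time_s", "fish_id", "x_mm", "y_mm"))
  if (!is.null(radius_mm)) attr(out, "radius_mm") <- radius_mm
  out
}

#' @rdname kick_io
#' @export
write_trajectory <- function(data, path) {
  need_cols(data, c("time_s", "fish_id", "x_mm", "y_mm"))
  utils::write.csv(data, path, row.names = FALSE)
  invisible(data)
}

#' @rdname kick_io
#' @export
read_kicks <- function(path, radius_mm = NULL) {
  out <- read_csv_file(path)
  need_cols(out, c("t_s", "fish_id", "x_mm", "y_mm", "phi_rad",
                   "dphi_rad", "l_mm", "tau_s"))
  if (!is.null(radius_mm)) attr(out, "radius_mm") <- radius_mm
  out
}

#' @rdname kick_io
#' @export
write_kicks <- function(data, path) {
  need_cols(data, c("t_s", "fish_id", "x_mm", "y_mm", "phi_rad",
                    "dphi_rad", "l_mm", "tau_s"))
  utils::write.csv(data, path, row.names = FALSE)
  invisible(data)
}

read_csv_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (requireNamespace("readr", quietly = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    tibble::as_tibble(utils::read.csv(path))
  }
}
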