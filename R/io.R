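#' Read / write timestamped streams as TSV
#'
#' Streams are plain tab-separated text: column 1 `time` (seconds), then
#' the channel columns (`ch01`...`ch32` for EMG) or DOF columns
#' (`dof1..3`, degrees) named in the header. The same layout is used for
#' raw EMG, normalized IEMG and angle streams.
#'
#' @param x Stream tibble.
#' @param path File path.
#' @return `write_stream_tsv` returns `path` invisibly; `read_stream_tsv`
#'   returns a tibble.
#' @export
write_stream_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname write_stream_tsv
#' @export
read_stream_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Read / write an MVC normalization profile as TSV
#'
#' One row per channel with its integrated-MVC `min` and `max`.
#'
#' @param profile An [compute_mvc_profile()] tibble.
#' @param path File path.
#' @return `write_mvc_profile` returns `path` invisibly; `read_mvc_profile`
#'   returns an `mvc_profile` tibble.
#' @export
write_mvc_profile <- function(profile, path) {
  readr::write_tsv(profile, path)
  invisible(path)
}

#' @rdname write_mvc_profile
#' @export
read_mvc_profile <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("channel", "min", "max") %in% names(out))) {
    abort("MVC profile needs columns channel, min, max.")
  }
  if (any(out$max <= out$min)) abort("MVC profile has max <= min.")
  class(out) <- c("mvc_profile", class(out))
  out
}
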