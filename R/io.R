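#' Write / read a simulated trajectory as CSV
#'
#' The CSV holds the time column and one rate column per population; the
#' reader restores the `cctc_trajectory` class and its `dt` attribute.
#'
#' @param traj A `cctc_trajectory`.
#' @param file Path.
#' @return `write_trajectory_csv()` returns `file` invisibly;
#'   `read_trajectory_csv()` returns a `cctc_trajectory`.
#' @export
write_trajectory_csv <- function(traj, file) {
  write.csv(as.data.frame(traj), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(file) {
  d <- as_tibble(read.csv(file))
  dt <- mean(diff(d$time))
  structure(d, class = c("cctc_trajectory", class(tibble())),
            dt = dt, method = "imported", drive_label = "imported")
}

#' Write an fNIRS session to CSV with a YAML sidecar
#'
#' The intensity data go to `<prefix>.csv` (long format: time, channel,
#' wavelength, intensity) and the metadata (channel table, wavelengths,
#' sample rate, block design) to `<prefix>.yaml`. Ground truth, if present,
#' is not exported.
#'
#' @param session An `fnirs_session`.
#' @param prefix Path prefix without extension.
#' @return The two file paths, invisibly.
#' @export
write_fnirs_csv <- function(session, prefix) {
  csv <- paste0(prefix, ".csv")
  meta <- paste0(prefix, ".yaml")
  write.csv(as.data.frame(session$intensity), csv, row.names = FALSE)
  yaml::write_yaml(list(
    fs = session$fs,
    wavelengths = session$wavelengths,
    design = session$design,
    channels = lapply(seq_len(nrow(session$channels)), function(i) {
      as.list(session$channels[i, ])
    })), meta)
  invisible(c(csv, meta))
}

#' @rdname write_fnirs_csv
#' @export
read_fnirs_csv <- function(prefix) {
  csv <- paste0(prefix, ".csv")
  meta <- paste0(prefix, ".yaml")
  m <- yaml::read_yaml(meta)
  channels <- dplyr::bind_rows(lapply(m$channels, function(ch) {
    ch$short_partner <- ch$short_partner %||% NA_character_
    as_tibble(ch)
  }))
  structure(list(channels = channels,
                 wavelengths = unlist(m$wavelengths),
                 fs = m$fs, design = m$design,
                 intensity = as_tibble(read.csv(csv)),
                 truth = NULL),
            class = "fnirs_session")
}
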