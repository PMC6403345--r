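# Plain-text I/O: one TSV matrix per subject x cell, an sfp-style montage
# file, and a JSON manifest tying them together.

#' Write / read a montage in sfp-style text format
#'
#' One whitespace-delimited `label x y z` record per channel.
#'
#' @param mont a [montage()].
#' @param path file path.
#' @return `read_montage_sfp` returns a [montage()].
#' @export
write_montage_sfp <- function(mont, path) {
  stopifnot(inherits(mont, "montage"))
  df <- data.frame(label = mont$labels, mont$positions)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_montage_sfp
#' @export
read_montage_sfp <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("label", "x", "y", "z"))
  montage(df$label, as.matrix(df[, c("x", "y", "z")]))
}

#' Write a study dataset as a directory of text files
#'
#' Emits `montage.sfp`, `manifest.json` (subjects, cells, sfreq, t0, file
#' paths) and one TSV per subject x cell with channels as rows and a header
#' row of times in ms.
#'
#' @param ds a [study_dataset()].
#' @param dir target directory (created if needed).
#' @return `read_study` returns a [study_dataset()].
#' @export
write_study <- function(ds, dir) {
  stopifnot(inherits(ds, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_montage_sfp(ds$montage, file.path(dir, "montage.sfp"))
  tms <- times_ms(dim(ds$data)[2L], ds$sfreq, ds$t0)
  files <- list()
  for (s in ds$subjects) {
    for (cell in CELLS) {
      fn <- sprintf("%s_%s.tsv", s, cell)
      m <- ds$data[, , s, cell]
      colnames(m) <- sprintf("%.6g", tms)
      utils::write.table(cbind(channel = ds$montage$labels, as.data.frame(m)),
                         file.path(dir, fn), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files[[paste(s, cell, sep = ".")]] <- fn
    }
  }
  manifest <- list(subjects = ds$subjects, cells = CELLS, sfreq = ds$sfreq,
                   t0 = ds$t0, montage = "montage.sfp", files = files)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_study
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  mont <- read_montage_sfp(file.path(dir, manifest$montage))
  subjects <- manifest$subjects
  probe <- utils::read.table(file.path(dir, manifest$files[[1L]]),
                             header = TRUE, sep = "\t", check.names = FALSE)
  n_times <- ncol(probe) - 1L
  data <- array(NA_real_, c(length(mont$labels), n_times, length(subjects), 4L))
  for (si in seq_along(subjects)) {
    for (ci in seq_along(CELLS)) {
      fn <- manifest$files[[paste(subjects[si], CELLS[ci], sep = ".")]]
      df <- utils::read.table(file.path(dir, fn), header = TRUE, sep = "\t",
                              check.names = FALSE)
      stopifnot(identical(as.character(df$channel), mont$labels))
      data[, , si, ci] <- as.matrix(df[, -1L])
    }
  }
  study_dataset(data, mont, manifest$sfreq, manifest$t0, subjects)
}
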