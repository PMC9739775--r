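# Reading and writing single-channel EEG in the Bonn ASCII dialect
# (one numeric sample per line, no header, one file per recording).

#' Construct a single-channel EEG recording
#'
#' @param samples numeric vector of amplitude values (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param label class symbol, one of [BONN_CLASSES].
#' @param source_id string identifier for provenance.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, fs, label, source_id = "recording") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || anyNA(samples)) {
    stop("a recording needs at least one sample and no missing values")
  }
  stopifnot_scalar_pos(fs, "fs")
  label <- toupper(as.character(label))
  if (length(label) != 1L || !label %in% BONN_CLASSES) {
    stop("label must be one of ", paste(BONN_CLASSES, collapse = "/"))
  }
  structure(
    list(samples = samples, fs = fs, label = label,
         source_id = as.character(source_id)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording %s> class %s, %d samples @ %.2f Hz (%.2f s)\n",
              x$source_id, x$label, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds (`n_samples / fs`).
#' @export
recording_duration <- function(rec) length(rec$samples) / rec$fs

#' Read one Bonn-dialect ASCII recording
#'
#' The Bonn dialect is plain text with one numeric amplitude per line and
#' no header. Blank lines and surrounding whitespace are ignored.
#'
#' @param path file to read.
#' @param label class symbol to attach.
#' @param fs sampling rate in Hz (default [BONN_FS]).
#' @param source_id identifier; defaults to the file's base name.
#' @return an `eeg_recording`.
#' @export
read_bonn_recording <- function(path, label, fs = BONN_FS,
                                source_id = basename(path)) {
  if (!file.exists(path)) stop("cannot read recording file: ", path)
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed)
  if (!any(keep)) stop("empty recording file: ", path)
  values <- suppressWarnings(as.numeric(trimmed[keep]))
  if (anyNA(values)) {
    bad_line <- which(keep)[which(is.na(values))[1L]]
    stop(sprintf("non-numeric sample at line %d of %s: '%s'",
                 bad_line, path, lines[bad_line]))
  }
  recording(values, fs = fs, label = label, source_id = source_id)
}

#' Write one recording in the Bonn ASCII dialect
#'
#' Samples are printed with full double precision (`%.17g`), so a
#' write/read round trip reproduces them exactly.
#'
#' @param rec an `eeg_recording`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_bonn_recording <- function(rec, path) {
  writeLines(sprintf("%.17g", rec$samples), path)
  invisible(path)
}

#' Construct a labelled recording set
#'
#' @param recordings list of `eeg_recording` objects.
#' @return an `eeg_recording_set` with a `class_counts` table over the
#'   canonical five classes.
#' @export
recording_set <- function(recordings) {
  if (!length(recordings)) stop("recording set must be non-empty")
  ok <- vapply(recordings, inherits, logical(1), "eeg_recording")
  if (!all(ok)) stop("all elements must be eeg_recording objects")
  labels <- vapply(recordings, function(r) r$label, character(1))
  counts <- table(factor(labels, levels = BONN_CLASSES))
  structure(list(recordings = recordings, class_counts = counts),
            class = "eeg_recording_set")
}

#' @export
print.eeg_recording_set <- function(x, ...) {
  cat(sprintf("<eeg_recording_set> %d recordings\n", length(x$recordings)))
  print(x$class_counts)
  invisible(x)
}

#' Load a five-class Bonn-dialect dataset from disk
#'
#' Looks first for subdirectories named after the class symbols
#' (case-insensitive); if no class subdirectory exists, files directly
#' under `root` are grouped by the first letter of their name. File order
#' within a class is lexicographic, so downstream seeded runs are
#' reproducible.
#'
#' @param root dataset directory.
#' @param fs sampling rate in Hz applied to every file.
#' @return an `eeg_recording_set` (100 recordings per class for the full
#'   Bonn distribution).
#' @export
load_bonn_dataset <- function(root, fs = BONN_FS) {
  if (!dir.exists(root)) stop("dataset directory not found: ", root)
  subdirs <- list.dirs(root, recursive = FALSE)
  names(subdirs) <- toupper(basename(subdirs))
  files_for <- function(cl) {
    if (cl %in% names(subdirs)) {
      sort(list.files(subdirs[[cl]], full.names = TRUE))
    } else {
      all_files <- sort(list.files(root, full.names = FALSE))
      all_files <- all_files[!dir.exists(file.path(root, all_files))]
      file.path(root, all_files[toupper(substr(all_files, 1L, 1L)) == cl])
    }
  }
  per_class <- lapply(BONN_CLASSES, files_for)
  names(per_class) <- BONN_CLASSES
  found <- BONN_CLASSES[lengths(per_class) > 0L]
  missing <- setdiff(BONN_CLASSES, found)
  if (length(missing) > 0L) {
    stop(sprintf("missing class group(s) %s under %s (found: %s)",
                 paste(missing, collapse = ", "), root,
                 if (length(found)) paste(found, collapse = ", ") else "none"))
  }
  recs <- list()
  for (cl in BONN_CLASSES) {
    for (f in per_class[[cl]]) {
      recs[[length(recs) + 1L]] <- read_bonn_recording(f, label = cl, fs = fs)
    }
  }
  recording_set(recs)
}

#' Write a recording set as a Bonn-dialect directory tree
#'
#' Creates one subdirectory per class under `root`, writes each recording
#' as an ASCII file named after its `source_id`, and writes a
#' `manifest.csv` at the top level.
#'
#' @param set an `eeg_recording_set`.
#' @param root destination directory (created if needed).
#' @return `root`, invisibly.
#' @export
write_bonn_dataset <- function(set, root) {
  for (rec in set$recordings) {
    dir_path <- file.path(root, rec$label)
    dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
    fname <- rec$source_id
    if (!grepl("\\.txt$", fname, ignore.case = TRUE)) fname <- paste0(fname, ".txt")
    write_bonn_recording(rec, file.path(dir_path, fname))
  }
  write_manifest(set, file.path(root, "manifest.csv"))
  invisible(root)
}

#' Write a dataset manifest CSV
#'
#' Columns: `source_id,label,n_samples,fs`.
#'
#' @param set an `eeg_recording_set`.
#' @param path destination CSV file.
#' @return the manifest data frame, invisibly.
#' @export
write_manifest <- function(set, path) {
  manifest <- data.frame(
    source_id = vapply(set$recordings, function(r) r$source_id, character(1)),
    label = vapply(set$recordings, function(r) r$label, character(1)),
    n_samples = vapply(set$recordings, function(r) length(r$samples), integer(1)),
    fs = vapply(set$recordings, function(r) r$fs, numeric(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(manifest)
}
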