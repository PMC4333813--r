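# Plain-text (and optional float32 binary) readers/writers. All formats
# round-trip losslessly through these functions.
#
# Recording: two files — a header (key<TAB>value lines: fs, n_channels,
# n_samples, channels (space-separated), data_format "text" or "float32",
# data_file) and a data file. Text data: one row per sample, one column per
# channel, tab-delimited, full precision. Binary data: little-endian 32-bit
# floats, sample-major (channel fastest), documented bit-exactly.

#' Write a hypnogram file
#'
#' Two-column delimited text `epoch_index stage` with a header line; epoch
#' indices are 1-based and consecutive.
#'
#' @param hyp A [hypnogram()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_length_s\t%.10g", hyp$epoch_length), con)
  writeLines("epoch_index\tstage", con)
  writeLines(sprintf("%d\t%d", seq_along(hyp$stages), hyp$stages), con)
  invisible(path)
}

#' Read a hypnogram file
#'
#' @param path Path written by [write_hypnogram()] (or any file in the same
#'   layout).
#' @param epoch_length Epoch length override; by default taken from the
#'   `# epoch_length_s` comment, falling back to 20 s.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_length = NULL) {
  lines <- readLines(path)
  if (is.null(epoch_length)) {
    hl <- grep("^# epoch_length_s\t", lines, value = TRUE)
    epoch_length <- if (length(hl)) as.numeric(sub("^# epoch_length_s\t", "", hl[1]))
                    else 20
  }
  keep <- !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 2L) stop("hypnogram file has no data rows")
  body <- lines[-1L]
  lineno <- lineno[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 2L || anyNA(suppressWarnings(as.numeric(p))))
      stop("malformed hypnogram row at line ", lineno[i], ": '", body[i], "'")
    if (!as.integer(p[2L]) %in% 0:5)
      stop("invalid stage code ", p[2L], " at line ", lineno[i])
  }
  stages <- vapply(parts, function(p) as.integer(p[2L]), integer(1))
  hypnogram(stages, epoch_length)
}

#' Write an annotation file
#'
#' Tab-delimited `channel onset_s duration_s` with a header line.
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("channel\tonset_s\tduration_s", con)
  if (nrow(ann))
    writeLines(sprintf("%s\t%.10g\t%.10g", ann$channel, ann$onset, ann$duration),
               con)
  invisible(path)
}

#' Read an annotation file
#'
#' @param path Path written by [write_annotations()].
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty annotation file")
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) return(annotation_set())
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    ok <- length(p) == 3L && !anyNA(suppressWarnings(as.numeric(p[2:3])))
    if (ok) {
      ok <- as.numeric(p[2L]) >= 0 && as.numeric(p[3L]) > 0
    }
    if (!ok) stop("malformed annotation row at line ", i + 1L, ": '", body[i], "'")
  }
  annotation_set(vapply(parts, `[`, "", 1L),
                 vapply(parts, function(p) as.numeric(p[2L]), 0),
                 vapply(parts, function(p) as.numeric(p[3L]), 0))
}

#' Write a recording (header + data file)
#'
#' @param recording An [eeg_recording()].
#' @param prefix Path prefix; writes `<prefix>.hdr` plus `<prefix>.dat`
#'   (binary) or `<prefix>.tsv` (text).
#' @param format `"float32"` (little-endian 32-bit floats, sample-major) or
#'   `"text"` (tab-delimited, one sample per row).
#' @return The header path, invisibly.
#' @export
write_recording <- function(recording, prefix, format = c("float32", "text")) {
  stopifnot(inherits(recording, "eeg_recording"))
  format <- match.arg(format)
  data_file <- paste0(basename(prefix), if (format == "float32") ".dat" else ".tsv")
  hdr <- paste0(prefix, ".hdr")
  con <- file(hdr, "w")
  writeLines(c(sprintf("fs\t%.10g", recording$fs),
               sprintf("n_channels\t%d", nrow(recording$samples)),
               sprintf("n_samples\t%d", ncol(recording$samples)),
               paste0("channels\t", paste(recording$channel_names, collapse = " ")),
               paste0("data_format\t", format),
               paste0("data_file\t", data_file)), con)
  close(con)
  dpath <- file.path(dirname(hdr), data_file)
  if (format == "float32") {
    bc <- file(dpath, "wb")
    writeBin(as.numeric(recording$samples), bc, size = 4L, endian = "little")
    close(bc)
  } else {
    con2 <- file(dpath, "w")
    writeLines(paste(recording$channel_names, collapse = "\t"), con2)
    # full double precision so the text dialect round-trips losslessly
    body <- apply(recording$samples, 2L,
                  function(col) paste(sprintf("%.17g", col), collapse = "\t"))
    writeLines(body, con2)
    close(con2)
  }
  invisible(hdr)
}

#' Read a recording written by [write_recording()]
#'
#' @param hdr Path to the `.hdr` header file.
#' @param layout Channel layout (default bundled 10-5 layout).
#' @return An [eeg_recording()].
#' @export
read_recording <- function(hdr, layout = default_layout()) {
  lines <- readLines(hdr)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  val <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("recording header missing field '", k, "'")
    kv[[i]][2L]
  }
  fs <- as.numeric(val("fs"))
  nc <- as.integer(val("n_channels"))
  nt <- as.integer(val("n_samples"))
  channels <- strsplit(val("channels"), " ", fixed = TRUE)[[1L]]
  fmt <- val("data_format")
  dpath <- file.path(dirname(hdr), val("data_file"))
  if (fmt == "float32") {
    bc <- file(dpath, "rb")
    x <- readBin(bc, "numeric", n = nc * nt, size = 4L, endian = "little")
    close(bc)
    S <- matrix(x, nrow = nc, ncol = nt)
  } else if (fmt == "text") {
    tab <- utils::read.table(dpath, header = TRUE, sep = "\t",
                             check.names = FALSE)
    S <- t(as.matrix(tab))
  } else stop("unknown recording data_format '", fmt, "'")
  eeg_recording(S, channels, fs, layout)
}

#' Write a feature/event table
#'
#' Tab-delimited with header, full double precision.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(tab, path) {
  num <- vapply(tab, is.numeric, TRUE)
  out <- tab
  out[num] <- lapply(tab[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature/event table
#'
#' @param path Path written by [write_event_table()].
#' @return Data frame.
#' @export
read_event_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a simulated polysomnogram to a directory
#'
#' Writes `recording.hdr` + data, `hypnogram.tsv`, `annotations.tsv` and
#' `ground_truth.tsv`; all round-trip losslessly through the package readers
#' (bit-exactly for the float32 recording dialect).
#'
#' @param sim A `"sim_psg"` from [simulate_psg()].
#' @param dir Output directory (created if needed).
#' @param format Recording data format, see [write_recording()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(sim, dir, format = "float32") {
  stopifnot(inherits(sim, "sim_psg"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_recording(sim$recording, file.path(dir, "recording"), format)
  write_hypnogram(sim$hypnogram, file.path(dir, "hypnogram.tsv"))
  write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  write_event_table(sim$ground_truth, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @param layout Channel layout.
#' @return List with `recording`, `hypnogram`, `annotations`, `ground_truth`.
#' @export
read_fixture <- function(dir, layout = default_layout()) {
  list(recording = read_recording(file.path(dir, "recording.hdr"), layout),
       hypnogram = read_hypnogram(file.path(dir, "hypnogram.tsv")),
       annotations = read_annotations(file.path(dir, "annotations.tsv")),
       ground_truth = read_event_table(file.path(dir, "ground_truth.tsv")))
}
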