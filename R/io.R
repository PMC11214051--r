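#' Write / read the epoch container
#'
#' Epoch arrays are serialized as RDS with named axes and the trial
#' metadata table; the round trip is bit-exact.
#'
#' @param epochs an `epoch_array`
#' @param path file path (conventionally `.epochs.rds`)
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_array"))
  saveRDS(epochs, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "epoch_array")) stop("not an epoch container: ", path)
  need <- c("data", "times", "channel_labels", "trial_meta")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("epoch container lacks field(s): ", paste(miss, collapse = ", "))
  x
}

#' Write / read an RDM archive
#'
#' A time x item x item array (time may be a single slice) together
#' with the item ordering, the dissimilarity kind and a configuration
#' echo.  Round trips are bit-exact.
#'
#' @param values numeric array (time x item x item) or matrix (item x
#'   item)
#' @param items ordered item identifiers
#' @param dissimilarity_kind one of "decoding_accuracy",
#'   "abs_rating_diff", "cosine_ltas", "abs_pc_diff"
#' @param path file path
#' @param times optional time axis (ms)
#' @param config optional configuration echo
#' @export
write_rdm_archive <- function(values, items, dissimilarity_kind, path,
                              times = NULL, config = NULL) {
  kinds <- c("decoding_accuracy", "abs_rating_diff", "cosine_ltas",
             "abs_pc_diff")
  if (!dissimilarity_kind %in% kinds)
    stop("unknown dissimilarity kind: ", dissimilarity_kind)
  if (is.matrix(values)) values <- array(values, c(1, dim(values)))
  if (length(dim(values)) != 3 || dim(values)[2] != dim(values)[3] ||
      dim(values)[2] != length(items))
    stop("values must be time x item x item with one entry per item")
  saveRDS(structure(list(values = values, items = items,
                         dissimilarity_kind = dissimilarity_kind,
                         times = times, config = config),
                    class = "rdm_archive"), path)
  invisible(path)
}

#' @rdname write_rdm_archive
#' @export
read_rdm_archive <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "rdm_archive")) stop("not an RDM archive: ", path)
  x
}

#' Write / read a ratings CSV
#'
#' Long format with columns `rater_id`, `stimulus_id`,
#' `characteristic`, `rating`; ratings are validated as integers in
#' [1, 9] on read and write.
#'
#' @param ratings a `rating_table`
#' @param path file path
#' @export
write_ratings_csv <- function(ratings, path) {
  validate_rating_table(ratings)
  write.csv(as.data.frame(ratings), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ratings_csv
#' @export
read_ratings_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  validate_rating_table(x)
  structure(x, class = c("rating_table", "data.frame"))
}

#' Write / read PCM16 mono WAV
#'
#' Minimal RIFF/WAVE support for mono 16-bit PCM, sufficient for short
#' voice recordings.
#'
#' @param waveform numeric vector in [-1, 1]
#' @param sfreq sampling frequency (Hz)
#' @param path file path
#' @export
write_wav <- function(waveform, sfreq, path) {
  pcm <- as.integer(pmax(-32767, pmin(32767, round(waveform * 32767))))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")  # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")  # mono
  writeBin(as.integer(sfreq), con, size = 4, endian = "little")
  writeBin(as.integer(sfreq * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' @rdname write_wav
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  sfreq <- NULL; data <- NULL
  repeat {
    id <- readChar(con, 4)
    if (!length(id) || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little")
      if (fmt[1] != 1 || fmt[2] != 1)
        stop("only mono PCM WAV is supported")
      sfreq <- readBin(con, "integer", 1, 4, endian = "little")
      invisible(readBin(con, "raw", sz - 8))
    } else if (id == "data") {
      data <- readBin(con, "integer", sz / 2, 2, signed = TRUE,
                      endian = "little")
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (!is.null(sfreq) && !is.null(data)) break
  }
  if (is.null(sfreq) || is.null(data)) stop("malformed WAV: ", path)
  list(waveform = data / 32767, sfreq = sfreq)
}

#' Write a long time-course table as CSV
#'
#' @param timecourses long data.frame from [run_all_models()]
#' @param path file path
#' @export
write_timecourses_csv <- function(timecourses, path) {
  need <- c("participant", "characteristic", "model", "time_ms", "rho")
  miss <- setdiff(need, names(timecourses))
  if (length(miss))
    stop("time-course table lacks column(s): ",
         paste(miss, collapse = ", "))
  write.csv(timecourses, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_timecourses_csv
#' @export
read_timecourses_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "characteristic", "model", "time_ms", "rho")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("time-course table lacks column(s): ",
         paste(miss, collapse = ", "))
  x
}
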