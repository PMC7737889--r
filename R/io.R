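# --- delimited interchange formats -------------------------------------
# recording matrix: UTF-8 TSV, header "time_s<TAB>Fz<TAB>Cz<TAB>Pz<TAB>Fp1",
# '.' decimal; events: "onset_s<TAB>label"

#' Write a recording (and its events) to tab-separated files
#'
#' @param rec An [recording()].
#' @param path Sample-matrix file path (`.tsv`); the events file is written
#'   next to it with suffix `_events.tsv` unless `events_path` is given.
#' @param events_path Optional explicit events file path.
#' @return Invisibly, the two paths.
#' @export
write_recording_tsv <- function(rec, path, events_path = NULL) {
  stopifnot(inherits(rec, "olf_recording"))
  n <- nrow(rec$samples)
  tab <- data.frame(time_s = (seq_len(n) - 1) / rec$fs, rec$samples,
                    check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  events_path <- events_path %||% sub("\\.tsv$", "_events.tsv", path)
  write.table(rec$events, events_path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(path, events_path))
}

#' Read a recording from tab-separated files
#'
#' Counterpart of [write_recording_tsv()]. The sampling rate is recovered
#' from the `time_s` column spacing.
#'
#' @param path Sample-matrix file path.
#' @param events_path Events file path (default: `_events.tsv` sibling).
#' @return An [recording()].
#' @export
read_recording_tsv <- function(path, events_path = NULL) {
  tab <- read.delim(path, check.names = FALSE)
  if (names(tab)[1] != "time_s") stop("expected a 'time_s' first column in ", path)
  dt <- diff(tab$time_s[1:2])
  samples <- as.matrix(tab[, -1, drop = FALSE])
  events_path <- events_path %||% sub("\\.tsv$", "_events.tsv", path)
  events <- if (file.exists(events_path)) {
    read.delim(events_path, stringsAsFactors = FALSE)
  } else NULL
  recording(samples, fs = round(1 / dt), events = events)
}

#' Write an epoch set to a single delimited container file
#'
#' The container is plain text: `#`-prefixed metadata lines (sampling rate,
#' window, channel names, per-epoch labels and kept flags) followed by a
#' tab-separated payload with one row per (epoch, sample) and one column
#' per channel.
#'
#' @param epochs An `olf_epochs` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_epochs_tsv <- function(epochs, path) {
  stopifnot(inherits(epochs, "olf_epochs"))
  n_ep <- dim(epochs$data)[1]
  n_samp <- dim(epochs$data)[3]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs=%g", epochs$fs),
    sprintf("# t_pre=%g", epochs$t_pre),
    sprintf("# t_post=%g", epochs$t_post),
    sprintf("# channels=%s", paste(epochs$channel_names, collapse = ",")),
    sprintf("# labels=%s", paste(epochs$labels, collapse = ",")),
    sprintf("# kept=%s", paste(as.integer(epochs$kept), collapse = ","))
  ), con)
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), n_ep * n_samp,
                 dim(epochs$data)[2])
  colnames(flat) <- epochs$channel_names
  tab <- data.frame(epoch = rep(seq_len(n_ep), each = n_samp),
                    sample = rep(seq_len(n_samp) - 1L, n_ep), flat,
                    check.names = FALSE)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an epoch set written by [write_epochs_tsv()]
#'
#' @param path Container file path.
#' @return An `olf_epochs` object.
#' @export
read_epochs_tsv <- function(path) {
  hdr <- character(0)
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    line <- readLines(con, 1)
    if (!length(line) || !startsWith(line, "#")) break
    hdr <- c(hdr, line)
  }
  meta <- sub("^# *", "", hdr)
  get <- function(key) sub(paste0(key, "="), "", meta[startsWith(meta, paste0(key, "="))])
  tab <- read.delim(textConnection(c(line, readLines(con))), check.names = FALSE)
  channels <- strsplit(get("channels"), ",")[[1]]
  labels <- strsplit(get("labels"), ",")[[1]]
  kept <- as.logical(as.integer(strsplit(get("kept"), ",")[[1]]))
  n_ep <- length(labels)
  n_samp <- nrow(tab) / n_ep
  data <- aperm(array(as.matrix(tab[, channels]),
                      c(n_samp, n_ep, length(channels))), c(2, 3, 1))
  structure(list(data = data, fs = as.numeric(get("fs")),
                 t_pre = as.numeric(get("t_pre")),
                 t_post = as.numeric(get("t_post")),
                 channel_names = channels, labels = labels, kept = kept),
            class = "olf_epochs")
}

#' Write a simulated cohort to a directory
#'
#' Writes the cohort table (`cohort.tsv`), the per-subject recordings and
#' event lists (`<id>.tsv`, `<id>_events.tsv`) when present, and the
#' generating configuration (`config.json`) so a run can be reproduced
#' bit-exactly from its output directory.
#'
#' @param sim An [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "olf_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  cfg <- sim$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(sim$recordings)) {
    for (id in names(sim$recordings)) {
      write_recording_tsv(sim$recordings[[id]], file.path(dir, paste0(id, ".tsv")))
    }
  }
  invisible(dir)
}

#' Read a simulated cohort back from a directory
#'
#' @param dir Directory written by [write_cohort()].
#' @param recordings Also load the per-subject recordings.
#' @return An `olf_cohort`-like list with `config`, `cohort` and
#'   `recordings` (profiles are not persisted).
#' @export
read_cohort <- function(dir, recordings = TRUE) {
  cohort <- read.delim(file.path(dir, "cohort.tsv"), stringsAsFactors = FALSE,
                       check.names = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  recs <- NULL
  if (recordings) {
    paths <- file.path(dir, paste0(cohort$subject, ".tsv"))
    have <- file.exists(paths)
    if (any(have)) {
      recs <- lapply(paths[have], read_recording_tsv)
      names(recs) <- cohort$subject[have]
    }
  }
  structure(list(config = cfg, cohort = cohort, recordings = recs),
            class = "olf_cohort")
}
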