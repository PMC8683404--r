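# Session serialisation. HDF5 is the canonical container (raw traces are
# binary); the CSV directory is the human-readable dialect. Both layouts are
# deterministic given identical input: rows are written in sorted key order
# with a fixed float format, so identical sessions produce identical files.

FLOAT_FMT <- "%.10g"

fmt_num <- function(x) sprintf(FLOAT_FMT, x)

#' Write a recording session to disk
#'
#' @param session a valid [recording_session].
#' @param path target path: a directory for `csv_dir`, a file for `hdf5`.
#' @param format `"csv_dir"` or `"hdf5"`.
#' @return `path`, invisibly.
#' @seealso [read_session()]
#' @export
write_session <- function(session, path, format = c("csv_dir", "hdf5")) {
  format <- match.arg(format)
  if (!inherits(session, "recording_session"))
    stopf("write_session needs a recording_session")
  for (st in session$spike_trains) {
    if (anyNA(st$times) || any(!is.finite(st$times)))
      stopf("spike train '%s': non-finite spike time", st$cell_id)
  }
  switch(format,
         csv_dir = write_session_csv(session, path),
         hdf5 = write_session_h5(session, path))
  invisible(path)
}

#' Read a recording session from disk
#'
#' Unknown optional blocks are ignored with a warning; missing mandatory
#' tables and invalid spike times are hard errors.
#'
#' @param path a directory (`csv_dir`) or HDF5 file.
#' @param format `"csv_dir"` or `"hdf5"`.
#' @return A [recording_session].
#' @export
read_session <- function(path, format = c("csv_dir", "hdf5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("path does not exist: %s", path)
  switch(format,
         csv_dir = read_session_csv(path),
         hdf5 = read_session_h5(path))
}

## ---- CSV dialect -----------------------------------------------------------

write_session_csv <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  trains <- session$spike_trains
  if (length(trains)) trains <- trains[order(names(trains))]
  spikes <- if (length(trains)) {
    do.call(rbind, lapply(trains, function(st) {
      if (!length(st$times)) {
        data.frame(cell_id = character(), channel_id = integer(),
                   unit_index = integer(), time_s = character())
      } else {
        data.frame(cell_id = st$cell_id, channel_id = st$channel_id,
                   unit_index = st$unit_index, time_s = fmt_num(st$times))
      }
    }))
  } else {
    data.frame(cell_id = character(), channel_id = integer(),
               unit_index = integer(), time_s = character())
  }
  utils::write.csv(spikes, file.path(path, "spikes.csv"), row.names = FALSE,
                   quote = FALSE)

  protos <- session$protocols
  if (length(protos)) protos <- protos[order(names(protos))]
  ptab <- do.call(rbind, c(list(data.frame(
    protocol_id = character(), kind = character(), amplitude_uA = character(),
    phase_duration_ms = character(), on_duration_s = character(),
    off_duration_s = character(), n_repeats = integer())),
    lapply(protos, function(p) data.frame(
      protocol_id = p$protocol_id, kind = p$kind,
      amplitude_uA = if (p$kind == "electrical") fmt_num(p$amplitude) else "",
      phase_duration_ms = if (p$kind == "electrical") fmt_num(p$phase_duration) else "",
      on_duration_s = if (p$kind == "light") fmt_num(p$on_duration) else "",
      off_duration_s = if (p$kind == "light") fmt_num(p$off_duration) else "",
      n_repeats = length(p$onsets)))))
  utils::write.csv(ptab, file.path(path, "protocols.csv"), row.names = FALSE,
                   quote = FALSE)

  otab <- do.call(rbind, c(list(data.frame(protocol_id = character(),
                                           onset_s = character())),
    lapply(protos, function(p) data.frame(protocol_id = p$protocol_id,
                                          onset_s = fmt_num(p$onsets)))))
  utils::write.csv(otab, file.path(path, "onsets.csv"), row.names = FALSE,
                   quote = FALSE)

  meta <- data.frame(key = c("session_id", "sampling_rate_hz", "group_label"),
                     value = c(session$session_id,
                               fmt_num(session$sampling_rate),
                               session$group_label))
  utils::write.csv(meta, file.path(path, "session.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(session$channel_map, file.path(path, "channel_map.csv"),
                   row.names = FALSE, quote = FALSE)
  # Raw traces are binary-scale data and belong in the HDF5 container only.
  if (!is.null(session$raw_traces))
    warnf("csv_dir format does not store raw traces; dropped on write")
  invisible(path)
}

read_session_csv <- function(path) {
  need <- c("spikes.csv", "protocols.csv", "onsets.csv", "session.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stopf("missing mandatory table '%s' in %s", f, path)
  }
  known <- c(need, "channel_map.csv")
  extra <- setdiff(list.files(path, pattern = "\\.csv$"), known)
  if (length(extra))
    warnf("ignoring unknown blocks: %s", paste(extra, collapse = ", "))

  meta <- utils::read.csv(file.path(path, "session.csv"),
                          colClasses = "character")
  getmeta <- function(k) {
    i <- match(k, meta$key)
    if (is.na(i)) stopf("session.csv is missing key '%s'", k)
    meta$value[i]
  }
  spikes <- utils::read.csv(file.path(path, "spikes.csv"),
                            colClasses = c(cell_id = "character"))
  trains <- list()
  if (nrow(spikes)) {
    for (cid in unique(spikes$cell_id)) {
      rows <- spikes[spikes$cell_id == cid, , drop = FALSE]
      tt <- as.numeric(rows$time_s)
      if (length(tt) && min(tt) < 0)
        stopf("spike train '%s': negative spike time", cid)
      trains[[cid]] <- spike_train(cid, rows$channel_id[1], rows$unit_index[1],
                                   tt)
    }
  }
  ptab <- utils::read.csv(file.path(path, "protocols.csv"),
                          colClasses = c(protocol_id = "character"))
  otab <- utils::read.csv(file.path(path, "onsets.csv"),
                          colClasses = c(protocol_id = "character"))
  protos <- list()
  if (nrow(ptab)) {
    for (i in seq_len(nrow(ptab))) {
      pid <- ptab$protocol_id[i]
      onsets <- as.numeric(otab$onset_s[otab$protocol_id == pid])
      protos[[pid]] <- if (ptab$kind[i] == "electrical") {
        stimulus_protocol(pid, "electrical", onsets,
                          amplitude = as.numeric(ptab$amplitude_uA[i]),
                          phase_duration = as.numeric(ptab$phase_duration_ms[i]))
      } else {
        stimulus_protocol(pid, "light", onsets,
                          on_duration = as.numeric(ptab$on_duration_s[i]),
                          off_duration = as.numeric(ptab$off_duration_s[i]))
      }
    }
  }
  cmap <- if (file.exists(file.path(path, "channel_map.csv"))) {
    utils::read.csv(file.path(path, "channel_map.csv"))
  } else default_channel_map()
  recording_session(getmeta("session_id"), trains, protos,
                    sampling_rate = as.numeric(getmeta("sampling_rate_hz")),
                    channel_map = cmap,
                    group_label = getmeta("group_label"))
}

## ---- HDF5 container --------------------------------------------------------
# Layout: /spikes/<cell_id>/times (float64 s) with attrs channel_id,
# unit_index; /protocols/<protocol_id>/onsets with protocol attrs on the
# group; /raw/<channel_id> optional; root attrs sampling_rate_hz, group_label,
# session_id.

write_session_h5 <- function(session, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(session$session_id, fid, "session_id")
  rhdf5::h5writeAttribute(session$sampling_rate, fid, "sampling_rate_hz")
  rhdf5::h5writeAttribute(session$group_label, fid, "group_label")
  rhdf5::H5Fclose(fid)

  rhdf5::h5createGroup(path, "spikes")
  for (cid in sort(names(session$spike_trains))) {
    st <- session$spike_trains[[cid]]
    g <- paste0("spikes/", cid)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(st$times, path, paste0(g, "/times"))
    gid <- rhdf5::H5Gopen(rhdf5::H5Fopen(path), g)
    rhdf5::h5writeAttribute(st$channel_id, gid, "channel_id")
    rhdf5::h5writeAttribute(st$unit_index, gid, "unit_index")
    rhdf5::H5Gclose(gid)
    rhdf5::h5closeAll()
  }
  rhdf5::h5createGroup(path, "protocols")
  for (pid in sort(names(session$protocols))) {
    p <- session$protocols[[pid]]
    g <- paste0("protocols/", pid)
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(p$onsets, path, paste0(g, "/onsets"))
    gid <- rhdf5::H5Gopen(rhdf5::H5Fopen(path), g)
    rhdf5::h5writeAttribute(p$kind, gid, "kind")
    if (p$kind == "electrical") {
      rhdf5::h5writeAttribute(p$amplitude, gid, "amplitude_uA")
      rhdf5::h5writeAttribute(p$phase_duration, gid, "phase_duration_ms")
    } else {
      rhdf5::h5writeAttribute(p$on_duration, gid, "on_duration_s")
      rhdf5::h5writeAttribute(p$off_duration, gid, "off_duration_s")
    }
    rhdf5::H5Gclose(gid)
    rhdf5::h5closeAll()
  }
  if (!is.null(session$raw_traces)) {
    rhdf5::h5createGroup(path, "raw")
    for (ch in sort(names(session$raw_traces)))
      rhdf5::h5write(session$raw_traces[[ch]], path, paste0("raw/", ch))
  }
  rhdf5::h5write(as.integer(session$channel_map$channel_id), path, "channel_map_id")
  rhdf5::h5write(as.integer(session$channel_map$grid_row), path, "channel_map_row")
  rhdf5::h5write(as.integer(session$channel_map$grid_col), path, "channel_map_col")
  rhdf5::h5write(as.integer(session$channel_map$is_reference), path,
                 "channel_map_ref")
  rhdf5::h5closeAll()
  invisible(path)
}

read_session_h5 <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  root_attr <- rhdf5::h5readAttributes(path, "/")
  for (k in c("session_id", "sampling_rate_hz", "group_label")) {
    if (is.null(root_attr[[k]])) stopf("missing mandatory root attribute '%s'", k)
  }
  top <- ls$name[ls$group == "/"]
  known <- c("spikes", "protocols", "raw", "channel_map_id", "channel_map_row",
             "channel_map_col", "channel_map_ref")
  if (length(setdiff(top, known)))
    warnf("ignoring unknown blocks: %s",
          paste(setdiff(top, known), collapse = ", "))
  if (!"spikes" %in% top) stopf("missing mandatory table 'spikes'")
  if (!"protocols" %in% top) stopf("missing mandatory table 'protocols'")

  trains <- list()
  for (cid in ls$name[ls$group == "/spikes"]) {
    g <- paste0("/spikes/", cid)
    at <- rhdf5::h5readAttributes(path, g)
    tt <- as.numeric(rhdf5::h5read(path, paste0(g, "/times")))
    if (length(tt) && min(tt) < 0)
      stopf("spike train '%s': negative spike time", cid)
    trains[[cid]] <- spike_train(cid, at$channel_id, at$unit_index, tt)
  }
  protos <- list()
  for (pid in ls$name[ls$group == "/protocols"]) {
    g <- paste0("/protocols/", pid)
    at <- rhdf5::h5readAttributes(path, g)
    onsets <- as.numeric(rhdf5::h5read(path, paste0(g, "/onsets")))
    protos[[pid]] <- if (at$kind == "electrical") {
      stimulus_protocol(pid, "electrical", onsets,
                        amplitude = as.numeric(at$amplitude_uA),
                        phase_duration = as.numeric(at$phase_duration_ms))
    } else {
      stimulus_protocol(pid, "light", onsets,
                        on_duration = as.numeric(at$on_duration_s),
                        off_duration = as.numeric(at$off_duration_s))
    }
  }
  raw <- NULL
  if ("raw" %in% top) {
    raw <- list()
    for (ch in ls$name[ls$group == "/raw"])
      raw[[ch]] <- as.numeric(rhdf5::h5read(path, paste0("raw/", ch)))
  }
  cmap <- if ("channel_map_id" %in% top) {
    data.frame(channel_id = as.integer(rhdf5::h5read(path, "channel_map_id")),
               grid_row = as.integer(rhdf5::h5read(path, "channel_map_row")),
               grid_col = as.integer(rhdf5::h5read(path, "channel_map_col")),
               is_reference = as.logical(rhdf5::h5read(path, "channel_map_ref")))
  } else default_channel_map()
  recording_session(root_attr$session_id, trains, protos,
                    sampling_rate = as.numeric(root_attr$sampling_rate_hz),
                    channel_map = cmap,
                    group_label = root_attr$group_label,
                    raw_traces = raw)
}
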