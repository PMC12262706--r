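# Spot-table I/O in the TrackMate export dialect, plus config and
# provenance helpers.

#' Spot-table dialect description
#'
#' Column mapping for TrackMate-style CSV exports. Matching is
#' case-insensitive; the three extra header rows that newer exports insert
#' below the column names (human-readable names and units) are detected and
#' skipped automatically.
#'
#' @param track_id,frame,x,y,t column names.
#' @param position_unit,time_unit declared units (um and s assumed, with a
#'   warning, when absent).
#' @export
spot_dialect <- function(track_id = "TRACK_ID", frame = "FRAME",
                         x = "POSITION_X", y = "POSITION_Y",
                         t = "POSITION_T",
                         position_unit = "um", time_unit = "s") {
  structure(list(track_id = track_id, frame = frame, x = x, y = y, t = t,
                 position_unit = position_unit, time_unit = time_unit),
            class = "spot_dialect")
}

#' Read a tracked-spot CSV into trajectories
#'
#' Groups rows by track id and sorts by frame. Frame gaps are allowed (no
#' gap closing upstream) and preserved; duplicate (track, frame) rows are an
#' error; non-numeric cells are reported with their line numbers.
#'
#' @param path CSV file path.
#' @param dialect a \code{\link{spot_dialect}}.
#' @param dt frame interval in seconds; when NULL it is inferred from the
#'   time column (median per-frame time difference), with a fallback of 1 s
#'   (warned) if no time column is present.
#' @return list of \code{smt_trajectory}.
#' @export
read_spot_table <- function(path, dialect = spot_dialect(), dt = NULL) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  find_col <- function(name, required = TRUE) {
    hit <- which(tolower(names(raw)) == tolower(name))
    if (length(hit) == 0L) {
      if (required) stop_domain("required column missing: ", name)
      return(NA_integer_)
    }
    hit[1L]
  }
  ci <- vapply(c(dialect$track_id, dialect$frame, dialect$x, dialect$y),
               find_col, integer(1))
  ct <- find_col(dialect$t, required = FALSE)
  if (nrow(raw) == 0L) return(list())
  # drop TrackMate's extra header rows (non-numeric FRAME cells at the top)
  frame_num <- suppressWarnings(as.numeric(raw[[ci[2L]]]))
  header_extra <- seq_len(nrow(raw)) <= 3L & is.na(frame_num)
  raw <- raw[!header_extra, , drop = FALSE]
  if (nrow(raw) == 0L) return(list())
  num <- function(col, label) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "")
    if (length(bad))
      stop_domain("non-numeric ", label, " value at data row ",
                  paste(utils::head(bad, 3L), collapse = ", "))
    v
  }
  tid <- as.character(raw[[ci[1L]]])
  frm <- num(ci[2L], "frame")
  xx <- num(ci[3L], "x"); yy <- num(ci[4L], "y")
  tt <- if (!is.na(ct)) num(ct, "time") else NULL
  if (is.null(dt)) {
    if (!is.null(tt)) {
      dfr <- unlist(tapply(frm, tid, diff, simplify = FALSE))
      dti <- unlist(tapply(tt, tid, diff, simplify = FALSE))
      ok <- !is.na(dfr) & dfr > 0
      dt <- if (any(ok)) stats::median(dti[ok] / dfr[ok]) else 1
      if (!is.finite(dt) || dt <= 0) dt <- 1
    } else {
      warning("no time column and no dt given; assuming dt = 1 s")
      dt <- 1
    }
  }
  out <- lapply(split(seq_along(tid), tid), function(idx) {
    o <- idx[order(frm[idx])]
    f <- as.integer(round(frm[o]))
    if (anyDuplicated(f))
      stop_domain("duplicate (track, frame) rows for track ", tid[idx[1L]])
    trajectory(tid[o][1L], frames = f, x = xx[o], y = yy[o], dt = dt,
               times = if (is.null(tt)) f * dt else tt[o])
  })
  unname(out[order(suppressWarnings(as.numeric(names(out))),
                   names(out), na.last = TRUE)])
}

#' Write trajectories as a tracked-spot CSV
#'
#' @param tracks list of \code{smt_trajectory} or an \code{smt_condensate}.
#' @param path output CSV path.
#' @param dialect a \code{\link{spot_dialect}}.
#' @return \code{path}, invisibly.
#' @export
write_spot_table <- function(tracks, path, dialect = spot_dialect()) {
  if (inherits(tracks, "smt_condensate")) tracks <- tracks$tracks
  df <- do.call(rbind, lapply(tracks, as.data.frame))
  names(df) <- c(dialect$track_id, dialect$frame, dialect$x, dialect$y,
                 dialect$t)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a provenance sidecar
#'
#' JSON record of the configuration, master seed, package version and a
#' stable hash of the serialized config; written next to every artefact the
#' CLI produces.
#'
#' @param config named list of settings.
#' @param seed master seed.
#' @param path output JSON path.
#' @param extra optional named list merged into the record (e.g. filter
#'   audit counts).
#' @export
write_provenance <- function(config, seed, path, extra = list()) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  rec <- c(list(config = config, config_hash = config_hash(cfg_json),
                seed = seed,
                package = "tetherSMT",
                version = as.character(utils::packageVersion("tetherSMT"))),
           extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
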