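#' Entry/exit landmark pair for one screw corridor
#'
#' The corridor axis is the straight segment from the entry landmark (pubic
#' tubercle region) to the exit landmark (posterior lateral ilium), both in
#' world mm.
#'
#' @param entry,exit world points (length-3 numeric, mm).
#' @param specimen_id identifier string.
#' @param side `"left"` or `"right"`.
#' @return object of class `landmark_pair`.
#' @export
landmark_pair <- function(entry, exit, specimen_id = "specimen", side = "left") {
  entry <- world_point(entry[1], entry[2], entry[3])
  exit <- world_point(exit[1], exit[2], exit[3])
  side <- match.arg(side, c("left", "right"))
  if (sqrt(sum((exit - entry)^2)) <= 0)
    stop("degenerate corridor: entry and exit landmarks coincide", call. = FALSE)
  structure(list(entry = entry, exit = exit,
                 specimen_id = as.character(specimen_id), side = side),
            class = "landmark_pair")
}

#' @export
print.landmark_pair <- function(x, ...) {
  cat(sprintf("<landmark_pair> %s/%s  entry (%.1f, %.1f, %.1f)  exit (%.1f, %.1f, %.1f)  |%.1f mm|\n",
              x$specimen_id, x$side, x$entry[1], x$entry[2], x$entry[3],
              x$exit[1], x$exit[2], x$exit[3],
              sqrt(sum((x$exit - x$entry)^2))))
  invisible(x)
}

#' Read corridor landmarks from CSV or JSON
#'
#' CSV must have header
#' `specimen_id,side,entry_x,entry_y,entry_z,exit_x,exit_y,exit_z`
#' (world mm). JSON is an array of objects with the same fields.
#'
#' @param path file path (`.csv` or `.json`).
#' @return list of [landmark_pair] objects.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.json$", tolower(path))) {
    df <- jsonlite::fromJSON(path)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  req <- c("specimen_id", "side", "entry_x", "entry_y", "entry_z",
           "exit_x", "exit_y", "exit_z")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("landmark file missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    landmark_pair(
      entry = c(df$entry_x[i], df$entry_y[i], df$entry_z[i]),
      exit = c(df$exit_x[i], df$exit_y[i], df$exit_z[i]),
      specimen_id = df$specimen_id[i], side = df$side[i])
  })
}

#' Write landmarks to CSV
#'
#' @param landmarks list of [landmark_pair] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  df <- do.call(rbind, lapply(landmarks, function(lm) {
    data.frame(specimen_id = lm$specimen_id, side = lm$side,
               entry_x = lm$entry[1], entry_y = lm$entry[2], entry_z = lm$entry[3],
               exit_x = lm$exit[1], exit_y = lm$exit[2], exit_z = lm$exit[3])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
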