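#' Optode montage for the 52-channel prefrontal probe
#'
#' The montage describes a 3 x 11 grid of alternating source/detector optodes
#' (17 sources, 16 detectors, approximately 3 cm apart) forming 52 measurement
#' channels: within each optode row, horizontally adjacent source-detector
#' pairs, and between rows, vertically adjacent pairs. The lowest probe row
#' sits on the T4-Fz-T3 line; the 20 channels nearest T3/T4 (the two lateral
#' optode columns on each side) are heavily noise-contaminated and excluded,
#' leaving 32 in-use channels over the prefrontal cortex.
#'
#' Channel labels: the 32 in-use channels are numbered `C1`..`C32` row-wise
#' over the central sub-grid (6 horizontal, 7 vertical, 6 horizontal, 7
#' vertical, 6 horizontal); the excluded lateral channels are `C33`..`C52`.
#' Two channels are *neighbors* when they share an optode and their
#' source-detector axes are perpendicular, i.e. the cross of up to four
#' channels around a given channel (so `C14`'s neighbors are `C7`, `C8`,
#' `C20`, `C21`).
#'
#' @param path Path to a montage YAML file (see packaged
#'   `extdata/montage_etg4000.yaml` for the schema).
#' @return A `nirs_montage` object with elements `channels` (data.frame
#'   `id`, `source`, `detector`), `optodes` (data.frame `id`, `row`, `col`),
#'   `in_use` (character), and `distance_cm`.
#' @export
default_montage <- function() {
  grid_rows <- 3L; grid_cols <- 11L
  opt <- expand.grid(col = seq_len(grid_cols), row = seq_len(grid_rows))
  opt <- opt[order(opt$row, opt$col), ]
  is_source <- (opt$row + opt$col) %% 2L == 0L
  ids <- character(nrow(opt))
  ids[is_source] <- paste0("S", seq_len(sum(is_source)))
  ids[!is_source] <- paste0("D", seq_len(sum(!is_source)))
  optodes <- data.frame(id = ids, row = opt$row, col = opt$col,
                        stringsAsFactors = FALSE)
  opt_at <- function(r, c) optodes$id[optodes$row == r & optodes$col == c]

  pair <- function(r1, c1, r2, c2) {
    a <- opt_at(r1, c1); b <- opt_at(r2, c2)
    if (startsWith(a, "S")) c(source = a, detector = b) else c(source = b, detector = a)
  }
  horiz <- function(r, j) pair(r, j, r, j + 1L)      # spans optode cols j, j+1
  vert  <- function(r, c) pair(r, c, r + 1L, c)      # spans optode rows r, r+1

  chans <- list()
  # in-use central sub-grid, row-wise: 6 / 7 / 6 / 7 / 6
  for (j in 3:8) chans[[length(chans) + 1L]] <- horiz(1L, j)
  for (c in 3:9) chans[[length(chans) + 1L]] <- vert(1L, c)
  for (j in 3:8) chans[[length(chans) + 1L]] <- horiz(2L, j)
  for (c in 3:9) chans[[length(chans) + 1L]] <- vert(2L, c)
  for (j in 3:8) chans[[length(chans) + 1L]] <- horiz(3L, j)
  # lateral channels near T3 (left) then T4 (right)
  for (r in 1:3) for (j in 1:2) chans[[length(chans) + 1L]] <- horiz(r, j)
  for (r in 1:2) for (c in 1:2) chans[[length(chans) + 1L]] <- vert(r, c)
  for (r in 1:3) for (j in 9:10) chans[[length(chans) + 1L]] <- horiz(r, j)
  for (r in 1:2) for (c in 10:11) chans[[length(chans) + 1L]] <- vert(r, c)

  channels <- data.frame(id = paste0("C", seq_along(chans)),
                         source = vapply(chans, `[[`, "", "source"),
                         detector = vapply(chans, `[[`, "", "detector"),
                         stringsAsFactors = FALSE)
  new_montage(channels, optodes, in_use = paste0("C", 1:32), distance_cm = 3.0)
}

new_montage <- function(channels, optodes, in_use, distance_cm) {
  m <- structure(list(channels = channels, optodes = optodes,
                      in_use = in_use, distance_cm = distance_cm),
                 class = "nirs_montage")
  validate_montage(m)
}

validate_montage <- function(m) {
  ch <- m$channels
  if (nrow(ch) != 52L)
    stop_nirs("montage must define 52 channels, found ", nrow(ch))
  if (anyDuplicated(ch$id))
    stop_nirs("duplicated channel id: ", ch$id[duplicated(ch$id)][1])
  known <- m$optodes$id
  for (i in seq_len(nrow(ch))) {
    for (o in c(ch$source[i], ch$detector[i]))
      if (!o %in% known)
        stop_nirs("channel ", ch$id[i], " references unknown optode ", o)
    if (!startsWith(ch$source[i], "S"))
      stop_nirs("channel ", ch$id[i], " source ", ch$source[i], " is not a source optode")
    if (!startsWith(ch$detector[i], "D"))
      stop_nirs("channel ", ch$id[i], " detector ", ch$detector[i], " is not a detector optode")
  }
  key <- paste(ch$source, ch$detector)
  if (anyDuplicated(key))
    stop_nirs("duplicated optode pair for channel ", ch$id[duplicated(key)][1])
  bad <- setdiff(m$in_use, ch$id)
  if (length(bad))
    stop_nirs("in-use channel not among channel ids: ", bad[1])
  if (!is.numeric(m$distance_cm) || m$distance_cm <= 0)
    stop_nirs("source-detector distance must be > 0")
  m
}

#' @rdname default_montage
#' @export
load_montage <- function(path) {
  if (!file.exists(path)) stop_nirs("montage file not found: ", path)
  y <- yaml::read_yaml(path)
  optodes <- do.call(rbind, lapply(y$optodes, function(o)
    data.frame(id = o$id, row = as.integer(o$row), col = as.integer(o$col),
               stringsAsFactors = FALSE)))
  channels <- do.call(rbind, lapply(y$channels, function(chan)
    data.frame(id = chan$id, source = chan$source, detector = chan$detector,
               stringsAsFactors = FALSE)))
  new_montage(channels, optodes, in_use = unlist(y$in_use),
              distance_cm = as.numeric(y$source_detector_distance_cm))
}

#' @rdname default_montage
#' @param montage A `nirs_montage` object.
#' @export
write_montage <- function(montage, path) {
  y <- list(
    source_detector_distance_cm = montage$distance_cm,
    optodes = lapply(seq_len(nrow(montage$optodes)), function(i)
      as.list(montage$optodes[i, ])),
    channels = lapply(seq_len(nrow(montage$channels)), function(i)
      as.list(montage$channels[i, ])),
    in_use = as.list(montage$in_use))
  yaml::write_yaml(y, path)
  invisible(path)
}

optode_pos <- function(montage, id) {
  i <- match(id, montage$optodes$id)
  c(row = montage$optodes$row[i], col = montage$optodes$col[i])
}

# "h" if the source-detector axis is within an optode row, "v" otherwise.
channel_orientation <- function(montage, channel) {
  i <- match(channel, montage$channels$id)
  s <- optode_pos(montage, montage$channels$source[i])
  d <- optode_pos(montage, montage$channels$detector[i])
  if (s["row"] == d["row"]) "h" else "v"
}

#' Neighboring channels of a measurement channel
#'
#' Neighbors are the in-use channels that share an optode with `channel` and
#' whose source-detector axis is perpendicular to it -- the cross of (up to
#' four) channels around it in the probe grid. Channels listed in `exclude`
#' (typically channels that were themselves reconstructed) are never returned,
#' so reconstructed channels cannot act as donors for further reconstruction.
#'
#' @param montage A `nirs_montage`.
#' @param channel A channel id present in the montage.
#' @param exclude Character vector of channel ids to drop from the result.
#' @return Character vector of neighboring in-use channel ids.
#' @examples
#' neighbors(default_montage(), "C14")   # C7, C8, C20, C21
#' @export
neighbors <- function(montage, channel, exclude = character()) {
  ch <- montage$channels
  i <- match(channel, ch$id)
  if (is.na(i)) stop_nirs("unknown channel id: ", channel)
  my_opt <- c(ch$source[i], ch$detector[i])
  my_orient <- channel_orientation(montage, channel)
  share <- (ch$source %in% my_opt | ch$detector %in% my_opt) & ch$id != channel
  cand <- ch$id[share]
  perp <- vapply(cand, function(id)
    channel_orientation(montage, id) != my_orient, logical(1))
  sort_channels(setdiff(intersect(cand[perp], montage$in_use), exclude))
}

# numeric sort on "C<k>" labels
sort_channels <- function(ids) ids[order(as.integer(sub("^C", "", ids)))]

#' @export
print.nirs_montage <- function(x, ...) {
  cat(sprintf("fNIRS montage: %d channels (%d in use), %d optodes, d = %g cm\n",
              nrow(x$channels), length(x$in_use), nrow(x$optodes), x$distance_cm))
  invisible(x)
}
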