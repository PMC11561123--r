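#' Tractogram: streamlines with optional per-streamline scores
#'
#' A `tractogram` is a list of streamlines (each an n x 3 matrix of
#' ordered template-space mm coordinates, n >= 2, consecutive points
#' distinct) plus, once fitted, a per-streamline correlation score
#' (`fiber_r` in [-1, 1]) and an `unscored` flag for streamlines whose
#' stimulation exposure was too sparse to score.
#'
#' @param streamlines list of n x 3 numeric matrices.
#' @param fiber_r optional numeric vector, one score per streamline.
#' @param unscored optional logical vector parallel to `fiber_r`.
#' @return object of class `tractogram`.
#' @export
new_tractogram <- function(streamlines, fiber_r = NULL, unscored = NULL) {
  if (!is.list(streamlines) || length(streamlines) == 0L)
    stop("streamlines must be a non-empty list")
  streamlines <- lapply(seq_along(streamlines), function(s) {
    m <- rbind_points(streamlines[[s]])
    if (nrow(m) < 2L)
      stop("streamline ", s, " has fewer than 2 points")
    if (any(rowSums(abs(diff(m))) == 0))
      stop("streamline ", s, " has consecutive duplicate points")
    unname(m)
  })
  if (!is.null(fiber_r)) {
    if (length(fiber_r) != length(streamlines))
      stop("fiber_r length must equal the number of streamlines")
    if (any(!is.na(fiber_r) & abs(fiber_r) > 1))
      stop("fiber_r values must lie in [-1, 1]")
    if (is.null(unscored)) unscored <- rep(FALSE, length(fiber_r))
  }
  structure(list(streamlines = streamlines, fiber_r = fiber_r,
                 unscored = unscored),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  cat("<tractogram> ", length(x$streamlines), " streamlines",
      if (!is.null(x$fiber_r)) ", scored", "\n", sep = "")
  invisible(x)
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' Read streamlines from TCK or the package's JSON dialect
#'
#' The JSON dialect is a list of streamlines, each a list of `[x, y, z]`
#' mm triplets (optionally wrapped in `{"streamlines": ...}` with an
#' optional `"fiber_r"` array). TCK files store mm coordinates natively
#' and are read directly. TRK is refused: its on-disk coordinate
#' convention varies by writer and cannot be validated here.
#'
#' @param path path ending in `.tck` or `.json`.
#' @return `tractogram` with coordinates in template-space mm.
#' @export
read_tractogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         tck  = read_tck(path),
         json = read_tractogram_json(path),
         trk  = stop("format error: TRK is not supported (ambiguous ",
                     "coordinate convention); convert to TCK or JSON"),
         stop("format error: unknown streamline extension '.", ext, "'"))
}

#' Write streamlines to TCK or JSON
#'
#' @param trk `tractogram`.
#' @param path output path ending in `.tck` or `.json`.
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(trk, path) {
  ext <- tolower(sub(".*\\.", "", path))
  switch(ext,
         tck = write_tck(trk, path),
         json = write_tractogram_json(trk, path),
         stop("format error: unknown streamline extension '.", ext, "'"))
  invisible(path)
}

read_tractogram_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(names(x)) && !is.null(x$streamlines)) {
    sl <- x$streamlines
    fr <- if (!is.null(x$fiber_r)) as.numeric(unlist(x$fiber_r))
    un <- if (!is.null(x$unscored)) as.logical(unlist(x$unscored))
  } else {
    sl <- x; fr <- NULL; un <- NULL
  }
  sl <- lapply(sl, function(m)
    do.call(rbind, lapply(m, function(p) as.numeric(unlist(p)))))
  new_tractogram(sl, fiber_r = fr, unscored = un)
}

write_tractogram_json <- function(trk, path) {
  obj <- list(streamlines = lapply(trk$streamlines, function(m)
    unname(as.matrix(m))))
  if (!is.null(trk$fiber_r)) {
    obj$fiber_r <- trk$fiber_r
    obj$unscored <- trk$unscored
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
}

# TCK (MRtrix track file): ASCII header terminated by "END", then
# little-endian float32 triplets; (NaN,NaN,NaN) separates streamlines,
# (Inf,Inf,Inf) terminates the stream.
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L, warn = FALSE)
  if (!grepl("^mrtrix tracks", magic))
    stop("malformed TCK file '", path, "': missing 'mrtrix tracks' magic line")
  offset <- NA_integer_
  datatype <- "Float32LE"
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (length(ln) == 0L)
      stop("malformed TCK file '", path, "': header field END missing")
    if (identical(trimws(ln), "END")) break
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) >= 2) {
      key <- trimws(kv[1])
      val <- trimws(paste(kv[-1], collapse = ":"))
      if (key == "file") offset <- as.integer(sub("^\\. ", "", val))
      if (key == "datatype") datatype <- val
    }
  }
  if (is.na(offset))
    stop("malformed TCK file '", path, "': header field 'file' missing")
  if (!identical(datatype, "Float32LE"))
    stop("malformed TCK file '", path, "': unsupported datatype field '",
         datatype, "'")
  seek(con, where = offset, origin = "start")
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  if (length(raw) %% 3L != 0L)
    stop("malformed TCK file '", path, "': truncated coordinate stream")
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  breaks <- which(apply(m, 1L, function(r) all(is.nan(r)) || all(is.infinite(r))))
  sl <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) sl[[length(sl) + 1L]] <- m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
  }
  new_tractogram(sl)
}

write_tck <- function(trk, path) {
  body <- do.call(rbind, lapply(trk$streamlines, function(m)
    rbind(m, c(NaN, NaN, NaN))))
  body <- rbind(body, c(Inf, Inf, Inf))
  hdr1 <- c("mrtrix tracks",
            sprintf("count: %d", length(trk$streamlines)),
            "datatype: Float32LE")
  # offset depends on its own textual length; iterate to fixed point
  off <- 0L
  repeat {
    hdr <- c(hdr1, sprintf("file: . %d", off), "END")
    new_off <- sum(nchar(hdr, type = "bytes")) + length(hdr)  # newlines
    if (new_off == off) break
    off <- new_off
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(t(body)), con, size = 4L, endian = "little")
  invisible(path)
}
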