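## Portable text container for dia-PASEF-like frames.
##
## Layout:
##   #imframes<TAB>1
##   #spec<TAB><json of frame_spec fields incl. windows>
##   #frame<TAB>window_id<TAB>cycle<TAB>n_points      (repeated)
##   scan<TAB>bin<TAB>intensity                       (n_points lines)
##   #end
## Integers round-trip bit-exact; intensities are written with "%.17g" so
## doubles round-trip exactly.

#' Write / read the portable frame container
#'
#' `write_frames()` stores a [frame_spec()] plus a list of [im_frame()]s in a
#' self-describing tab-separated text container; `read_frames()` is its exact
#' inverse. A truncated file raises an error naming the last cycle index that
#' was read completely.
#'
#' @param frames List of [im_frame()] objects (may be empty).
#' @param spec A [frame_spec()].
#' @param path File path.
#' @return `read_frames()` returns `list(spec = frame_spec, frames = list)`.
#' @export
write_frames <- function(frames, spec, path) {
  stopifnot(inherits(spec, "frame_spec"))
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("#imframes\t1", con)
  sp <- spec[c("n_scans", "im_begin", "im_end", "n_bins", "mz_min", "mz_max",
               "frames_per_window", "cycle_time")]
  sp$windows <- spec$windows
  writeLines(paste0("#spec\t", jsonlite::toJSON(sp, digits = NA, auto_unbox = TRUE)),
             con)
  for (f in frames) {
    p <- f$points
    writeLines(sprintf("#frame\t%d\t%d\t%d", f$window_id, f$cycle, nrow(p)), con)
    if (nrow(p))
      writeLines(sprintf("%d\t%d\t%.17g", as.integer(p$scan), as.integer(p$bin),
                         p$intensity), con)
  }
  writeLines("#end", con)
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L || lines[1] != "#imframes\t1")
    stop("not an imframes container: ", path)
  if (!startsWith(lines[2], "#spec\t"))
    stop("missing #spec header in ", path)
  sp <- jsonlite::fromJSON(sub("^#spec\t", "", lines[2]))
  spec <- frame_spec(sp$n_scans, sp$im_begin, sp$im_end, sp$n_bins,
                     sp$mz_min, sp$mz_max, sp$windows,
                     frames_per_window = sp$frames_per_window,
                     cycle_time = sp$cycle_time)
  frames <- list()
  i <- 3L
  last_complete_cycle <- NA_integer_
  while (i <= length(lines)) {
    ln <- lines[i]
    if (ln == "#end") return(list(spec = spec, frames = frames))
    if (!startsWith(ln, "#frame\t"))
      stop(sprintf("corrupt container %s: unexpected line %d; last complete cycle: %s",
                   path, i, last_complete_cycle))
    hdr <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    wid <- as.integer(hdr[2]); cyc <- as.integer(hdr[3]); n <- as.integer(hdr[4])
    if (i + n > length(lines))
      stop(sprintf("truncated container %s: frame (window %d, cycle %d) incomplete; last complete cycle: %s",
                   path, wid, cyc, last_complete_cycle))
    if (n > 0L) {
      block <- lines[(i + 1L):(i + n)]
      m <- matrix(scan(text = block, what = numeric(), sep = "\t", quiet = TRUE),
                  ncol = 3L, byrow = TRUE)
      pts <- data.frame(scan = as.integer(m[, 1]), bin = as.integer(m[, 2]),
                        intensity = m[, 3])
    } else {
      pts <- data.frame(scan = integer(), bin = integer(), intensity = numeric())
    }
    frames[[length(frames) + 1L]] <- im_frame(wid, cyc, pts)
    last_complete_cycle <- cyc
    i <- i + n + 1L
  }
  stop(sprintf("truncated container %s: missing #end; last complete cycle: %s",
               path, last_complete_cycle))
}
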