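# Shared helpers: seeded RNG scoping and atomic file writes.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a root seed and a stream index, kept within the
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647)
}

# Atomic write: `writer(tmp)` writes to a temp file in the destination
# directory, which is then renamed over `path`.
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = paste0(".tmp-", basename(path)))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# Write/read a list of records as JSON lines.
write_jsonl <- function(records, path) {
  atomic_write(path, function(tmp) {
    lines <- vapply(records, function(r) {
      as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA))
    }, character(1))
    writeLines(lines, tmp)
  })
}

read_jsonl <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON)
}

#' Read and write binary masks as 8-bit PNG
#'
#' Masks are serialized as single-channel 8-bit PNG with 0 = background and
#' 255 = foreground.
#'
#' @param m A binary mask.
#' @param path File path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a binary mask.
#' @export
write_mask_png <- function(m, path) {
  m <- as_mask(m)
  atomic_write(path, function(tmp) png::writePNG(m * 1.0, tmp))
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  matrix(as.integer(v >= 0.5), nrow(v), ncol(v))
}

# Write an RGB array (h x w x 3, values in [0,1]) as PNG.
write_rgb_png <- function(img, path) {
  atomic_write(path, function(tmp) png::writePNG(img, tmp))
  invisible(path)
}

read_rgb_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2) v <- array(rep(v, 3), c(nrow(v), ncol(v), 3))
  v[, , 1:3, drop = FALSE]
}
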