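# Internal helpers shared across the package.

abort_validation <- function(...) {
  stop(structure(class = c("anodet_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_io <- function(...) {
  stop(structure(class = c("anodet_io_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_parse <- function(...) {
  stop(structure(class = c("anodet_parse_error", "anodet_io_error", "error",
                           "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

abort_schema <- function(...) {
  stop(structure(class = c("anodet_schema_error", "anodet_validation_error",
                           "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

# Write `lines`/writer output atomically: temp file in the same directory,
# then rename, so a crash never leaves a truncated output behind.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) abort_io("directory does not exist: ", dir)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort_io("cannot write to ", path)
  invisible(path)
}

# Full-precision decimal text for doubles: round-trips bit-exactly through
# as.numeric().
format_full <- function(x) sprintf("%.17g", x)
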