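# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_data <- function(msg, class = "entrotme_data_error") {
  rlang::abort(msg, class = c(class, "entrotme_error"))
}

abort_config <- function(msg, class = "entrotme_config_error") {
  rlang::abort(msg, class = c(class, "entrotme_error"))
}

# FNV-1a 32-bit hash of a character scalar; used for config fingerprints in
# output metadata headers (stable across sessions, no external dependency).
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor the byte into the low 8 bits (kept exact in doubles)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    # 32-bit modular multiply by the FNV prime, split to stay within 2^53
    hi <- h %/% 65536; lo <- h %% 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(x) {
  fnv1a32(paste(deparse(x, control = "all"), collapse = "\n"))
}

# derive a reproducible 31-bit sub-stream seed from a base seed and a path of
# identifiers, so each core/patient owns an independent RNG stream
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  strtoi(substr(fnv1a32(key), 1, 7), base = 16L) %% 2147483647L
}

#' Write a delimited table with a reproducibility metadata header
#'
#' Output files carry `#`-prefixed header lines (package version, seed,
#' configuration hash) so any result file can be traced to the run that
#' produced it. [read_meta_csv()] skips these lines transparently.
#'
#' @param df Data frame to write.
#' @param path Output file path.
#' @param meta Named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_meta_csv <- function(df, path, meta = list()) {
  meta <- c(list(generator = paste0("entroTME ", as.character(utils::packageVersion("entroTME")))), meta)
  hdr <- sprintf("# %s: %s", names(meta), vapply(meta, as.character, character(1)))
  writeLines(hdr, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a delimited table written by [write_meta_csv()]
#'
#' @param path File path.
#' @return A tibble; metadata header lines are available via
#'   `attr(, "meta")` as a named character vector.
#' @export
read_meta_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  hdr <- grep("^# ", lines, value = TRUE)
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  if (length(hdr)) {
    kv <- sub("^# ([^:]+): (.*)$", "\\1\x01\\2", hdr)
    parts <- strsplit(kv, "\x01", fixed = TRUE)
    meta <- vapply(parts, `[`, character(1), 2)
    names(meta) <- vapply(parts, `[`, character(1), 1)
    attr(df, "meta") <- meta
  }
  df
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

stopifnot_scalar_num <- function(x, nm, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort_config(sprintf("`%s` must be a single number", nm))
  }
  if (positive && x <= 0) abort_config(sprintf("`%s` must be positive", nm))
  invisible(x)
}
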