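# Parse a flat "key = value" config file; '#' starts a comment line.
read_keyvalue <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
    if (length(parts) < 2) stop("malformed config line ", i, ": ", lines[i])
    key <- trimws(parts[1])
    kv[[key]] <- trimws(paste(parts[-1], collapse = "="))
  }
  kv
}
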