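# MD5 of a string via tools::md5sum (file-based, base R only).
md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

# Stable hash of a thresholds object (provenance stamp).
threshold_hash <- function(...) {
  objs <- list(...)
  md5_string(paste(vapply(objs, function(o) {
    paste(deparse(unclass(o)), collapse = "")
  }, ""), collapse = "|"))
}

md5_file <- function(path) {
  if (!file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}
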