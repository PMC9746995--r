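# Minimal 4-line-record FASTQ I/O. Hand-rolled on purpose: ShortRead is
# not a dependency, files here are small demultiplexing fixtures, and
# the simulator's byte-identity contract needs full control of output.

read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  n <- length(lines) %/% 4L
  idx <- seq_len(n)
  ids <- lines[(idx - 1L) * 4L + 1L]
  if (n > 0L && any(substr(ids, 1L, 1L) != "@")) stop("malformed FASTQ header: ", path)
  data.table::data.table(
    read_id = sub("^@", "", sub("\\s.*$", "", ids)),
    seq = toupper(lines[(idx - 1L) * 4L + 2L]),
    qual = lines[(idx - 1L) * 4L + 4L]
  )
}

write_fastq <- function(ids, seqs, quals, path) {
  lines <- character(4L * length(ids))
  lines[seq_along(ids) * 4L - 3L] <- paste0("@", ids)
  lines[seq_along(ids) * 4L - 2L] <- seqs
  lines[seq_along(ids) * 4L - 1L] <- "+"
  lines[seq_along(ids) * 4L] <- quals
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

# phred integer vector -> Sanger(+33) quality string, and back
phred_to_string <- function(q) {
  vapply(q, function(v) rawToChar(as.raw(v + 33L)), character(1))
}

string_to_phred <- function(s) {
  lapply(s, function(x) as.integer(charToRaw(x)) - 33L)
}
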