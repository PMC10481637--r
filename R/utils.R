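`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Stable hash of an R object via its deparsed text; used to stamp report
# outputs so a rerun under an identical configuration is recognisable.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
               collapse = "\n")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

# seeds derived from a master seed stay well below .Machine$integer.max
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013L * as.integer(offset)) %% 2147483647L
}
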