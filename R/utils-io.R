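## TSV interchange with a provenance header. Every stage output carries
## commented header lines naming the producing stage, a config hash and
## the seed, so runs are auditable and resumable.

write_stage_tsv <- function(df, path, stage = "unknown", seed = NA,
                            config_hash = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# namqtl stage=%s config_hash=%s seed=%s date=%s",
                     stage, config_hash, seed, format(Sys.Date())), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_stage_tsv <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

## stable short hash of an R object (config provenance); content-based,
## via serialization to a temp file and md5
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

## derive a stream-specific 32-bit seed from a base seed; arithmetic in
## doubles so large derived seeds cannot overflow integer range
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + as.numeric(stream) * 12347) %%
               2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
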