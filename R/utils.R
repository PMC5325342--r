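# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.assertCount <- function(x, what) {
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop(what, " must be non-negative integer(s)", call. = FALSE)
}

.assertPositive <- function(x, what) {
  if (any(is.na(x)) || any(x <= 0))
    stop(what, " must be positive", call. = FALSE)
}

# provenance comment lines written at the top of output TSVs
.provenanceHeader <- function(params = list()) {
  c(paste0("# glioVPA ", as.character(utils::packageVersion("glioVPA")),
           " | ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    if (length(params))
      paste0("# ", names(params), " = ",
             vapply(params, function(p) paste(format(p), collapse = ","), "")))
}

.writeTsv <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.provenanceHeader(params), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
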