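# Run expr with a fixed RNG state, restoring the caller's stream afterwards.
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One-decimal percentage, the reporting convention used throughout.
pct1 <- function(x) round(100 * x, 1)

# Numeric columns formatted so values survive a CSV round trip exactly.
format_full_precision <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- ifelse(is.na(df[[nm]]), NA,
                         sprintf("%.17g", df[[nm]]))
    if (inherits(df[[nm]], "Date")) df[[nm]] <- as.character(df[[nm]])
  }
  df
}
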