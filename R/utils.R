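# internal helpers shared across modules

# Round half away from zero (the convention of the reported tables; base
# round() is round-half-even). A 9-digit pre-round absorbs binary noise in
# count/denominator ratios without disturbing genuine halves.
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  s <- sign(x)
  s * trunc(round(abs(x) * p, 9) + 0.5) / p
}

# Percentage string with 2 decimals, half-up, as printed in report tables.
pctStr <- function(count, denom) {
  r <- 100 * count / denom
  v <- sprintf("%.2f", roundHalfUp(ifelse(is.finite(r), r, 0), 2))
  v[!is.finite(r)] <- "NA"
  v
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Canonical ICD-10 code normalization: uppercase, strip whitespace, drop dots
# ("C22.0" -> "C220"). Comparison downstream is exact-string.
normalizeCodeVector <- function(x) {
  gsub("\\.", "", gsub("\\s+", "", toupper(as.character(x))))
}

# Per-patient count of diagnosis codes falling in `codes`.
countCodeHits <- function(cohort, codes) {
  dxl <- cohort@diagnoses
  all <- unlist(dxl, use.names = FALSE)
  pat <- rep.int(seq_along(dxl), S4Vectors::elementNROWS(dxl))
  tabulate(pat[all %in% codes], nbins = length(dxl))
}

.assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != trunc(x))
    stop("'", name, "' must be a single non-negative integer", call. = FALSE)
  invisible(as.numeric(x))
}
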