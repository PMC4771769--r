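#' Write a data frame as a deterministic CSV
#'
#' Doubles are formatted with `%.6g` so that repeated runs of the same
#' analysis produce byte-identical tables across platforms.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) {
      v <- out[[nm]]
      whole <- !is.na(v) & v == round(v) & abs(v) < 2^53
      s <- ifelse(is.na(v), NA_character_,
                  ifelse(whole, sprintf("%.0f", v), sprintf("%.6g", v)))
      out[[nm]] <- s
    }
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

# stochastic rounding: floor(x) + Bernoulli(frac(x)); unbiased for counts
stoch_round <- function(x) {
  f <- floor(x)
  as.integer(f + (runif(length(x)) < (x - f)))
}

# offsets (dr, dc) of pixels whose centre lies within `radius` of the origin
disc_offsets <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dr = -r:r, dc = -r:r)
  keep <- g$dr^2 + g$dc^2 <= radius^2
  g[keep, , drop = FALSE]
}
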