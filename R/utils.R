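`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-stream seed from a base seed and a name
#'
#' Simulation stages draw from named sub-streams so that, e.g., adding a trait
#' to the phenotype generator does not perturb the genotype draws. The mapping
#' is a small polynomial string hash folded with the base seed, kept strictly
#' below 2^31 so it is always a valid R integer seed.
#'
#' @param seed integer base seed.
#' @param key character stream name.
#' @return an integer seed.
#' @export
substream_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(key) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(key))) h <- (h * 131 + ch) %% 2147483399
  as.integer((h + (as.numeric(seed) %% 2147483399) * 7919) %% 2147483399 + 1)
}

## Rescale zero-mean draws so their realized sample variance is exactly s2.
## With few groups (2-4 populations) raw draws realize a chi-square-distributed
## variance; rescaling makes "simulated sigma^2 = x" an exact study condition.
scale_to_variance <- function(x, s2) {
  if (s2 <= 0) return(rep(0, length(x)))
  x <- x - mean(x)
  sdx <- sd(x)
  if (length(x) < 2L || sdx == 0) stop("cannot rescale fewer than two distinct draws")
  x / sdx * sqrt(s2)
}

write_tsv_file <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

read_table_auto <- function(path) {
  stopifnot(file.exists(path))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  read.delim(path, sep = sep, header = TRUE, na.strings = c("NA", ""),
             check.names = FALSE, stringsAsFactors = FALSE)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
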