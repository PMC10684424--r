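#' @importFrom stats lm coef predict quantile rnorm rpois rexp runif qnorm
#'   qchisq cor median approx setNames fitted resid aggregate sd simulate
#'   residuals
#' @importFrom utils write.csv read.csv modifyList
NULL

GENERATOR_VERSION <- "0.1.0"

SEXES <- c("male", "female")

CRF_NAMES <- c("prior_fracture", "parent_hip_fracture", "smoking",
               "glucocorticoids", "rheumatoid_arthritis", "alcohol")

MOF_SITES <- c("spine", "forearm", "humerus")

#' Standard 5-year age bands from 50 with an open 90+ band
#'
#' @return data.frame with columns `age_lo`, `age_hi` (Inf for 90+) and
#'   `midpoint` (92.5 for the 90+ band).
#' @export
age_bands <- function() {
  lo <- seq(50, 90, by = 5)
  hi <- c(seq(55, 90, by = 5), Inf)
  data.frame(age_lo = lo, age_hi = hi, midpoint = band_midpoint(lo, hi))
}

# midpoint convention: (lo + hi)/2 for closed bands, 92.5 for the 90+ band
band_midpoint <- function(lo, hi) {
  ifelse(is.finite(hi), (lo + hi) / 2, lo + 2.5)
}

# evaluate expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# derive a stream-specific 31-bit sub-seed from a master seed
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 2654435.0 + h * 97.0) %% 2147483647)
}

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Write a data frame as CSV with a commented metadata header
#'
#' Files carry `# key=value` header lines (at least `seed` and
#' `generator_version`) before the column header, readable back with
#' [read_table_csv()].
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @param meta named list of scalar metadata values.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, meta = list()) {
  meta <- modifyList(list(generator_version = GENERATOR_VERSION), meta)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta)) cat(sprintf("# %s=%s\n", k, meta[[k]]), file = con)
  write.csv(x, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#'
#' @param path file path.
#' @return data.frame; the `# key=value` header is attached as attribute
#'   `"meta"`.
#' @export
read_table_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  x <- read.csv(text = lines[!grepl("^#", lines)], stringsAsFactors = FALSE)
  kv <- sub("^#\\s*", "", hdr)
  meta <- strsplit(kv, "=", fixed = TRUE)
  attr(x, "meta") <- setNames(
    lapply(meta, function(p) paste(p[-1], collapse = "=")),
    vapply(meta, `[[`, "", 1L)
  )
  x
}
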