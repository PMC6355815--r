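#' Derive a child seed from a master seed
#'
#' Sweeps, replicate runs, connectivity wiring and stimulus realizations all
#' draw their randomness from seeds derived deterministically from a single
#' master seed, so that a whole experiment is reproducible from one integer.
#' The expansion hashes a character tag into the 31-bit integer range.
#'
#' @param seed master seed (integer).
#' @param tag character scalar naming the consumer (e.g. `"connectivity"`,
#'   `"stimulus/cortical/12"`, `"replicate/3"`).
#' @return an integer in `[0, 2^31 - 2]`, usable with [set.seed()].
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(tag)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' MD5 hash of an R object via its canonical JSON form
#'
#' Used to key sweep caches and to stamp run manifests. The object is
#' serialized to JSON with full numeric precision and hashed with MD5.
#'
#' @param x an R object (typically an `lcm_config`).
#' @return character MD5 digest.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(jsonlite::toJSON(unclass_deep(x), digits = NA, auto_unbox = TRUE,
                              null = "null"), tf)
  unname(tools::md5sum(tf))
}

# strip S3 classes recursively so hashing is representation-independent
unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    attr(x, "row.names") <- NULL
    lapply(x, unclass_deep)
  } else {
    x
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
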