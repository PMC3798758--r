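#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so library randomness never leaks into
#' user sessions.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("`seed` must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Write an R object as JSON
#'
#' Thin wrapper pinning the serialization conventions used for all result
#' bundles (auto-unboxed scalars, full numeric precision).
#'
#' @param x object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_json_result <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @keywords internal
read_json_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
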