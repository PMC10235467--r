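`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a label path
#'
#' Deterministic, platform-stable integer hash used to give every cell,
#' sweep and fly its own reproducible random stream. The result is always
#' in [1, 2^31 - 2] so it is a valid R integer seed.
#'
#' @param master integer master seed
#' @param ... labels (genotype, cell index, sweep index, ...) coerced to
#'   character and folded into the hash
#' @return a single integer seed
#' @examples
#' seedFrom(42, "p12c", 3, 1)
#' @export
seedFrom <- function(master, ...) {
  key <- paste(c(format(master), vapply(list(...), format, "")),
               collapse = "\r")
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1L)
}

# run `expr` under `seed` without disturbing the caller's RNG stream;
# seed = NULL uses the current stream
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}
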