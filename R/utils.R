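# internal helpers shared across modules

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Run code with a private RNG state
#'
#' Evaluates `expr` after seeding the RNG, restoring the caller's RNG state
#' on exit so library users never see their random stream clobbered.
#' @noRd
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
assertScalarCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min)
    stop("'", name, "' must be a single number >= ", min, call. = FALSE)
  invisible(x)
}

#' @noRd
seqToInt <- function(seq) {
  if (!nchar(seq)) stop("empty sequence", call. = FALSE)
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET20)
  if (anyNA(idx))
    stop("sequence contains non-canonical residues; sanitize first",
         call. = FALSE)
  idx
}
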