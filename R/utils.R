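# Internal helpers shared across modules.

# Scalar finite-number validation with a consistent error style.
check_scalar <- function(x, name, positive = FALSE, non_negative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  if (non_negative && x < 0)
    stop(sprintf("`%s` must be >= 0 (got %g)", name, x), call. = FALSE)
  as.numeric(x)
}

check_count <- function(x, name, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < minimum)
    stop(sprintf("`%s` must be an integer >= %d", name, minimum), call. = FALSE)
  as.integer(x)
}

logistic <- function(x) 1 / (1 + exp(-x))

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so simulation calls do not perturb
# the session RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# MD5 of the canonical (sorted-key, compact) JSON serialization of a list.
# Used to stamp outputs so mixed-provenance files are detectable.
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, sort_keys = TRUE, null = "null")
}

#' Provenance hash of a configuration
#'
#' MD5 digest of the canonical JSON serialization of a configuration list.
#' Every container and flat export written by the package embeds this hash so
#' that outputs produced under different configurations cannot be silently
#' mixed.
#'
#' @param config A list (typically a [rar_config()] object).
#' @return A 32-character hexadecimal string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(as.character(canonical_json(unclass(config))), tmp)
  unname(tools::md5sum(tmp))
}
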