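#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with an arbitrary set of keys (strings or integers)
#' through a Lehmer-style modular hash, so that per-mouse / per-slice seeds are
#' deterministic functions of the master seed and adding mice never perturbs
#' the seeds of existing mice.
#'
#' @param master integer master seed.
#' @param ... keys (character or numeric scalars) identifying the child stream.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (key in list(...)) {
    vals <- if (is.character(key)) utf8ToInt(paste(key, collapse = "|")) else as.numeric(key)
    for (v in vals) h <- (h * 48271 + (v %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

#' Fingerprint an R object
#'
#' FNV-1a hash of the JSON serialization; used to stamp ground-truth tables
#' with the generator configuration that produced them.
#'
#' @param x any jsonlite-serializable object.
#' @return hex string.
#' @export
config_digest <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
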