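#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the R random seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so seeded generators never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and a path of integers
#'
#' Deterministic hierarchical seed derivation (one master seed per run, one
#' child per subject/run/session). A multiplicative-congruential mix keeps the
#' result in `[1, 2^31 - 2]`, exactly representable in doubles.
#'
#' @param master Integer master seed.
#' @param ... Further integers identifying the stream (e.g. subject, run).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, 3, 7)
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- (abs(as.numeric(master)) %% m)
  for (k in c(...)) {
    h <- (h * 69069 + abs(as.numeric(k)) + 1) %% m
  }
  as.integer(h %% (m - 1) + 1)
}

# FNV-1a hash of a character string, as a hex string; used for config
# provenance stamps (no external digest dependency).
fnv1a_hex <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), b) + 2^30 # keep in int range
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Stop unless all conditions hold, with a compact message.
stopifnot_named <- function(...) {
  conds <- list(...)
  nms <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) stop(nms[i], call. = FALSE)
  }
  invisible(TRUE)
}

chroma_levels <- function() c("/0", "/2", "/4", "/6")

check_chroma <- function(condition) {
  if (!all(condition %in% chroma_levels())) {
    stop("invalid chroma condition label: ",
      paste(setdiff(condition, chroma_levels()), collapse = ", "),
      "; expected one of ", paste(chroma_levels(), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(condition)
}
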