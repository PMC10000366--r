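# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_emofuse <- function(msg, class) {
  rlang::abort(msg, class = c(class, "emofuse_error"))
}

assert_that <- function(ok, msg, class = "emofuse_invalid") {
  if (!isTRUE(ok)) stop_emofuse(msg, class)
  invisible(TRUE)
}

# All emotion labels, in canonical order.
emotion_levels <- function() c("happy", "neutral", "sad")

# Derive a stream-specific child seed from a top-level seed so that the
# different random stages do not share streams.  Kept below 2^31 - 1.
child_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
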