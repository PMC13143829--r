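# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generator calls never leak randomness into the session.
#'
#' @param seed integer scalar seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# fft frequencies in cycles per sample, matching numpy's fftfreq layout
fft_freq <- function(n) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1) / n
}

# inverse 2-D FFT returning the real part, normalized
ifft2_real <- function(z) {
  Re(stats::fft(z, inverse = TRUE)) / length(z)
}

stop_input <- function(msg, class) {
  stop(structure(
    class = c(class, "collmot_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
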