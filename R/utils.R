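`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the previous RNG state so callers
#' are unaffected.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Round half away from zero
#'
#' Commercial rounding (0.5 rounds up), as opposed to the IEEE
#' round-half-even used by [round()].
#' @param x numeric.
#' @return rounded numeric.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Per-frame acquisition time of a radial readout
#'
#' Temporal resolution of one image acquired from `n_spokes` radial spokes at
#' repetition time `tr_ms`, rounded half-up to whole milliseconds.
#'
#' @param n_spokes number of radial spokes per image (default 21).
#' @param tr_ms repetition time in milliseconds (default 4.5).
#' @return acquisition time per frame in ms.
#' @examples
#' frame_acquisition_ms() # 95
#' @export
frame_acquisition_ms <- function(n_spokes = 21, tr_ms = 4.5) {
  stopifnot(n_spokes > 0, tr_ms > 0)
  round_half_up(n_spokes * tr_ms)
}

stop_carpo <- function(msg, class) {
  stop(structure(
    class = c(class, "carpo_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

is_label_mask <- function(m) {
  is.matrix(m) && all(m == floor(m)) && min(m) >= 0 && max(m) <= 8
}
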