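#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so seeded internals never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Named RNG substreams derived from one global seed, so each pipeline stage
# (scenes, split, init, shuffle, crops) is reproducible in isolation.
sub_seed <- function(seed, stream) {
  offsets <- c(scenes = 101L, split = 211L, init = 307L, shuffle = 401L,
               crops = 503L, eval = 601L)
  if (!stream %in% names(offsets))
    stop("unknown RNG substream: ", stream)
  s <- (as.double(seed) * 7919 + offsets[[stream]]) %% 2147483629
  as.integer(s) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_with <- function(class, msg, ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}
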