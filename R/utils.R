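# Shared constants and small helpers.

ELEMENT_CATEGORIES <- c("location", "person", "object")

# Pair presentation sequences for the overlapping-pairs protocol. The purely
# neutral location-object pair is studied first under person_last and last
# under person_first; the middle pair is always person-location.
PAIR_ORDERS <- list(
  person_last = list(
    c("location", "object"),
    c("person", "location"),
    c("object", "person")
  ),
  person_first = list(
    c("object", "person"),
    c("person", "location"),
    c("location", "object")
  )
)

# All six directed cue -> target questions for a three-element event.
question_pairs <- function() {
  out <- expand.grid(
    cue_category = ELEMENT_CATEGORIES,
    target_category = ELEMENT_CATEGORIES,
    stringsAsFactors = FALSE
  )
  out[out$cue_category != out$target_category, c("cue_category", "target_category")]
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
# seed = NULL leaves the ambient RNG in charge (still advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive per-participant RNG streams from a master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 ||
      x != round(x)) {
    stop("`", name, "` must be a single non-negative integer", call. = FALSE)
  }
  as.integer(x)
}
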