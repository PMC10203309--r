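# Internal helpers shared across modules.

# Draw `n` independent substream seeds (< 2^31) from a master seed, so stages
# and iterations have decoupled randomness.
spawn_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# run `expr` under `seed` without perturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  expr
}

check_binary_classes <- function(classes, levels = c("greater", "lesser")) {
  classes <- as.character(classes)
  bad <- setdiff(unique(classes), levels)
  if (length(bad)) {
    stop("unknown class labels: ", paste(bad, collapse = ", "))
  }
  factor(classes, levels = levels)
}
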