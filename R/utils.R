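# internal helpers shared across modules

# multiply each column j of x by m[j]; x is n x D, m length D
.mask_cols <- function(x, m) {
  x * rep(m, each = nrow(x))
}

.check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name))
  }
  if (!all(is.finite(x))) {
    abort(sprintf("`%s` contains non-finite values.", name))
  }
  invisible(x)
}

.check_same_shape <- function(a, b, na = "x", nb = "mask") {
  if (!identical(dim(a), dim(b))) {
    abort(sprintf(
      "Shape mismatch: `%s` is %s but `%s` is %s.",
      na, paste(dim(a), collapse = "x"), nb, paste(dim(b), collapse = "x")
    ))
  }
  invisible(TRUE)
}

.as_row_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

# run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

.relu <- function(x) {
  x * (x > 0)
}

.softplus <- function(x) {
  # log(1 + exp(x)) without overflow
  pmax(x, 0) + log1p(exp(-abs(x)))
}

.row_softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
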