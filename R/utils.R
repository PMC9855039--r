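# internal helpers shared across modules

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(glue::glue(
      "{what} is missing required column(s): {paste(missing, collapse = ', ')}"
    ), class = "mrpipe_config_error")
  }
  invisible(df)
}

assert_scalar_prob <- function(x, name, open_left = TRUE, open_right = TRUE) {
  lo_ok <- if (open_left) x > 0 else x >= 0
  hi_ok <- if (open_right) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok) {
    abort(glue::glue("`{name}` must be a single probability in the valid range"),
          class = "mrpipe_config_error")
  }
  invisible(x)
}

BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

# Derive a reproducible child seed (< 2^31) from a master seed and a label.
# Used so every stochastic step in a study run has its own stream. A rolling
# polynomial hash keeps distinct labels (incl. permuted digit strings like
# "12" vs "21") on distinct streams.
derive_seed <- function(seed, label) {
  h <- 0
  for (c in utf8ToInt(as.character(label))) {
    h <- (h * 131 + c) %% 2147483629
  }
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}

# Run code under a temporary RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
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
  set.seed(seed)
  force(code)
}

two_sided_p <- function(z, df = NULL, dist = c("norm", "t")) {
  dist <- match.arg(dist)
  if (dist == "norm") 2 * pnorm(-abs(z)) else 2 * pt(-abs(z), df = df)
}
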