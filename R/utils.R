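# Internal helpers: seeded substreams and input validation.

# Deterministic substream seed derived from a root seed and a stream index.
# Linear congruential mixing over the Mersenne prime 2^31 - 1 keeps every
# derived seed a valid 32-bit integer and means stream i is unaffected by
# how many other streams exist (adding a library never perturbs earlier
# ones).
substream_seed <- function(seed, stream) {
  m <- 2147483647
  s <- (as.double(seed) %% m) + 1
  for (k in seq_len(length(stream))) {
    s <- (s * 48271 + as.double(stream[[k]]) * 16807 + 1) %% m
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_columns <- function(x, cols, what) {
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(x)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s]", name, lower, upper))
  }
  invisible(x)
}

# normalise free-text sex / combination / generation codes used in design
# and trait files
normalise_sex <- function(x) {
  out <- c(
    "f" = "female", "female" = "female", "♀" = "female",
    "m" = "male", "male" = "male", "♂" = "male"
  )[tolower(trimws(x))]
  if (anyNA(out)) {
    abort(sprintf("unknown sex code(s): %s", paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}

normalise_combination <- function(x) {
  out <- c(
    "cross" = "cross", "c" = "cross",
    "reciprocal" = "reciprocal", "recip" = "reciprocal", "r" = "reciprocal",
    "reciprocal cross" = "reciprocal", "reciprocal_cross" = "reciprocal"
  )[tolower(trimws(x))]
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort(sprintf("unknown combination code(s): %s", paste(unique(x[bad]), collapse = ", ")))
  }
  unname(out)
}

normalise_generation <- function(x) {
  out <- c(
    "parent" = "parent", "p" = "parent",
    "f1" = "F1", "hybrid" = "F1"
  )[tolower(trimws(x))]
  if (anyNA(out)) {
    abort(sprintf("unknown generation code(s): %s", paste(unique(x[is.na(out)]), collapse = ", ")))
  }
  unname(out)
}
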