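# internal helpers shared across modules

# consistent condition for user-input problems
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("comolead_validation", "error")))
}

stop_chemistry <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("comolead_chemistry", "error")))
}

# scalar checks; bound names appear in error messages so a violated
# invariant is traceable to its argument
assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != as.integer(x))
    stop_validation("`%s` must be a single integer >= %d (got %s)", name, min,
                    paste(format(x), collapse = ","))
  as.integer(x)
}

assert_prob <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1)
    stop_validation("`%s` must be a single probability in [0, 1]", name)
  as.numeric(x)
}

assert_number <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    stop_validation("`%s` must be a single finite number", name)
  as.numeric(x)
}

# case-normalize gene symbols: upper-case, whitespace-stripped, unique,
# non-empty.  Mixed-case duplicates collapse to one symbol.
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[nzchar(x)]
  unique(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
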