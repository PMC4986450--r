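# Internal helpers shared across modules. All genomic intervals in this
# package are 0-based half-open [start, end); human-readable reports are
# 1-based inclusive.

`%||%` <- rlang::`%||%`

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s; got %s.", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", format(x)
    ))
  }
  invisible(x)
}

assert_columns <- function(df, cols, what) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0L) {
    abort(sprintf(
      "%s is missing required column(s): %s.",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}

# Merge possibly-overlapping half-open intervals (single linkage, any shared
# base). Abutting intervals ([a,b) then [b,c)) do NOT merge: they share no
# base. Input need not be sorted. Returns a tibble(start, end) sorted by
# start, plus the 1-based group index of each input row (in input order).
merge_halfopen <- function(start, end) {
  stopifnot(length(start) == length(end))
  n <- length(start)
  if (n == 0L) {
    return(list(merged = tibble(start = integer(), end = integer()),
                group = integer()))
  }
  ord <- order(start, end)
  s <- start[ord]
  e <- end[ord]
  grp_sorted <- integer(n)
  grp_sorted[1L] <- 1L
  cur_end <- e[1L]
  cur <- 1L
  if (n > 1L) {
    for (i in 2:n) {
      if (s[i] < cur_end) { # strict: any-base overlap, abutting excluded
        cur_end <- max(cur_end, e[i])
      } else {
        cur <- cur + 1L
        cur_end <- e[i]
      }
      grp_sorted[i] <- cur
    }
  }
  merged <- tibble(
    start = as.integer(tapply(s, grp_sorted, min)),
    end   = as.integer(tapply(e, grp_sorted, max))
  )
  group <- integer(n)
  group[ord] <- grp_sorted
  list(merged = merged, group = group)
}

# Total length of the union of half-open intervals.
union_width <- function(start, end) {
  m <- merge_halfopen(start, end)$merged
  # merged intervals may still abut; width sums are correct either way
  sum(as.numeric(m$end - m$start))
}

# Deterministic per-stage seed derivation from one global seed: a small
# string hash folded into [0, 2^20), offset by the global seed modulo 2^30
# so derived seeds remain valid 32-bit integers.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 1048576L
  as.integer((as.integer(seed) %% 1073741824L) + h)
}
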