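# shortcut constructors used throughout the suite

pr <- function(a, b, ...) paired_ratings(a, b, ...)

# binary ratings with prescribed agreement pattern: na cases (+,+),
# nd_ab cases (+,-), nd_ba cases (-,+), nn cases (-,-)
pattern_ratings <- function(na_pp = 0, nd_ab = 0, nd_ba = 0, na_mm = 0) {
  a <- c(rep("+", na_pp + nd_ab), rep("-", nd_ba + na_mm))
  b <- c(rep("+", na_pp), rep("-", nd_ab), rep("+", nd_ba), rep("-", na_mm))
  paired_ratings(a, b, categories = c("+", "-"))
}
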