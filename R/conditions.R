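.hel_cache <- new.env(parent = emptyenv())

# Classed error conditions so callers (and tests) can discriminate failure
# modes without string matching.

hel_error <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "helidesign_error")))
}

hel_warning <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "helidesign_warning")))
}
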