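# internal helpers

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# quantile dialect fixed package-wide: type 7 (linear interpolation)
quantile7 <- function(x, p) stats::quantile(x, probs = p, names = FALSE, type = 7)

`%||%` <- function(a, b) if (is.null(a)) b else a

log_note <- function(...) message(sprintf(...))
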