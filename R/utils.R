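# Internal helpers shared across modules.

# Classed conditions so callers can distinguish format, parse and
# validation failures programmatically.
abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "frinstab_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Standard gravity; normal force on the contact is (applied mass + finger
# deadweight) * g, masses in grams.
GRAVITY <- 9.81

normal_force <- function(applied_mass, deadweight = 6) {
  (applied_mass + deadweight) / 1000 * GRAVITY
}

# Full-precision numeric formatting so write/read round-trips are
# bit-comparable for doubles.
fmt_num <- function(x) sprintf("%.17g", x)

# Derive a bounded child seed from a master seed and a counter (keeps
# within 32-bit integer range).
child_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(counter)) %% 2147483647)
}
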