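# Constants shared across modules (file sorts first for load order).

# the five positional regions, 5' to 3'
REGION_LABELS <- c("five_prime_utr", "start", "cds", "stop", "three_prime_utr")
# half-width of the start/stop codon windows (nt)
REGION_WINDOW <- 50L
# positional archetypes the simulator can plant (plus "none" = unbound)
ARCHETYPES <- c(REGION_LABELS, "none")

`%||%` <- function(a, b) if (is.null(a)) b else a
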