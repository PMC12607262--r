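`%||%` <- function(a, b) if (is.null(a)) b else a

# classed error helper so callers (and the CLI) can react to specific failures
stop_rnac <- function(type, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(paste0("rnaconsensus_", type),
                                "rnaconsensus_error", "error", "condition")))
}

# 62-symbol chain alphabet: uppercase, lowercase, digits (PDB chain id space)
chain_alphabet <- function() c(LETTERS, letters, as.character(0:9))

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# deterministic 6-decimal formatting used by all CSV writers
fmt_num <- function(x) sprintf("%.6f", x)
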