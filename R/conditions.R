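# Classed conditions so callers (and the CLI) can distinguish bad
# configuration from bad data from bad schemas.

ovutherm_error <- function(subclass, msg) {
  cond <- structure(
    list(message = msg, call = sys.call(-2)),
    class = c(paste0("ovutherm_", subclass), "ovutherm_error",
              "error", "condition"))
  stop(cond)
}

schema_error <- function(msg) ovutherm_error("schema_error", msg)
data_error   <- function(msg) ovutherm_error("data_error", msg)
config_error <- function(msg) ovutherm_error("config_error", msg)
domain_error <- function(msg) ovutherm_error("domain_error", msg)
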