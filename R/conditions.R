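# Classed conditions so callers (and the batch runner) can discriminate failure modes.

zh_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "zebraheart_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

zh_format_error <- function(msg) zh_error("zh_format_error", msg)
zh_parse_error <- function(msg) zh_error("zh_parse_error", msg)
zh_parameter_error <- function(msg) zh_error("zh_parameter_error", msg)
zh_domain_error <- function(msg) zh_error("zh_domain_error", msg)
zh_contract_error <- function(msg) zh_error("zh_contract_error", msg)
zh_io_error <- function(msg) zh_error("zh_io_error", msg)
zh_insufficient_beats <- function(msg) zh_error("zh_insufficient_beats", msg)
zh_unrecoverable_track <- function(msg) zh_error("zh_unrecoverable_track", msg)
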