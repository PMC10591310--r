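# Classed error conditions so callers and tests can dispatch on failure mode
# rather than on message text.

dsr_abort <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c(class, "dsr_error"),
                      call = sys.call(-1)))
}

abort_empty_input     <- function(msg, ...) dsr_abort("dsr_empty_input", msg, ...)
abort_alphabet        <- function(msg, ...) dsr_abort("dsr_alphabet_error", msg, ...)
abort_duplicate_id    <- function(msg, ...) dsr_abort("dsr_duplicate_id", msg, ...)
abort_metadata        <- function(msg, ...) dsr_abort("dsr_metadata_mismatch", msg, ...)
abort_label_domain    <- function(msg, ...) dsr_abort("dsr_label_domain_error", msg, ...)
abort_orientation     <- function(msg, ...) dsr_abort("dsr_orientation_error", msg, ...)
abort_length          <- function(msg, ...) dsr_abort("dsr_length_error", msg, ...)
abort_alignment       <- function(msg, ...) dsr_abort("dsr_alignment_error", msg, ...)
abort_taxonomy        <- function(msg, ...) dsr_abort("dsr_taxonomy_error", msg, ...)
abort_config          <- function(msg, ...) dsr_abort("dsr_config_error", msg, ...)
abort_empty_clade     <- function(msg, ...) dsr_abort("dsr_empty_clade_error", msg, ...)
abort_schema          <- function(msg, ...) dsr_abort("dsr_schema_error", msg, ...)
abort_no_dsr          <- function(msg, ...) dsr_abort("dsr_no_dsr_error", msg, ...)
abort_value           <- function(msg, ...) dsr_abort("dsr_value_error", msg, ...)
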