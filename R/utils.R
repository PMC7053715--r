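# internal helpers shared across modules

csk_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "cropshock_error", "error", "condition")))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# structural fingerprint of an arbitrary (small) R object; used for decision
# caching and config provenance
csk_fingerprint <- function(x) {
  tf <- tempfile(fileext = ".rds")
  on.exit(unlink(tf), add = TRUE)
  # version fixed so the hash is stable across R sessions
  saveRDS(x, tf, version = 2)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
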