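# Shared helpers: classed conditions and small array utilities.

stop_strokeloc <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "strokeloc_error"),
                      call = call))
}

stop_format    <- function(msg) stop_strokeloc(msg, "strokeloc_format_error")
stop_geometry  <- function(msg) stop_strokeloc(msg, "strokeloc_geometry_error")
stop_parameter <- function(msg) stop_strokeloc(msg, "strokeloc_parameter_error")
stop_usage     <- function(msg) stop_strokeloc(msg, "strokeloc_usage_error")
stop_state     <- function(msg) stop_strokeloc(msg, "strokeloc_state_error")

# Deterministic sub-seed derivation: keeps derived seeds positive and below
# 2^31 whatever the master seed is.
derive_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 1009 + index * 9176) %% 2147483647L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_imat <- function(x) {
  storage.mode(x) <- "integer"
  x
}

# 3D array -> list of matrices (one per slice along dim 3)
slice_list <- function(arr) {
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}
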