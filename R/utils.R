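# Internal helpers: typed error conditions and argument checks.

stop_with <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("toeinkam_", class), "toeinkam_error")))
}

abort_schema    <- function(msg) stop_with(msg, "schema_error")
abort_format    <- function(msg) stop_with(msg, "format_error")
abort_integrity <- function(msg) stop_with(msg, "integrity_error")
abort_version   <- function(msg) stop_with(msg, "version_error")
abort_value     <- function(msg) stop_with(msg, "value_error")

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    abort_value(sprintf("'%s' must be a single finite number", name))
  if (x < lower || x > upper)
    abort_value(sprintf("'%s' = %g outside [%g, %g]", name, x, lower, upper))
  invisible(x)
}

# Channels carried by every stance cycle. The first four are pelvis-relative
# and are the ones patterns are learned on; *_LAB_* are lab-frame positions
# used for the lever-arm KAM; GRF_* are plate forces.
PATTERN_CHANNELS <- c("KJC_ML", "KJC_AP", "FCP_ML", "FCP_AP")
LAB_CHANNELS     <- c("KJC_LAB_ML", "KJC_LAB_Z", "COP_LAB_ML", "COP_LAB_Z")
GRF_CHANNELS     <- c("GRF_ML", "GRF_AP", "GRF_V")
CYCLE_CHANNELS   <- c(PATTERN_CHANNELS, LAB_CHANNELS, GRF_CHANNELS)

N_STANCE_SAMPLES <- 101L  # 0..100% stance inclusive

# %BW*HT uses standard gravity
GRAVITY <- 9.81
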