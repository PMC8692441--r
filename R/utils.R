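#' @importFrom rlang abort warn %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n across all_of
#' @importFrom tibble tibble as_tibble new_tibble
NULL

# consistent condition classes so callers can distinguish user error kinds
stop_validation <- function(msg, field = NULL) {
  if (!is.null(field)) msg <- sprintf("%s (field `%s`)", msg, field)
  abort(msg, class = "loyscan_validation_error")
}

stop_parse <- function(msg) abort(msg, class = "loyscan_parse_error")

check_number <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, allow_null = FALSE) {
  if (is.null(x)) {
    if (allow_null) return(invisible(x))
    stop_validation("value is required", field)
  }
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("must be a single finite number", field)
  }
  if (strict_min && x <= min) {
    stop_validation(sprintf("must be > %s", format(min)), field)
  }
  if (!strict_min && x < min) {
    stop_validation(sprintf("must be >= %s", format(min)), field)
  }
  if (x > max) stop_validation(sprintf("must be <= %s", format(max)), field)
  invisible(x)
}

# stable per-sample seed stream: mixing (master, index) through a
# Lehmer-style step keeps every derived seed in [1, 2^31 - 2] and makes a
# sample's stream independent of cohort membership changes
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  s <- (abs(as.double(master_seed)) %% m)
  s <- (s * 48271 + as.double(index) * 69621 + 11) %% m
  as.integer(s + 1)
}

require_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_validation(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}
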