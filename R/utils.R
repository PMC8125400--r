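# shared internal helpers

# user-facing input errors get a dedicated class so the CLI can map them to
# exit code 1 (internal faults keep code 2)
stop_user <- function(...) {
  stop(structure(class = c("picboost_user_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# trapezoidal integral of y over x (x ascending, may be irregular)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_positive <- function(x, name) {
  if (!is_number(x) || x <= 0) stop_user("'", name, "' must be a positive number")
  x
}
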