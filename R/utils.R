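# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_contract <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' @noRd
check_axis <- function(wavenumber, what = "wavenumber axis") {
  if (!is.numeric(wavenumber) || length(wavenumber) < 1L)
    stop_contract("%s must be a non-empty numeric vector", what)
  if (anyNA(wavenumber) || any(!is.finite(wavenumber)))
    stop_contract("%s contains non-finite values", what)
  if (any(wavenumber <= 0))
    stop_contract("%s must be strictly positive (cm^-1)", what)
  if (length(wavenumber) > 1L && any(diff(wavenumber) <= 0))
    stop_contract("%s must be strictly increasing", what)
  invisible(wavenumber)
}

# indices of axis points inside the closed interval [lo, hi]
axis_window_idx <- function(wavenumber, lo, hi) {
  if (lo >= hi) stop_contract("window lower bound %g must be < upper bound %g", lo, hi)
  which(wavenumber >= lo & wavenumber <= hi)
}

axis_is_uniform <- function(wavenumber, rel_tol = 1e-8) {
  if (length(wavenumber) < 3L) return(TRUE)
  d <- diff(wavenumber)
  max(abs(d - d[1])) <= rel_tol * abs(d[1])
}

# deterministic substream seed below 2^31, from a base seed and labels
derive_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
  }, numeric(1))
  s <- as.numeric(seed) %% 2147483647
  for (p in parts) s <- (s * 69069 + p * 1009 + 13) %% 2147483647
  as.integer(s)
}

# tiny FNV-1a style hash for provenance stamps (hex string)
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

pkg_provenance <- function(extra = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("vibrostage")), error = function(e) "dev")
  paste0("# vibrostage ", v, if (!is.null(extra)) paste0(" ", extra))
}
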