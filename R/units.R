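#' Parse a physical quantity with a unit suffix
#'
#' Configuration files state every physical value with an explicit unit
#' (e.g. `"40 mm"`, `"22 pF"`, `"0.5 uH"`, `"20 MHz"`, `"3.3 ohm/m"`).
#' `parse_quantity()` converts such a string (or a bare number, taken as SI)
#' to the SI base value used internally: metres, farads, henries, hertz,
#' ohms, seconds.
#'
#' @param x A length-1 character string such as `"40 mm"`, or a numeric
#'   value (returned unchanged).
#' @return A numeric scalar in SI units.
#' @examples
#' parse_quantity("40 mm")   # 0.04
#' parse_quantity("22 pF")   # 2.2e-11
#' parse_quantity("20 MHz")  # 2e+07
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L)
    return(as.numeric(x))
  }
  stopifnot(is.character(x), length(x) == 1L)
  x <- trimws(x)
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*([^0-9[:space:]][^[:space:]]*)?$", x))[[1]]
  if (length(m) == 0L || m[2] == "") {
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  }
  value <- suppressWarnings(as.numeric(m[2]))
  if (is.na(value)) stop("cannot parse quantity: '", x, "'", call. = FALSE)
  unit <- if (length(m) >= 3L) m[3] else ""
  if (is.na(unit) || unit == "") return(value)
  scale <- .unit_table[[unit]]
  if (is.null(scale)) stop("unknown unit '", unit, "' in '", x, "'", call. = FALSE)
  value * scale
}

# SI scale factors; "u" accepted as micro alongside the Greek letter.
.unit_table <- local({
  tab <- list(
    # length
    "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6,
    # capacitance
    "F" = 1, "mF" = 1e-3, "uF" = 1e-6, "nF" = 1e-9, "pF" = 1e-12,
    # inductance
    "H" = 1, "mH" = 1e-3, "uH" = 1e-6, "nH" = 1e-9,
    # frequency
    "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6, "GHz" = 1e9,
    # resistance (plain and per-length)
    "ohm" = 1, "Ohm" = 1, "ohm/m" = 1, "Ohm/m" = 1,
    # time
    "s" = 1, "ms" = 1e-3, "us" = 1e-6
  )
  tab[["µH"]] <- 1e-6
  tab[["μH"]] <- 1e-6
  tab[["µF"]] <- 1e-6
  tab[["μF"]] <- 1e-6
  tab[["µm"]] <- 1e-6
  tab[["μm"]] <- 1e-6
  tab[["Ω"]] <- 1
  tab[["Ω/m"]] <- 1
  tab
})

# Internal scalar validators ------------------------------------------------

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop("'", name, "' must be a positive number", call. = FALSE)
  }
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop("'", name, "' must be a non-negative number", call. = FALSE)
  }
  invisible(x)
}
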