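#' Prime field specification
#'
#' Discrete model states live in the integers modulo a prime `p`: each
#' variable takes values in `{0, ..., p-1}` and all coefficient arithmetic
#' is carried out modulo `p`. Boolean models use `p = 2`; multi-valued
#' logical models use the smallest prime exceeding every variable's
#' maximum level. Prime-power fields GF(p^k), k > 1, are deliberately not
#' supported: every model type handled here maps its levels onto
#' consecutive residues, which only requires prime order.
#'
#' @param p Number of states per variable; must be a prime >= 2.
#' @return An integer of class `field_spec`.
#' @examples
#' field_spec(2)
#' field_spec(3)
#' @export
field_spec <- function(p) {
  p <- as.integer(p)
  if (length(p) != 1L || is.na(p) || !is_prime(p)) {
    stop("field order p must be a single prime >= 2, got ", deparse(p))
  }
  structure(p, class = "field_spec")
}

#' Test whether an integer is prime
#'
#' @param p integer scalar
#' @return `TRUE` if `p` is a prime number.
#' @keywords internal
#' @export
is_prime <- function(p) {
  p <- as.integer(p)
  if (is.na(p) || p < 2L) return(FALSE)
  if (p < 4L) return(TRUE)
  if (p %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= p) {
    if (p %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field F_%d>\n", unclass(x)))
  invisible(x)
}

# coerce a p argument (plain integer or field_spec) to validated integer
as_field_p <- function(p) {
  if (inherits(p, "field_spec")) return(as.integer(unclass(p)))
  as.integer(unclass(field_spec(p)))
}
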