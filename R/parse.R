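# Recursive-descent parsers for the two expression grammars:
#   polynomial:  +, -, *, ^, parentheses, integer coefficients, x<i>
#   boolean:     NOT/AND/OR (case-insensitive) or ! ~ & |, parentheses,
#                constants 0/1, variables x<i>
# Errors carry the 1-based character position of the offending token.

tokenize <- function(text, boolean = FALSE) {
  pats <- c(
    ws    = "\\s+",
    num   = "[0-9]+",
    var   = "x[0-9]+",
    word  = "[A-Za-z_][A-Za-z0-9_]*",
    op    = if (boolean) "[()!~&|]" else "[-+*^()]"
  )
  toks <- list()
  pos <- 1L
  nch <- nchar(text)
  while (pos <= nch) {
    rest <- substr(text, pos, nch)
    matched <- FALSE
    for (ty in names(pats)) {
      m <- regmatches(rest, regexpr(paste0("^(", pats[[ty]], ")"), rest))
      if (length(m) == 1L && nchar(m) > 0L) {
        if (ty != "ws") {
          toks[[length(toks) + 1L]] <- list(type = ty, value = m, pos = pos)
        }
        pos <- pos + nchar(m)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      stop("unexpected character '", substr(text, pos, pos), "' at position ", pos)
    }
  }
  toks
}

new_token_stream <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks
  env$i <- 1L
  env
}

ts_peek <- function(ts) if (ts$i <= length(ts$toks)) ts$toks[[ts$i]] else NULL

ts_next <- function(ts) {
  tok <- ts_peek(ts)
  if (!is.null(tok)) ts$i <- ts$i + 1L
  tok
}

ts_expect <- function(ts, value) {
  tok <- ts_next(ts)
  if (is.null(tok)) stop("unexpected end of expression; expected '", value, "'")
  if (tok$value != value) {
    stop("expected '", value, "' at position ", tok$pos, ", found '", tok$value, "'")
  }
  tok
}

var_index <- function(tok, nvars) {
  i <- as.integer(sub("^x", "", tok$value))
  if (is.na(i) || i < 1L || i > nvars) {
    stop("variable ", tok$value, " out of range 1..", nvars,
         " at position ", tok$pos)
  }
  i
}

#' Parse a polynomial expression
#'
#' Grammar: sums and differences of products of powers; `*` is required
#' between factors (no juxtaposition), `^` takes a non-negative integer
#' exponent, variables are `x1..xn`. The result is canonicalized over
#' F_p.
#'
#' @param text expression string, e.g. `"x1*x2 + 2*x3^2 + 1"`.
#' @param p prime field order.
#' @param nvars number of variables in the ambient ring.
#' @return An [fpoly].
#' @export
parse_polynomial <- function(text, p, nvars) {
  p <- as_field_p(p)
  nvars <- as.integer(nvars)
  ts <- new_token_stream(tokenize(text, boolean = FALSE))

  parse_expr <- function() {
    tok <- ts_peek(ts)
    neg <- FALSE
    if (!is.null(tok) && tok$value %in% c("+", "-")) {
      ts_next(ts)
      neg <- tok$value == "-"
    }
    acc <- parse_term()
    if (neg) acc <- fp_neg(acc)
    repeat {
      tok <- ts_peek(ts)
      if (is.null(tok) || !(tok$value %in% c("+", "-"))) break
      ts_next(ts)
      rhs <- parse_term()
      acc <- if (tok$value == "+") fp_add(acc, rhs) else fp_sub(acc, rhs)
    }
    acc
  }
  parse_term <- function() {
    acc <- parse_factor()
    repeat {
      tok <- ts_peek(ts)
      if (is.null(tok) || tok$value != "*") break
      ts_next(ts)
      acc <- fp_mul(acc, parse_factor())
    }
    acc
  }
  parse_factor <- function() {
    base <- parse_base()
    tok <- ts_peek(ts)
    if (!is.null(tok) && tok$value == "^") {
      ts_next(ts)
      etok <- ts_next(ts)
      if (is.null(etok) || etok$type != "num") {
        stop("expected integer exponent after '^'",
             if (!is.null(etok)) paste0(" at position ", etok$pos) else "")
      }
      base <- fp_pow(base, as.integer(etok$value))
    }
    base
  }
  parse_base <- function() {
    tok <- ts_next(ts)
    if (is.null(tok)) stop("unexpected end of expression")
    if (tok$type == "num") return(fp_const(as.integer(tok$value) %% p, p, nvars))
    if (tok$type == "var") return(fp_var(var_index(tok, nvars), p, nvars))
    if (tok$value == "(") {
      inner <- parse_expr()
      ts_expect(ts, ")")
      return(inner)
    }
    if (tok$value == "-") return(fp_neg(parse_base()))
    stop("unexpected token '", tok$value, "' at position ", tok$pos)
  }

  out <- parse_expr()
  tok <- ts_peek(ts)
  if (!is.null(tok)) {
    stop("trailing input '", tok$value, "' at position ", tok$pos)
  }
  out
}

#' Parse a Boolean expression into a polynomial over F_2
#'
#' Translation rules: `NOT a -> a + 1`, `a AND b -> a*b`,
#' `a OR b -> a + b + a*b`, applied recursively and canonicalized, so the
#' truth table of the polynomial equals that of the expression.
#' `AND`/`OR`/`NOT` are matched case-insensitively; `&`, `|`, `!`, `~`
#' are accepted aliases. Precedence is NOT > AND > OR. XOR is not a
#' primitive (write it with AND/OR/NOT).
#'
#' @param text Boolean expression, e.g. `"(x1 OR x2) AND NOT x3"`.
#' @param nvars number of variables.
#' @return An [fpoly] over F_2.
#' @export
parse_boolean <- function(text, nvars) {
  nvars <- as.integer(nvars)
  p <- 2L
  ts <- new_token_stream(tokenize(text, boolean = TRUE))
  is_word <- function(tok, w) {
    !is.null(tok) && ((tok$type == "word" && toupper(tok$value) == w) ||
                        (w == "AND" && tok$value == "&") ||
                        (w == "OR" && tok$value == "|") ||
                        (w == "NOT" && tok$value %in% c("!", "~")))
  }
  one <- fp_const(1L, p, nvars)

  parse_or <- function() {
    acc <- parse_and()
    while (is_word(ts_peek(ts), "OR")) {
      ts_next(ts)
      b <- parse_and()
      acc <- fp_add(fp_add(acc, b), fp_mul(acc, b))
    }
    acc
  }
  parse_and <- function() {
    acc <- parse_not()
    while (is_word(ts_peek(ts), "AND")) {
      ts_next(ts)
      acc <- fp_mul(acc, parse_not())
    }
    acc
  }
  parse_not <- function() {
    if (is_word(ts_peek(ts), "NOT")) {
      ts_next(ts)
      return(fp_add(parse_not(), one))
    }
    parse_atom()
  }
  parse_atom <- function() {
    tok <- ts_next(ts)
    if (is.null(tok)) stop("unexpected end of expression")
    if (tok$type == "var") return(fp_var(var_index(tok, nvars), p, nvars))
    if (tok$type == "num") {
      v <- as.integer(tok$value)
      if (!v %in% c(0L, 1L)) {
        stop("Boolean constant must be 0 or 1 at position ", tok$pos)
      }
      return(fp_const(v, p, nvars))
    }
    if (tok$value == "(") {
      inner <- parse_or()
      ts_expect(ts, ")")
      return(inner)
    }
    stop("unexpected token '", tok$value, "' at position ", tok$pos)
  }

  out <- parse_or()
  tok <- ts_peek(ts)
  if (!is.null(tok)) stop("trailing input '", tok$value, "' at position ", tok$pos)
  out
}
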