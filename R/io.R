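#' Read a model file
#'
#' Plain-text model formats, one per analysis input type:
#'
#' * `"polynomial"` — lines `f<i> = <polynomial>` over F_p (see
#'   [parse_polynomial()]); variables `x1..xn` with `n` inferred from the
#'   largest index used (rule or variable); coordinates without a rule
#'   line default to the identity `x_i`.
#' * `"boolean"` — lines `f<i> = <Boolean expression>` (see
#'   [parse_boolean()]); always F_2.
#' * `"table"` — a multi-valued logical model: a header line
#'   `levels <l1> <l2> ...` with each variable's maximum level, then one
#'   block per variable starting `f<i>`, whose rows give an input tuple
#'   (one level per variable) followed by the output level,
#'   whitespace-separated. Parsed into a [logical_table()] and extended
#'   over F_p with [extend_multivalued()].
#' * `"probabilistic"` — lines `f<i> = <polynomial> # <probability>`,
#'   several lines per coordinate; the probability (decimal or `a/b`)
#'   is optional, and coordinates with no probabilities get the uniform
#'   distribution.
#'
#' Lines starting with `#` and blank lines are ignored (in the
#' probabilistic format `#` after an expression introduces the
#' probability instead). An optional alias table maps external names
#' (e.g. gene symbols) to variables: names are substituted by `x<i>`
#' before parsing, on both sides of the `=`.
#'
#' @param path file path.
#' @param format one of `"polynomial"`, `"boolean"`, `"table"`,
#'   `"probabilistic"`.
#' @param p prime field order (ignored for `"boolean"`; for `"table"` it
#'   must cover every variable's levels).
#' @param aliases optional named integer vector mapping variable names to
#'   indices, e.g. `c(WG = 1, EN = 2)`.
#' @return A [pds] (polynomial/boolean/table) or [ppds] (probabilistic).
#' @export
parse_model <- function(path, format = c("polynomial", "boolean", "table",
                                         "probabilistic"),
                        p = 2L, aliases = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_parse(paste0("model file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  parse_model_lines(lines, format = format, p = p, aliases = aliases)
}

#' @rdname parse_model
#' @param lines character vector of model lines (in-memory variant).
#' @export
parse_model_lines <- function(lines, format = c("polynomial", "boolean", "table",
                                                "probabilistic"),
                              p = 2L, aliases = NULL) {
  format <- match.arg(format)
  p <- tryCatch(as_field_p(p), error = function(e) stop_parse(conditionMessage(e)))
  if (!is.null(aliases)) {
    for (nm in names(aliases)) {
      lines <- gsub(paste0("\\b", nm, "\\b"), paste0("x", aliases[[nm]]), lines)
    }
  }
  switch(format,
         polynomial = parse_rule_file(lines, p, boolean = FALSE),
         boolean = parse_rule_file(lines, 2L, boolean = TRUE),
         table = parse_table_file(lines, p),
         probabilistic = parse_prob_file(lines, p))
}

rule_line_re <- "^\\s*f([0-9]+)\\s*=\\s*(.*?)\\s*$"

split_rule_lines <- function(lines, allow_prob = FALSE) {
  out <- list()
  for (ln in seq_along(lines)) {
    raw <- lines[[ln]]
    s <- trimws(raw)
    if (s == "" || startsWith(s, "#")) next
    prob <- NA_character_
    if (allow_prob && grepl("#", s)) {
      parts <- strsplit(s, "#", fixed = TRUE)[[1L]]
      s <- trimws(parts[[1L]])
      prob <- trimws(paste(parts[-1L], collapse = "#"))
    }
    if (!grepl(rule_line_re, s)) {
      stop_parse(paste0("line ", ln, ": expected 'f<i> = <expression>', got: ", raw))
    }
    i <- as.integer(sub(rule_line_re, "\\1", s))
    expr <- sub(rule_line_re, "\\2", s)
    if (expr == "") stop_parse(paste0("line ", ln, ": empty right-hand side"))
    out[[length(out) + 1L]] <- list(i = i, expr = expr, prob = prob, line = ln)
  }
  if (length(out) == 0L) stop_parse("no rules found in model file")
  out
}

parse_rule_file <- function(lines, p, boolean) {
  rules <- split_rule_lines(lines)
  max_f <- max(vapply(rules, function(r) r$i, integer(1)))
  max_x <- 0L
  for (r in rules) {
    xs <- regmatches(r$expr, gregexpr("x[0-9]+", r$expr))[[1L]]
    if (length(xs)) max_x <- max(max_x, as.integer(sub("x", "", xs)))
  }
  n <- max(max_f, max_x)
  fns <- lapply(seq_len(n), fp_var, p = p, nvars = n)  # default: identity
  seen <- logical(n)
  for (r in rules) {
    if (seen[r$i]) stop_parse(paste0("line ", r$line, ": duplicate rule for f", r$i))
    seen[r$i] <- TRUE
    fns[[r$i]] <- tryCatch(
      if (boolean) parse_boolean(r$expr, n) else parse_polynomial(r$expr, p, n),
      error = function(e) stop_parse(paste0("line ", r$line, ": ",
                                            conditionMessage(e))))
  }
  pds(fns, p = p)
}

parse_prob_file <- function(lines, p) {
  rules <- split_rule_lines(lines, allow_prob = TRUE)
  max_f <- max(vapply(rules, function(r) r$i, integer(1)))
  max_x <- 0L
  for (r in rules) {
    xs <- regmatches(r$expr, gregexpr("x[0-9]+", r$expr))[[1L]]
    if (length(xs)) max_x <- max(max_x, as.integer(sub("x", "", xs)))
  }
  n <- max(max_f, max_x)
  fns <- rep(list(list()), n)
  prs <- rep(list(character(0)), n)
  for (r in rules) {
    f <- tryCatch(parse_polynomial(r$expr, p, n),
                  error = function(e) stop_parse(paste0("line ", r$line, ": ",
                                                        conditionMessage(e))))
    fns[[r$i]] <- c(fns[[r$i]], list(f))
    prs[[r$i]] <- c(prs[[r$i]], r$prob)
  }
  for (i in seq_len(n)) {
    if (length(fns[[i]]) == 0L) {
      fns[[i]] <- list(fp_var(i, p, n))
      prs[[i]] <- NA_character_
    }
  }
  probs <- lapply(seq_len(n), function(i) {
    pr <- prs[[i]]
    if (all(is.na(pr))) return(NULL)
    if (anyNA(pr)) {
      stop_parse(paste0("coordinate ", i,
                        ": either all rules or none must carry probabilities"))
    }
    pr
  })
  tryCatch(ppds(fns, probs = probs, p = p),
           error = function(e) stop_parse(conditionMessage(e)))
}

parse_table_file <- function(lines, p) {
  toks <- lapply(lines, function(s) strsplit(trimws(s), "[ \t]+")[[1L]])
  keep <- which(vapply(seq_along(lines), function(ln) {
    s <- trimws(lines[[ln]])
    s != "" && !startsWith(s, "#")
  }, logical(1)))
  if (length(keep) == 0L) stop_parse("empty table file")
  hdr <- toks[[keep[[1L]]]]
  if (tolower(hdr[[1L]]) != "levels") {
    stop_parse(paste0("line ", keep[[1L]], ": table file must start with 'levels <l1> <l2> ...'"))
  }
  max_levels <- suppressWarnings(as.integer(hdr[-1L]))
  if (anyNA(max_levels) || any(max_levels < 1L)) {
    stop_parse(paste0("line ", keep[[1L]], ": bad levels header"))
  }
  n <- length(max_levels)
  N <- prod(max_levels + 1L)
  outputs <- rep(list(rep(NA_integer_, N)), n)
  cur <- NA_integer_
  for (ln in keep[-1L]) {
    tk <- toks[[ln]]
    if (length(tk) == 1L && grepl("^f[0-9]+$", tk)) {
      cur <- as.integer(sub("f", "", tk))
      if (cur < 1L || cur > n) stop_parse(paste0("line ", ln, ": variable f", cur,
                                                 " out of range 1..", n))
      next
    }
    if (is.na(cur)) stop_parse(paste0("line ", ln, ": row before any 'f<i>' block header"))
    vals <- suppressWarnings(as.integer(tk))
    if (anyNA(vals) || length(vals) != n + 1L) {
      stop_parse(paste0("line ", ln, ": expected ", n,
                        " input levels and one output level"))
    }
    inp <- vals[seq_len(n)]
    if (any(inp < 0L | inp > max_levels)) {
      stop_parse(paste0("line ", ln, ": input level out of declared range"))
    }
    sizes <- max_levels + 1L
    idx <- 0
    for (j in seq_len(n)) idx <- idx * sizes[j] + inp[j]
    outputs[[cur]][idx + 1L] <- vals[n + 1L]
  }
  for (i in seq_len(n)) {
    if (anyNA(outputs[[i]])) {
      stop_parse(paste0("incomplete table for variable f", i, ": ",
                        sum(is.na(outputs[[i]])), " input tuples missing"))
    }
  }
  tab <- tryCatch(logical_table(max_levels, outputs),
                  error = function(e) stop_parse(conditionMessage(e)))
  extend_multivalued(tab, p)
}

#' Write a model file
#'
#' The inverse of [parse_model()]: writing a parsed model and re-parsing
#' it reproduces the model exactly (canonical forms are unique).
#' `format = "boolean"` rewrites each F_2 rule as a disjunctive normal
#' form over its support.
#'
#' @param model a [pds] or [ppds].
#' @param path output file, or `NULL` to return the lines invisibly.
#' @param format `"polynomial"` (any model), `"boolean"` (F_2 [pds]
#'   only), or `"probabilistic"` ([ppds]).
#' @return The model lines, invisibly.
#' @export
write_model <- function(model, path = NULL,
                        format = c("polynomial", "boolean", "probabilistic")) {
  format <- match.arg(format)
  lines <- switch(format,
    polynomial = {
      if (!inherits(model, "pds")) stop("polynomial format needs a pds")
      vapply(seq_len(model$nvars), function(i) {
        sprintf("f%d = %s", i, format(model$functions[[i]]))
      }, character(1))
    },
    boolean = {
      if (!inherits(model, "pds") || model$p != 2L) {
        stop("boolean format needs a pds over F_2")
      }
      vapply(seq_len(model$nvars), function(i) {
        sprintf("f%d = %s", i, boolean_expression(model$functions[[i]]))
      }, character(1))
    },
    probabilistic = {
      if (!inherits(model, "ppds")) stop("probabilistic format needs a ppds")
      unlist(lapply(seq_len(model$nvars), function(i) {
        vapply(seq_along(model$functions[[i]]), function(r) {
          w <- model$probs[[i]][r, ]
          sprintf("f%d = %s # %g/%g", i, format(model$functions[[i]][[r]]),
                  w[1], w[2])
        }, character(1))
      }))
    })
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

# DNF over the support of an F_2 polynomial (for the boolean writer)
boolean_expression <- function(f) {
  if (fp_is_zero(f)) return("0")
  supp <- fp_support(f)
  if (length(supp) == 0L) return(as.character(fp_constant_value(f)))
  tt <- fp_truth_table(f, vars = supp)
  grid <- all_states(2L, length(supp))
  ones <- which(tt == 1L)
  if (length(ones) == 0L) return("0")
  if (length(ones) == nrow(grid)) return("1")
  terms <- vapply(ones, function(r) {
    lits <- vapply(seq_along(supp), function(k) {
      if (grid[r, k] == 1L) paste0("x", supp[k]) else paste0("NOT x", supp[k])
    }, character(1))
    if (length(lits) == 1L) lits else paste0("(", paste(lits, collapse = " AND "), ")")
  }, character(1))
  paste(terms, collapse = " OR ")
}
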