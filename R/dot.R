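# DOT (Graphviz) emission. Wiring-diagram edge styles: solid arrowhead
# for activation (+), tee/blunt head for inhibition (-), dashed for
# non-unate or unsigned edges.

dot_quote <- function(s) paste0("\"", s, "\"")

#' Emit graphs in DOT format
#'
#' @param x the object to render (wiring diagram, phase space,
#'   trajectory, probabilistic transition graph).
#' @param path output file, or `NULL` to return the lines.
#' @param ... unused.
#' @return Character vector of DOT lines, invisibly when written.
#' @export
to_dot <- function(x, path = NULL, ...) UseMethod("to_dot")

dot_finish <- function(lines, path) {
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname to_dot
#' @export
to_dot.wiring_diagram <- function(x, path = NULL, ...) {
  lines <- c("digraph wiring {", "  node [shape=circle];")
  for (i in seq_len(x$nvars)) {
    lines <- c(lines, sprintf("  %s;", dot_quote(paste0("x", i))))
  }
  for (k in seq_len(nrow(x$edges))) {
    e <- x$edges[k, ]
    style <- if (is.na(e$sign)) "style=dashed"
    else if (e$sign == "+") "arrowhead=normal"
    else if (e$sign == "-") "arrowhead=tee"
    else "style=dashed, arrowhead=odot"
    lines <- c(lines, sprintf("  %s -> %s [%s];",
                              dot_quote(paste0("x", e$from)),
                              dot_quote(paste0("x", e$to)), style))
  }
  dot_finish(c(lines, "}"), path)
}

#' @rdname to_dot
#' @export
to_dot.phase_space <- function(x, path = NULL, ...) {
  keys <- vapply(asplit(x$states, 1), state_to_string, character(1))
  lines <- c("digraph phase_space {", "  node [shape=box];")
  lines <- c(lines, sprintf("  %s -> %s;", dot_quote(keys), dot_quote(keys[x$succ])))
  dot_finish(c(lines, "}"), path)
}

#' @rdname to_dot
#' @export
to_dot.pds_trajectory <- function(x, path = NULL, ...) {
  keys <- vapply(asplit(x$path, 1), state_to_string, character(1))
  lines <- c("digraph trajectory {", "  node [shape=box];")
  if (length(keys) > 1L) {
    lines <- c(lines, sprintf("  %s -> %s;",
                              dot_quote(keys[-length(keys)]), dot_quote(keys[-1L])))
  }
  # closing edge of the attractor
  akeys <- vapply(asplit(x$attractor$states, 1), state_to_string, character(1))
  lines <- c(lines, sprintf("  %s -> %s;", dot_quote(akeys[length(akeys)]),
                            dot_quote(akeys[1L])))
  dot_finish(c(lines, "}"), path)
}

#' @rdname to_dot
#' @export
to_dot.prob_phase_space <- function(x, path = NULL, ...) {
  lines <- c("digraph prob_phase_space {", "  node [shape=box];")
  for (k in seq_len(nrow(x$edges))) {
    e <- x$edges[k, ]
    lines <- c(lines, sprintf("  %s -> %s [label=\"%g/%g\"];",
                              dot_quote(e$from), dot_quote(e$to), e$num, e$den))
  }
  dot_finish(c(lines, "}"), path)
}
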