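# Excel-like formula language for well and plate calculations.
#
# Grammar (standard precedence, left associative):
#   expr    := term (("+"|"-") term)*
#   term    := factor (("*"|"/") factor)*
#   factor  := "-" factor | primary
#   primary := number | "value" | WELLREF
#            | ("avg"|"sd"|"cv"|"min"|"max"|"median"|"count") "(" GROUP ")"
#            | "plate" "(" NAME ")"
#            | "(" expr ")"
# Identifiers are case-sensitive; whitespace is insignificant. A bare
# identifier of the form letter(s)+digits (e.g. A1) is a well reference;
# groups are marker names and appear only as aggregate arguments.

AGG_FNS <- c("avg", "sd", "cv", "min", "max", "median", "count")

tokenize_formula <- function(text) {
  tokens <- list()
  i <- 1L
  n <- nchar(text)
  push <- function(type, value, pos) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^[ \t\r\n]$", ch)) { i <- i + 1L; next }
    if (ch %in% c("+", "-", "*", "/", "(", ")")) {
      push(ch, ch, i); i <- i + 1L; next
    }
    rest <- substr(text, i, n)
    m <- regmatches(rest, regexpr("^[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?|^\\.[0-9]+([eE][+-]?[0-9]+)?", rest))
    if (length(m) == 1L && nzchar(m)) {
      push("number", as.numeric(m), i); i <- i + nchar(m); next
    }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_%]*", rest))
    if (length(m) == 1L && nzchar(m)) {
      push("ident", m, i); i <- i + nchar(m); next
    }
    stop_parse(sprintf("unexpected character '%s' at position %d", ch, i), position = i)
  }
  push("end", "", n + 1L)
  tokens
}

#' Parse a calculation formula
#'
#' Parses the Excel-like formula language used by well functions and plate
#' functions. The language offers numbers, the four arithmetic operators,
#' unary minus, parentheses, the `value` token (the current well's raw
#' value), A1-style well references, group aggregates
#' `avg/sd/cv/min/max/median/count(GROUP)` over a marker's non-outlier
#' wells, and `plate(NAME)` references to named plate functions.
#'
#' @param text formula source text.
#' @return an object of class `pw_formula` with elements `source` and `ast`.
#' @examples
#' parse_formula("(value - avg(BLANK)) / (avg(CTRL) - avg(BLANK)) * 100")
#' @export
parse_formula <- function(text) {
  assert_scalar_chr(text, "formula text")
  tokens <- tokenize_formula(text)
  pos <- 1L
  peek <- function() tokens[[pos]]
  advance <- function() { t <- tokens[[pos]]; pos <<- pos + 1L; t }
  expect <- function(type, what) {
    t <- peek()
    if (t$type != type)
      stop_parse(sprintf("expected %s at position %d", what, t$pos), position = t$pos)
    advance()
  }

  parse_expr <- function() {
    node <- parse_term()
    while (peek()$type %in% c("+", "-")) {
      op <- advance()$type
      node <- list(type = "binop", op = op, lhs = node, rhs = parse_term())
    }
    node
  }
  parse_term <- function() {
    node <- parse_factor()
    while (peek()$type %in% c("*", "/")) {
      op <- advance()$type
      node <- list(type = "binop", op = op, lhs = node, rhs = parse_factor())
    }
    node
  }
  parse_factor <- function() {
    if (peek()$type == "-") { advance(); return(list(type = "neg", arg = parse_factor())) }
    parse_primary()
  }
  parse_primary <- function() {
    t <- peek()
    if (t$type == "number") { advance(); return(list(type = "num", value = t$value)) }
    if (t$type == "(") {
      advance()
      node <- parse_expr()
      expect(")", "')'")
      return(node)
    }
    if (t$type == "ident") {
      advance()
      if (identical(t$value, "value")) return(list(type = "value"))
      if (peek()$type == "(") {
        if (!(t$value %in% c(AGG_FNS, "plate")))
          stop_parse(sprintf("unknown function '%s' at position %d", t$value, t$pos),
                     position = t$pos)
        advance()
        arg <- peek()
        if (arg$type != "ident")
          stop_parse(sprintf("expected a name at position %d", arg$pos), position = arg$pos)
        advance()
        expect(")", "')'")
        if (t$value == "plate") return(list(type = "plate_fn", name = arg$value))
        return(list(type = "agg", fn = t$value, group = arg$value))
      }
      if (grepl("^[A-Z]+[0-9]+$", t$value)) return(list(type = "wellref", label = t$value))
      stop_parse(sprintf("unknown name '%s' at position %d (not a well reference; groups appear only inside aggregates)",
                         t$value, t$pos), position = t$pos)
    }
    stop_parse(sprintf("unexpected %s at position %d",
                       if (t$type == "end") "end of formula" else sprintf("'%s'", t$type), t$pos),
               position = t$pos)
  }

  ast <- parse_expr()
  t <- peek()
  if (t$type != "end")
    stop_parse(sprintf("unexpected '%s' at position %d", t$value, t$pos), position = t$pos)
  structure(list(source = text, ast = ast), class = "pw_formula")
}

#' @export
print.pw_formula <- function(x, ...) {
  cat("<formula>", x$source, "\n")
  invisible(x)
}

#' Render a formula AST back to source text
#'
#' The result re-parses to a structurally identical tree (round-trip
#' property of the language).
#'
#' @param formula a [parse_formula()] result.
#' @return a single string.
#' @export
deparse_formula <- function(formula) {
  stopifnot(inherits(formula, "pw_formula"))
  deparse_node(formula$ast)
}

deparse_node <- function(node) {
  switch(node$type,
    num = format(node$value, digits = 15),
    value = "value",
    wellref = node$label,
    agg = sprintf("%s(%s)", node$fn, node$group),
    plate_fn = sprintf("plate(%s)", node$name),
    neg = sprintf("-(%s)", deparse_node(node$arg)),
    binop = sprintf("(%s %s %s)", deparse_node(node$lhs), node$op, deparse_node(node$rhs)),
    stop_validation(sprintf("unknown AST node type '%s'", node$type))
  )
}

# Walk an AST collecting a property of its nodes.
walk_ast <- function(node, visit) {
  visit(node)
  if (node$type == "binop") { walk_ast(node$lhs, visit); walk_ast(node$rhs, visit) }
  if (node$type == "neg") walk_ast(node$arg, visit)
  invisible(NULL)
}

formula_uses_value <- function(formula) {
  found <- FALSE
  walk_ast(formula$ast, function(n) if (n$type == "value") found <<- TRUE)
  found
}

formula_groups <- function(formula) {
  groups <- character(0)
  walk_ast(formula$ast, function(n) if (n$type == "agg") groups <<- c(groups, n$group))
  unique(groups)
}

# ---- evaluation ------------------------------------------------------------

# Values of a marker group on a plate: non-outlier wells holding raw data.
group_values <- function(plate, group) {
  m <- find_marker(layout_of(plate), group)
  if (is.null(m))
    stop_reference(sprintf("group '%s' is not a marker on this plate's layout", group))
  w <- plate$wells
  keep <- w$label %in% m$positions & !w$outlier & !is.na(w$raw_value)
  w$raw_value[keep]
}

agg_value <- function(fn, values) {
  n <- length(values)
  switch(fn,
    count = as.numeric(n),
    avg = if (n >= 1L) mean(values) else NA_real_,
    sd = if (n >= 2L) stats::sd(values) else NA_real_,
    cv = {
      if (n < 2L) return(NA_real_)
      m <- mean(values)
      if (m == 0) NA_real_ else 100 * stats::sd(values) / m
    },
    min = if (n >= 1L) min(values) else NA_real_,
    max = if (n >= 1L) max(values) else NA_real_,
    median = if (n >= 1L) stats::median(values) else NA_real_,
    stop_validation(sprintf("unknown aggregate '%s'", fn))
  )
}

eval_node <- function(node, plate, well, stack) {
  switch(node$type,
    num = node$value,
    value = {
      if (is.null(well))
        stop_validation("'value' is only available in a well context (not in plate functions)")
      idx <- match(well, plate$wells$label)
      plate$wells$raw_value[idx]
    },
    wellref = {
      idx <- match(node$label, plate$wells$label)
      if (is.na(idx))
        stop_reference(sprintf("well reference '%s' is outside the plate", node$label))
      plate$wells$raw_value[idx]
    },
    agg = agg_value(node$fn, group_values(plate, node$group)),
    plate_fn = {
      pf <- layout_of(plate)$plate_functions[[node$name]]
      if (is.null(pf))
        stop_reference(sprintf("unknown plate function '%s'", node$name))
      if (node$name %in% stack)
        stop_reference(sprintf("plate function cycle: %s",
                               paste(c(stack, node$name), collapse = " -> ")))
      eval_node(pf$formula$ast, plate, NULL, c(stack, node$name))
    },
    neg = {
      v <- eval_node(node$arg, plate, well, stack)
      if (is.na(v)) NA_real_ else -v
    },
    binop = {
      l <- eval_node(node$lhs, plate, well, stack)
      r <- eval_node(node$rhs, plate, well, stack)
      if (is.na(l) || is.na(r)) return(NA_real_)
      switch(node$op,
        "+" = l + r, "-" = l - r, "*" = l * r,
        "/" = if (r == 0) NA_real_ else l / r)  # division by zero -> missing
    },
    stop_validation(sprintf("unknown AST node type '%s'", node$type))
  )
}

#' Evaluate a formula for one well
#'
#' The `value` token resolves to the well's raw measurement; aggregates are
#' computed over each group's non-outlier wells that hold data. Missing data
#' and division by zero propagate as `NA` (curation must not crash reports);
#' structural problems — an unknown group or plate function — raise errors.
#'
#' @param plate a plate with imported data.
#' @param formula a [parse_formula()] result (or formula text).
#' @param well well label, e.g. `"C4"`.
#' @return a number, or `NA` when an operand is missing.
#' @export
eval_well_function <- function(plate, formula, well) {
  stopifnot(inherits(plate, "pw_plate"))
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "pw_formula"))
  assert_scalar_chr(well, "well label")
  if (is.na(match(well, plate$wells$label)))
    stop_validation(sprintf("well '%s' is outside the plate", well))
  eval_node(formula$ast, plate, well, character(0))
}

#' Evaluate a plate-level formula
#'
#' Like [eval_well_function()] but produces a single scalar per plate; the
#' formula may not contain the `value` token.
#'
#' @inheritParams eval_well_function
#' @return a number or `NA`.
#' @export
eval_plate_function <- function(plate, formula) {
  stopifnot(inherits(plate, "pw_plate"))
  if (is.character(formula)) formula <- parse_formula(formula)
  stopifnot(inherits(formula, "pw_formula"))
  if (formula_uses_value(formula))
    stop_validation("a plate function may not reference the current well's value")
  eval_node(formula$ast, plate, NULL, character(0))
}
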