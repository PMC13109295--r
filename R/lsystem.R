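# Bracketed parametric stochastic L-systems: grammar dialect parser,
# restricted expression language, parallel derivation, and hierarchical
# embedding of organ (leaf/branch) sub-grammar strings.

## ---- expression language ---------------------------------------------------

# Arithmetic/boolean expressions over a rule's formal parameters. Parsed with
# R's parser, then the AST is whitelisted: only the operators below, sin/cos/
# pow, numeric literals, and declared formal parameters may appear. Evaluation
# happens in a sealed environment so rule files cannot reach package or user
# code.
.lsys_allowed_calls <- c("+", "-", "*", "/", "^", "(",
                         "<", ">", "<=", ">=", "==", "!=",
                         "&", "|", "!", "&&", "||",
                         "sin", "cos", "pow")

.check_lsys_expr <- function(ex, params, where) {
  if (is.numeric(ex) || is.logical(ex)) return(invisible(NULL))
  if (is.name(ex)) {
    nm <- as.character(ex)
    if (!nm %in% params) {
      stop(sprintf("%s: '%s' is not a declared formal parameter", where, nm),
           call. = FALSE)
    }
    return(invisible(NULL))
  }
  if (is.call(ex)) {
    fn <- ex[[1]]
    if (!is.name(fn) || !as.character(fn) %in% .lsys_allowed_calls) {
      stop(sprintf("%s: call to '%s' is not allowed in rule expressions",
                   where, deparse(fn)), call. = FALSE)
    }
    for (i in seq_along(ex)[-1]) .check_lsys_expr(ex[[i]], params, where)
    return(invisible(NULL))
  }
  stop(sprintf("%s: unsupported expression element '%s'", where, deparse(ex)),
       call. = FALSE)
}

parse_lsys_expr <- function(text, params, where) {
  ex <- tryCatch(
    parse(text = text, keep.source = FALSE),
    error = function(e) stop(sprintf("%s: cannot parse expression '%s'",
                                     where, text), call. = FALSE)
  )
  if (length(ex) != 1L) {
    stop(sprintf("%s: expected a single expression, got '%s'", where, text),
         call. = FALSE)
  }
  ex <- ex[[1]]
  .check_lsys_expr(ex, params, where)
  ex
}

.lsys_eval_env <- function(params = list()) {
  e <- new.env(parent = emptyenv())
  for (op in c("+", "-", "*", "/", "^", "(", "<", ">", "<=", ">=",
               "==", "!=", "&", "|", "!", "&&", "||")) {
    assign(op, get(op, baseenv()), envir = e)
  }
  e$sin <- function(x) base::sin(x * pi / 180)
  e$cos <- function(x) base::cos(x * pi / 180)
  e$pow <- function(a, b) a^b
  if (length(params)) list2env(params, e)
  e
}

eval_lsys_expr <- function(ex, env) {
  v <- eval(ex, env)
  if (!is.numeric(v) && !is.logical(v)) {
    stop("expression did not evaluate to a number", call. = FALSE)
  }
  v
}

## ---- tokenizer -------------------------------------------------------------

.lsys_single_chars <- c("+", "-", "&", "^", "\\", "/", "|",
                        "[", "]", "{", "}", ".", "!", "'")

# Split a top-level comma-separated argument list (no nested function calls
# beyond parentheses are possible in the dialect).
.split_args <- function(text) {
  depth <- 0L
  out <- character()
  cur <- ""
  for (ch in strsplit(text, "", fixed = TRUE)[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      out <- c(out, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  c(out, cur)
}

# Tokenize a symbol sequence into a list of list(name, args = character()).
# `args` are raw expression strings; callers decide whether they must be
# constants (axiom) or parameter expressions (rule successors).
tokenize_symbols <- function(text, where = "string") {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  out <- list()
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    name <- NULL
    if (ch == "%" && i < n && chars[i + 1L] %in% c("{", "}")) {
      name <- paste0("%", chars[i + 1L])
      i <- i + 2L
    } else if (ch %in% .lsys_single_chars) {
      name <- ch
      i <- i + 1L
    } else if (grepl("[A-Za-z_]", ch)) {
      j <- i
      while (j < n && grepl("[A-Za-z0-9_]", chars[j + 1L])) j <- j + 1L
      name <- paste(chars[i:j], collapse = "")
      i <- j + 1L
    } else {
      stop(sprintf("%s: unexpected character '%s'", where, ch), call. = FALSE)
    }
    args <- character()
    if (i <= n && chars[i] == "(") {
      depth <- 1L
      j <- i + 1L
      while (j <= n && depth > 0L) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth != 0L) {
        stop(sprintf("%s: unbalanced parentheses after '%s'", where, name),
             call. = FALSE)
      }
      inner <- paste(chars[(i + 1L):(j - 2L)], collapse = "")
      if (nzchar(trimws(inner))) args <- trimws(.split_args(inner))
      i <- j
    }
    out[[length(out) + 1L]] <- list(name = name, args = args)
  }
  out
}

## ---- grammar parsing -------------------------------------------------------

.new_symbol <- function(name, params = numeric()) {
  list(name = name, params = as.numeric(params))
}

# Evaluate axiom tokens to constant-parameter symbols.
.tokens_to_axiom <- function(tokens, where) {
  env <- .lsys_eval_env()
  lapply(tokens, function(tk) {
    params <- vapply(tk$args, function(a) {
      ex <- parse_lsys_expr(a, character(), where)
      as.numeric(eval_lsys_expr(ex, env))
    }, numeric(1))
    if (any(!is.finite(params))) {
      stop(sprintf("%s: non-finite parameter on '%s'", where, tk$name),
           call. = FALSE)
    }
    .new_symbol(tk$name, params)
  })
}

.parse_rule <- function(line, lineno) {
  where <- sprintf("line %d", lineno)
  parts <- regmatches(line, regexpr("->", line), invert = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop(sprintf("%s: rule must contain exactly one '->'", where),
         call. = FALSE)
  }
  lhs <- trimws(parts[1])
  rhs <- trimws(parts[2])

  condition_text <- NULL
  if (grepl(":", lhs, fixed = TRUE)) {
    lp <- strsplit(lhs, ":", fixed = TRUE)[[1]]
    lhs <- trimws(lp[1])
    condition_text <- trimws(paste(lp[-1], collapse = ":"))
  }
  m <- regexec("^([A-Za-z_][A-Za-z0-9_]*)(\\(([^)]*)\\))?$", lhs)[[1]]
  if (m[1] == -1) {
    stop(sprintf("%s: malformed rule predecessor '%s'", where, lhs),
         call. = FALSE)
  }
  name <- regmatches(lhs, regexec("^([A-Za-z_][A-Za-z0-9_]*)", lhs))[[1]][2]
  formal <- character()
  pm <- regmatches(lhs, regexec("\\(([^)]*)\\)", lhs))[[1]]
  if (length(pm) == 2 && nzchar(trimws(pm[2]))) {
    formal <- trimws(strsplit(pm[2], ",", fixed = TRUE)[[1]])
    if (any(!grepl("^[A-Za-z_][A-Za-z0-9_]*$", formal))) {
      stop(sprintf("%s: invalid formal parameter name in '%s'", where, lhs),
           call. = FALSE)
    }
  }
  condition <- if (!is.null(condition_text) && nzchar(condition_text)) {
    parse_lsys_expr(condition_text, formal, where)
  } else NULL

  alts <- strsplit(rhs, "|", fixed = TRUE)[[1]]
  if (!length(alts)) alts <- ""  # empty successor: the symbol is erased
  successors <- lapply(alts, function(alt) {
    alt <- trimws(alt)
    weight <- 1
    wm <- regexec("^\\(\\s*([0-9.eE+-]+)\\s*\\)", alt)[[1]]
    if (wm[1] == 1) {
      weight <- as.numeric(regmatches(alt, regexec(
        "^\\(\\s*([0-9.eE+-]+)\\s*\\)", alt))[[1]][2])
      alt <- trimws(substring(alt, attr(wm, "match.length")[1] + 1L))
    }
    if (is.na(weight) || weight < 0) {
      stop(sprintf("%s: successor weight must be a non-negative number",
                   where), call. = FALSE)
    }
    tokens <- tokenize_symbols(alt, where)
    template <- lapply(tokens, function(tk) {
      list(name = tk$name,
           args = lapply(tk$args, parse_lsys_expr, params = formal,
                         where = where))
    })
    list(weight = weight, template = template)
  })
  if (sum(vapply(successors, `[[`, numeric(1), "weight")) <= 0) {
    stop(sprintf("%s: successor weights must sum to a positive value", where),
         call. = FALSE)
  }
  list(name = name, params = formal, condition = condition,
       successors = successors)
}

#' Parse an L-system grammar document
#'
#' Reads the plain-text grammar dialect: `angle:` and `step:` directives,
#' an `axiom:` line, optional `terminals:` declarations, one production rule
#' per line of the form `pred(p1,p2) [: condition] -> (w) succ | (w) succ`,
#' and sub-grammar bindings `sub L = file.lsys @ n class=leaf`. Lines
#' starting with `#` are comments. Nonterminals are the rule predecessors;
#' all other symbols are terminals. When a `terminals:` line is present,
#' any identifier symbol not declared anywhere raises an undeclared-symbol
#' error.
#'
#' @param text grammar document as a single string or character vector of
#'   lines.
#' @param dir directory against which `sub` file references are resolved.
#' @return an object of class `lsys_grammar` with components `axiom`,
#'   `rules`, `nonterminals`, `terminals`, `angle` (degrees), `step`
#'   (length units), and `subgrammars` (placeholder name -> list of
#'   `grammar`, `iterations`, `organ_class`).
#' @seealso [read_grammar()], [derive()], [expand_hierarchical()]
#' @export
#' @examples
#' g <- parse_grammar("axiom: A\nA -> A B\nB -> A")
#' derive(g, 5, seed = 1)
parse_grammar <- function(text, dir = ".") {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  source_text <- paste(lines, collapse = "\n")
  lines <- sub("#.*$", "", lines)

  axiom <- NULL
  angle <- 90
  step <- 1
  declared_terminals <- NULL
  rules <- list()
  subgrammars <- list()

  for (k in seq_along(lines)) {
    line <- trimws(lines[k])
    if (!nzchar(line)) next
    if (grepl("^angle\\s*:", line)) {
      angle <- as.numeric(trimws(sub("^angle\\s*:", "", line)))
      if (is.na(angle)) stop(sprintf("line %d: bad angle", k), call. = FALSE)
    } else if (grepl("^step\\s*:", line)) {
      step <- as.numeric(trimws(sub("^step\\s*:", "", line)))
      if (is.na(step) || step <= 0) {
        stop(sprintf("line %d: step must be a positive number", k),
             call. = FALSE)
      }
    } else if (grepl("^axiom\\s*:", line)) {
      ax_text <- trimws(sub("^axiom\\s*:", "", line))
      axiom <- .tokens_to_axiom(
        tokenize_symbols(ax_text, sprintf("line %d", k)),
        sprintf("line %d", k))
    } else if (grepl("^terminals\\s*:", line)) {
      declared_terminals <- trimws(strsplit(
        trimws(sub("^terminals\\s*:", "", line)), "[ ,]+")[[1]])
      declared_terminals <- declared_terminals[nzchar(declared_terminals)]
    } else if (grepl("^sub\\s+", line)) {
      m <- regexec(paste0("^sub\\s+([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(\\S+)",
                          "\\s*@\\s*([0-9]+)\\s*(?:iterations?\\s*)?",
                          "class\\s*=\\s*(leaf|branch)\\s*$"), line)[[1]]
      if (m[1] == -1) {
        stop(sprintf("line %d: malformed sub binding", k), call. = FALSE)
      }
      g <- regmatches(line, list(m))[[1]]
      placeholder <- g[2]
      if (placeholder %in% names(subgrammars)) {
        stop(sprintf("line %d: duplicate placeholder '%s'", k, placeholder),
             call. = FALSE)
      }
      sub_path <- file.path(dir, g[3])
      if (!file.exists(sub_path)) {
        stop(sprintf("line %d: sub-grammar file '%s' not found", k, g[3]),
             call. = FALSE)
      }
      subgrammars[[placeholder]] <- list(
        grammar = read_grammar(sub_path),
        iterations = as.integer(g[4]),
        organ_class = g[5])
    } else if (grepl("->", line, fixed = TRUE)) {
      rules[[length(rules) + 1L]] <- .parse_rule(line, k)
    } else {
      stop(sprintf("line %d: cannot parse '%s'", k, line), call. = FALSE)
    }
  }

  if (is.null(axiom)) stop("grammar has no axiom", call. = FALSE)

  nonterminals <- unique(vapply(rules, `[[`, character(1), "name"))
  placeholders <- names(subgrammars)
  if (length(intersect(nonterminals, placeholders))) {
    stop(sprintf("placeholder '%s' also appears as a rule predecessor",
                 intersect(nonterminals, placeholders)[1]), call. = FALSE)
  }

  all_names <- unique(c(
    vapply(axiom, `[[`, character(1), "name"),
    unlist(lapply(rules, function(r) {
      unlist(lapply(r$successors, function(s) {
        vapply(s$template, `[[`, character(1), "name")
      }))
    }))))
  identifier_names <- setdiff(
    all_names[grepl("^[A-Za-z_]", all_names)],
    c(nonterminals, placeholders))
  if (!is.null(declared_terminals)) {
    undeclared <- setdiff(identifier_names, declared_terminals)
    if (length(undeclared)) {
      stop(sprintf("undeclared symbol '%s'", undeclared[1]), call. = FALSE)
    }
    terminals <- declared_terminals
  } else {
    terminals <- identifier_names
  }
  if (length(intersect(terminals, nonterminals))) {
    stop("a symbol cannot be both terminal and nonterminal", call. = FALSE)
  }
  if (length(intersect(terminals, placeholders))) {
    stop("a placeholder name cannot also be a terminal", call. = FALSE)
  }

  structure(
    list(axiom = axiom, rules = rules, nonterminals = nonterminals,
         terminals = terminals, angle = angle, step = step,
         subgrammars = subgrammars, source = source_text),
    class = "lsys_grammar")
}

#' Read an L-system grammar from a file
#'
#' @param path path to a grammar document; `sub` bindings inside it are
#'   resolved relative to the file's directory.
#' @return an `lsys_grammar` object; see [parse_grammar()].
#' @export
read_grammar <- function(path) {
  if (!file.exists(path)) stop(sprintf("grammar file '%s' not found", path),
                               call. = FALSE)
  parse_grammar(readLines(path, warn = FALSE), dir = dirname(path))
}

#' @export
print.lsys_grammar <- function(x, ...) {
  cat("L-system grammar\n")
  cat("  axiom:       ", format_symbols(x$axiom), "\n", sep = "")
  cat("  nonterminals:", paste(x$nonterminals, collapse = " "), "\n")
  cat("  terminals:   ", paste(x$terminals, collapse = " "), "\n")
  cat("  rules:       ", length(x$rules), "\n")
  cat("  angle/step:  ", x$angle, "deg /", x$step, "\n")
  if (length(x$subgrammars)) {
    for (nm in names(x$subgrammars)) {
      sg <- x$subgrammars[[nm]]
      cat(sprintf("  sub %s: %s organ, %d iterations\n",
                  nm, sg$organ_class, sg$iterations))
    }
  }
  invisible(x)
}

## ---- symbol strings --------------------------------------------------------

new_symbol_string <- function(symbols, organ_spans = NULL, angle = 90,
                              step = 1) {
  if (is.null(organ_spans)) {
    organ_spans <- data.frame(instance_id = integer(),
                              organ_class = character(),
                              start = integer(), end = integer())
  }
  structure(list(symbols = symbols, organ_spans = organ_spans),
            angle = angle, step = step, class = "symbol_string")
}

format_symbols <- function(symbols) {
  paste(vapply(symbols, function(s) {
    if (length(s$params)) {
      paste0(s$name, "(", paste(format(s$params, trim = TRUE,
                                       digits = 10), collapse = ","), ")")
    } else s$name
  }, character(1)), collapse = "")
}

#' @export
as.character.symbol_string <- function(x, ...) format_symbols(x$symbols)

#' @export
print.symbol_string <- function(x, ...) {
  s <- as.character(x)
  if (nchar(s) > 200) s <- paste0(substr(s, 1, 200), "...")
  cat("symbol string (", length(x$symbols), " symbols, ",
      nrow(x$organ_spans), " organ spans)\n", s, "\n", sep = "")
  invisible(x)
}

#' @export
length.symbol_string <- function(x) length(x$symbols)

#' Build a symbol string from literal text
#'
#' Tokenizes a turtle command sequence with constant numeric parameters,
#' e.g. `"F[+F(0.5)][-F]"`, into a `symbol_string` ready for
#' [interpret()]. No rewriting is involved.
#'
#' @param text command text.
#' @param angle,step defaults attached for interpretation.
#' @return a `symbol_string`.
#' @export
lsys_string <- function(text, angle = 90, step = 1) {
  tokens <- tokenize_symbols(text, "string")
  new_symbol_string(.tokens_to_axiom(tokens, "string"),
                    angle = angle, step = step)
}

## ---- derivation ------------------------------------------------------------

# First rule whose name, arity and condition match wins; a name match with
# the wrong arity is a hard error.
.match_rule <- function(grammar, sym) {
  for (r in grammar$rules) {
    if (r$name != sym$name) next
    if (length(r$params) != length(sym$params)) {
      stop(sprintf(
        "parameter-arity mismatch: symbol '%s' carries %d parameter(s), rule expects %d",
        sym$name, length(sym$params), length(r$params)), call. = FALSE)
    }
    if (!is.null(r$condition)) {
      env <- .lsys_eval_env(stats::setNames(as.list(sym$params), r$params))
      if (!isTRUE(as.logical(eval_lsys_expr(r$condition, env)))) next
    }
    return(r)
  }
  NULL
}

#' Derive an L-system string
#'
#' Applies the grammar's production rules in parallel for `n` iterations
#' starting from the axiom. Symbols with no matching rule (terminals,
#' placeholders) are copied unchanged. When a rule has several weighted
#' successors, the choice at string position `p` of iteration `i` is made
#' from a counter-based deviate keyed on `(seed, i, p)`, so derivation is
#' fully deterministic given `(grammar, n, seed)` and individual draws do
#' not shift when unrelated rules change.
#'
#' @param grammar an `lsys_grammar`.
#' @param n number of rewriting iterations (>= 0); `n = 0` returns the axiom.
#' @param seed integer seed for stochastic successor choice.
#' @return a `symbol_string` (no organ spans; see [expand_hierarchical()]).
#' @export
#' @examples
#' algae <- parse_grammar("axiom: A\nA -> A B\nB -> A")
#' as.character(derive(algae, 5, seed = 1))  # "ABAABABA"
derive <- function(grammar, n, seed = 0L) {
  stopifnot(inherits(grammar, "lsys_grammar"), n >= 0)
  s <- grammar$axiom
  if (n > 0) {
    for (iter in seq_len(n)) {
      out <- vector("list", length(s))
      for (pos in seq_along(s)) {
        sym <- s[[pos]]
        r <- .match_rule(grammar, sym)
        if (is.null(r)) {
          out[[pos]] <- list(sym)
          next
        }
        weights <- vapply(r$successors, `[[`, numeric(1), "weight")
        idx <- if (length(weights) == 1L) 1L else {
          choose_weighted(weights, counter_uniform(seed, iter, pos))
        }
        env <- .lsys_eval_env(stats::setNames(as.list(sym$params), r$params))
        out[[pos]] <- lapply(r$successors[[idx]]$template, function(tmpl) {
          params <- vapply(tmpl$args, function(ex) {
            as.numeric(eval_lsys_expr(ex, env))
          }, numeric(1))
          if (any(!is.finite(params))) {
            stop(sprintf("non-finite parameter produced for '%s'", tmpl$name),
                 call. = FALSE)
          }
          .new_symbol(tmpl$name, params)
        })
      }
      s <- unlist(out, recursive = FALSE)
      if (is.null(s)) s <- list()
    }
  }
  new_symbol_string(s, angle = grammar$angle, step = grammar$step)
}

#' Derive a plant string with embedded organ sub-grammar strings
#'
#' First derives the plant-level string, then replaces each sub-grammar
#' placeholder occurrence (left to right) with the derived string of its
#' bound organ grammar, wrapped in organ-span markers `%{` / `%}` that
#' carry a fresh instance id and the placeholder's organ class. The stem
#' and branch skeleton outside any span belongs to background instance 0.
#' Each occurrence derives its sub-grammar with a child seed split
#' deterministically from `(seed, occurrence index)`.
#'
#' @inheritParams derive
#' @param plant a plant-level `lsys_grammar` whose `sub` bindings name the
#'   organ grammars.
#' @param n_plant rewriting iterations for the plant grammar.
#' @return a `symbol_string` whose `organ_spans` data frame lists one row
#'   per embedded organ instance (ids contiguous from 1 in occurrence
#'   order); span indices cover the markers and the embedded symbols.
#' @export
expand_hierarchical <- function(plant, n_plant, seed = 0L) {
  stopifnot(inherits(plant, "lsys_grammar"))
  sp <- derive(plant, n_plant, seed)
  placeholders <- names(plant$subgrammars)

  symbols <- list()
  spans <- list()
  k <- 0L
  class_code <- c(leaf = 1, branch = 2)
  for (sym in sp$symbols) {
    if (sym$name %in% placeholders) {
      sg <- plant$subgrammars[[sym$name]]
      if (is.null(sg)) {
        stop(sprintf("placeholder '%s' has no bound sub-grammar", sym$name),
             call. = FALSE)
      }
      k <- k + 1L
      seed_k <- split_seed(seed, k, stream = 1L)
      sub_s <- derive(sg$grammar, sg$iterations, seed_k)
      start <- length(symbols) + 1L
      symbols[[length(symbols) + 1L]] <-
        .new_symbol("%{", c(k, class_code[[sg$organ_class]]))
      symbols <- c(symbols, sub_s$symbols)
      symbols[[length(symbols) + 1L]] <- .new_symbol("%}")
      spans[[k]] <- data.frame(instance_id = k,
                               organ_class = sg$organ_class,
                               start = start,
                               end = length(symbols) + 1L)
    } else {
      symbols[[length(symbols) + 1L]] <- sym
    }
  }
  organ_spans <- if (length(spans)) do.call(rbind, spans) else NULL
  new_symbol_string(symbols, organ_spans,
                    angle = plant$angle, step = plant$step)
}
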