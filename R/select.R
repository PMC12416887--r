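# Atom selection mini-language: keyword terms ("resid 205-225", "name CA CB",
# "chain A", "element C"), combined with "and"/"or" and parentheses.
# Selections resolve to strictly increasing atom indices; an empty result is
# legal at selection time (use sites decide whether to error).

tokenize_selection <- function(expression) {
  pat <- "\\(|\\)|[^()\\s]+"
  m <- gregexpr(pat, expression, perl = TRUE)[[1]]
  if (m[1] == -1) abort("empty selection expression")
  tok <- regmatches(expression, gregexpr(pat, expression, perl = TRUE))[[1]]
  tibble(token = tok, pos = as.integer(m))
}

sel_keywords <- c("resid", "name", "chain", "element")

parse_values <- function(state) {
  vals <- character(0)
  pos <- integer(0)
  while (state$i <= nrow(state$tokens)) {
    tk <- state$tokens$token[state$i]
    if (tk %in% c("and", "or", ")", "(") || tk %in% sel_keywords) break
    vals <- c(vals, tk)
    pos <- c(pos, state$tokens$pos[state$i])
    state$i <- state$i + 1
  }
  list(values = vals, pos = pos)
}

eval_term <- function(state, atoms) {
  if (state$i > nrow(state$tokens)) {
    abort("selection ended where a term was expected")
  }
  tk <- state$tokens$token[state$i]
  pos <- state$tokens$pos[state$i]
  if (tk == "(") {
    state$i <- state$i + 1
    res <- eval_or(state, atoms)
    if (state$i > nrow(state$tokens) ||
        state$tokens$token[state$i] != ")") {
      abort(paste0("unbalanced parenthesis opened at position ", pos))
    }
    state$i <- state$i + 1
    return(res)
  }
  if (!tk %in% sel_keywords) {
    abort(paste0("syntax error at position ", pos, ": unexpected token '",
                 tk, "'"))
  }
  state$i <- state$i + 1
  pv <- parse_values(state)
  vals <- pv$values
  if (!length(vals)) {
    abort(paste0("keyword '", tk, "' at position ", pos, " has no values"))
  }
  if (tk == "resid") {
    ids <- integer(0)
    for (vi in seq_along(vals)) {
      for (piece in strsplit(vals[vi], ",", fixed = TRUE)[[1]]) {
        if (grepl("^[0-9]+-[0-9]+$", piece)) {
          nums <- as.integer(strsplit(piece, "-", fixed = TRUE)[[1]])
          ids <- c(ids, seq(nums[1], nums[2]))
        } else if (grepl("^-?[0-9]+$", piece)) {
          ids <- c(ids, as.integer(piece))
        } else {
          abort(paste0("syntax error at position ", pv$pos[vi],
                       ": bad resid value '", piece, "'"))
        }
      }
    }
    return(atoms$resid %in% ids)
  }
  vals <- unlist(strsplit(vals, ",", fixed = TRUE))
  switch(tk,
    name = atoms$name %in% vals,
    chain = atoms$chain %in% vals,
    element = toupper(atoms$element) %in% toupper(vals)
  )
}

eval_and <- function(state, atoms) {
  res <- eval_term(state, atoms)
  while (state$i <= nrow(state$tokens) &&
         state$tokens$token[state$i] == "and") {
    state$i <- state$i + 1
    res <- res & eval_term(state, atoms)
  }
  res
}

eval_or <- function(state, atoms) {
  res <- eval_and(state, atoms)
  while (state$i <= nrow(state$tokens) &&
         state$tokens$token[state$i] == "or") {
    state$i <- state$i + 1
    res <- res | eval_and(state, atoms)
  }
  res
}

#' Select atoms from a topology
#'
#' Evaluates a selection expression over the atom table. Supported terms:
#' `resid` with single numbers or ranges (`resid 205-225`), `name`, `chain`
#' and `element` with one or more values, combined with `and`, `or` and
#' parentheses. Resolution is deterministic and order-preserving (indices
#' strictly increasing). An empty result is allowed here; operations that
#' need atoms raise their own errors.
#'
#' @param topology A [new_topology()].
#' @param expression Selection string.
#' @return Object of class `selection` with fields `expression` and
#'   `indices`.
#' @export
select_atoms <- function(topology, expression) {
  state <- new.env()
  state$tokens <- tokenize_selection(expression)
  state$i <- 1L
  mask <- eval_or(state, topology$atoms)
  if (state$i <= nrow(state$tokens)) {
    abort(paste0("syntax error at position ", state$tokens$pos[state$i],
                 ": unexpected token '", state$tokens$token[state$i], "'"))
  }
  structure(list(expression = expression, indices = which(mask)),
            class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("<selection> '", x$expression, "': ", length(x$indices),
      " atom(s)\n", sep = "")
  invisible(x)
}

# resolve a selection-or-indices argument to integer indices
resolve_indices <- function(topology, sel, what = "selection",
                            allow_empty = FALSE) {
  idx <- if (inherits(sel, "selection")) {
    sel$indices
  } else if (is.character(sel)) {
    select_atoms(topology, sel)$indices
  } else {
    as.integer(sel)
  }
  if (!allow_empty && !length(idx)) {
    abort(paste0("empty ", what))
  }
  idx
}
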