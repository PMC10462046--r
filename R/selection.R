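#' Select particles by a small selection language
#'
#' Supported grammar, modelled on common MD selection syntax but
#' deliberately small:
#' \preformatted{
#'   expr      := term ("or" term)*
#'   term      := factor ("and" factor)*
#'   factor    := "not" factor | "(" expr ")" | primitive
#'   primitive := "name" value+ | "resname" value+ | "resid" (id | lo-hi)+
#' }
#' `resid` accepts single ids and inclusive ranges like `74-100` (1-based, as
#' printed in GRO/PDB files). Matching any zero particles is not an error.
#'
#' @param topology an sk_topology
#' @param expression selection text, e.g. `"resname POPC and name PO4"`
#' @param label optional label stored on the selection (defaults to the
#'   expression text)
#' @return an object of class "sk_selection": list(label, indices) with
#'   sorted unique 1-based particle indices
#' @examples
#' top <- system_topology(c("PO4", "C1", "PO4", "BB"),
#'                        c("POPC", "POPC", "POPC", "PROT"),
#'                        c(1, 1, 2, 3))
#' select(top, "resname POPC and name PO4")
#' @export
select <- function(topology, expression, label = expression) {
  stopifnot(inherits(topology, "sk_topology"))
  tokens <- sel_tokenize(expression)
  st <- list(tokens = tokens, pos = 1L, expr = expression)
  res <- sel_parse_expr(st, topology)
  if (res$state$pos <= length(tokens)) {
    sel_error(res$state, "unexpected token")
  }
  structure(list(label = label, indices = which(res$mask)),
            class = "sk_selection")
}

#' @export
print.sk_selection <- function(x, ...) {
  cat("<sk_selection> '", x$label, "': ", length(x$indices),
      " particles\n", sep = "")
  invisible(x)
}

sel_tokenize <- function(expression) {
  s <- gsub("([()])", " \\1 ", expression)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  if (length(toks) == 0L || identical(toks, "")) {
    stop("selection syntax error: empty expression")
  }
  toks
}

sel_error <- function(state, msg) {
  tok <- if (state$pos <= length(state$tokens)) {
    paste0("'", state$tokens[state$pos], "'")
  } else "end of expression"
  stop("selection syntax error at token ", state$pos, " (", tok, "): ", msg)
}

sel_peek <- function(state) {
  if (state$pos > length(state$tokens)) NA_character_ else state$tokens[state$pos]
}

sel_parse_expr <- function(state, top) {
  res <- sel_parse_term(state, top)
  mask <- res$mask; state <- res$state
  while (identical(sel_peek(state), "or")) {
    state$pos <- state$pos + 1L
    res <- sel_parse_term(state, top)
    mask <- mask | res$mask; state <- res$state
  }
  list(mask = mask, state = state)
}

sel_parse_term <- function(state, top) {
  res <- sel_parse_factor(state, top)
  mask <- res$mask; state <- res$state
  while (identical(sel_peek(state), "and")) {
    state$pos <- state$pos + 1L
    res <- sel_parse_factor(state, top)
    mask <- mask & res$mask; state <- res$state
  }
  list(mask = mask, state = state)
}

sel_parse_factor <- function(state, top) {
  tok <- sel_peek(state)
  if (is.na(tok)) sel_error(state, "expected a selection clause")
  if (tok == "not") {
    state$pos <- state$pos + 1L
    res <- sel_parse_factor(state, top)
    return(list(mask = !res$mask, state = res$state))
  }
  if (tok == "(") {
    state$pos <- state$pos + 1L
    res <- sel_parse_expr(state, top)
    state <- res$state
    if (!identical(sel_peek(state), ")")) sel_error(state, "expected ')'")
    state$pos <- state$pos + 1L
    return(list(mask = res$mask, state = state))
  }
  if (!tok %in% c("name", "resname", "resid")) {
    sel_error(state, "expected 'name', 'resname', 'resid', 'not' or '('")
  }
  state$pos <- state$pos + 1L
  values <- character(0)
  while (!is.na(v <- sel_peek(state)) &&
         !v %in% c("and", "or", "not", "(", ")")) {
    values <- c(values, v)
    state$pos <- state$pos + 1L
  }
  if (length(values) == 0L) sel_error(state, paste0("'", tok, "' needs a value"))
  mask <- switch(tok,
    name = top$name %in% values,
    resname = top$resname %in% values,
    resid = top$resid %in% sel_expand_ids(values, state)
  )
  list(mask = mask, state = state)
}

sel_expand_ids <- function(values, state) {
  out <- integer(0)
  for (v in values) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v) || grepl("^[0-9]+-[0-9]+$", v)) {
      parts <- as.integer(strsplit(v, "(?<=[0-9])-", perl = TRUE)[[1]])
      out <- c(out, seq(parts[1], parts[2]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else {
      sel_error(state, paste0("invalid resid value '", v, "'"))
    }
  }
  out
}
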