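#' Select atoms with a small expression language
#'
#' The grammar supports the predicates `name`, `element`, `residue_name`,
#' `residue_seq` (single value or `lo:hi` range), `chain` and `role`
#' (one of `protein`, `lipid`, `glycan_anchor`, `hbond_donor`,
#' `hbond_acceptor`, `hydrogen`), combined with `and`, `or`, `not` and
#' parentheses. `not` binds tightest, then `and`, then `or`.
#'
#' Examples: `"role protein and name CA"`,
#' `"residue_name DOPC or residue_name CHOL"`,
#' `"chain A and not element H"`, `"residue_seq 1:38"`.
#'
#' @param topology a [Topology()]
#' @param expression selection string
#' @return integer vector of 0-based atom indices, ordered by index; may be
#'   empty.
#' @export
select_atoms <- function(topology, expression) {
  toks <- .tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .parse_or(st, topology)
  if (st$pos <= nrow(toks))
    stop("selection syntax error: unexpected token '",
         toks$text[st$pos], "' at position ", toks$at[st$pos])
  which(mask) - 1L
}

.tokenize_selection <- function(expression) {
  if (!is.character(expression) || length(expression) != 1L)
    stop("selection expression must be a single string")
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, expression)[[1]]
  if (m[1] == -1) stop("selection syntax error: empty expression")
  text <- regmatches(expression, gregexpr(pat, expression))[[1]]
  data.frame(text = text, at = as.integer(m), stringsAsFactors = FALSE)
}

.sel_peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$text[st$pos] else NA_character_

.sel_take <- function(st, what) {
  tok <- .sel_peek(st)
  if (is.na(tok))
    stop("selection syntax error: expected ", what, " at end of expression")
  st$pos <- st$pos + 1L
  tok
}

.parse_or <- function(st, topo) {
  mask <- .parse_and(st, topo)
  while (identical(.sel_peek(st), "or")) {
    st$pos <- st$pos + 1L
    mask <- mask | .parse_and(st, topo)
  }
  mask
}

.parse_and <- function(st, topo) {
  mask <- .parse_not(st, topo)
  while (identical(.sel_peek(st), "and")) {
    st$pos <- st$pos + 1L
    mask <- mask & .parse_not(st, topo)
  }
  mask
}

.parse_not <- function(st, topo) {
  if (identical(.sel_peek(st), "not")) {
    st$pos <- st$pos + 1L
    return(!.parse_not(st, topo))
  }
  .parse_primary(st, topo)
}

.parse_primary <- function(st, topo) {
  tok <- .sel_peek(st)
  if (is.na(tok))
    stop("selection syntax error: expected predicate at end of expression")
  if (tok == "(") {
    st$pos <- st$pos + 1L
    mask <- .parse_or(st, topo)
    closing <- .sel_peek(st)
    if (!identical(closing, ")"))
      stop("selection syntax error: expected ')' at position ",
           if (st$pos <= nrow(st$toks)) st$toks$at[st$pos] else nchar(".") )
    st$pos <- st$pos + 1L
    return(mask)
  }
  .parse_predicate(st, topo)
}

.parse_predicate <- function(st, topo) {
  at <- st$toks$at[st$pos]
  key <- .sel_take(st, "predicate keyword")
  a <- topo$atoms
  switch(key,
    name         = a$name == .sel_take(st, "atom name"),
    element      = toupper(a$element) == toupper(.sel_take(st, "element")),
    residue_name = a$residue_name == .sel_take(st, "residue name"),
    chain        = a$chain == .sel_take(st, "chain id"),
    residue_seq  = {
      val <- .sel_take(st, "residue_seq value or range")
      if (grepl("^-?[0-9]+:-?[0-9]+$", val)) {
        lohi <- as.integer(strsplit(val, ":", fixed = TRUE)[[1]])
        a$residue_seq >= lohi[1] & a$residue_seq <= lohi[2]
      } else if (grepl("^-?[0-9]+$", val)) {
        a$residue_seq == as.integer(val)
      } else {
        stop("selection syntax error: bad residue_seq value '", val,
             "' at position ", at)
      }
    },
    role = {
      r <- .sel_take(st, "role name")
      if (!r %in% .atom_roles)
        stop("selection syntax error: unknown role '", r,
             "' at position ", at)
      a[[r]]
    },
    stop("selection syntax error: unknown keyword '", key,
         "' at position ", at)
  )
}
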