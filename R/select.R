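#' Select sites by a small query grammar
#'
#' Expressions combine `field:pattern` atoms with `and`, `or`, `not` and
#' parentheses. Fields are `name`, `domain`, `helix`, `tag` and `id`;
#' patterns may use `*` and `?` globs. Examples: `"tag:acidic"`,
#' `"domain:I and tag:gate_cyt"`, `"not name:*"`.
#'
#' @param topology a `site_model`.
#' @param expression selection string.
#' @return 0-based, strictly ascending integer site indices (possibly
#'   empty).
#' @export
select <- function(topology, expression) {
  toks <- .sel_tokenize(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- .sel_or(st, topology)
  if (st$pos <= length(st$toks))
    stop("selection-syntax error: unexpected token '",
         st$toks[st$pos], "'")
  sort(which(mask) - 1L)
}

.sel_tokenize <- function(expr) {
  if (!is.character(expr) || length(expr) != 1L)
    stop("selection expression must be a single string")
  expr <- gsub("([()])", " \\1 ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  toks[nzchar(toks)]
}

.sel_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

.sel_or <- function(st, topo) {
  m <- .sel_and(st, topo)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "or") {
    st$pos <- st$pos + 1L
    m <- m | .sel_and(st, topo)
  }
  m
}

.sel_and <- function(st, topo) {
  m <- .sel_factor(st, topo)
  while (!is.na(.sel_peek(st)) && tolower(.sel_peek(st)) == "and") {
    st$pos <- st$pos + 1L
    m <- m & .sel_factor(st, topo)
  }
  m
}

.sel_factor <- function(st, topo) {
  tok <- .sel_peek(st)
  if (is.na(tok)) stop("selection-syntax error: unexpected end of input")
  if (tolower(tok) == "not") {
    st$pos <- st$pos + 1L
    return(!.sel_factor(st, topo))
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    m <- .sel_or(st, topo)
    if (is.na(.sel_peek(st)) || .sel_peek(st) != ")")
      stop("selection-syntax error: missing ')'")
    st$pos <- st$pos + 1L
    return(m)
  }
  st$pos <- st$pos + 1L
  .sel_atom(tok, topo)
}

.sel_atom <- function(tok, topo) {
  parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop("selection-syntax error: expected field:pattern, got '", tok, "'")
  field <- tolower(parts[1])
  pat <- parts[2]
  rx <- utils::glob2rx(pat)
  n <- n_sites(topo)
  switch(field,
    name = grepl(rx, topo$name),
    domain = grepl(rx, topo$domain),
    helix = !is.na(topo$helix) & grepl(rx, topo$helix),
    tag = vapply(topo$tags, function(tg) any(grepl(rx, tg)), logical(1)),
    id = {
      ids <- suppressWarnings(as.integer(pat))
      if (is.na(ids)) stop("selection-syntax error: id pattern must be ",
                           "an integer, got '", pat, "'")
      topo$site_id == ids
    },
    stop("selection-syntax error: unknown field '", field,
         "' (use name, domain, helix, tag, id)"))
}
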