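#' Resolve an atom selection expression
#'
#' A small, deterministic selection grammar over a [topology()]:
#'
#' * `role:<protein|lipid|ligand|ion|solvent>`
#' * `chain:<id>[,<id>...]`
#' * `resid:<n>`, `resid:<a>-<b>`, comma lists allowed
#' * `resname:<name>[,<name>...]`
#' * `name:<glob>[,<glob>...]` (atom-name glob, `*` and `?`)
#' * `element:<sym>[,<sym>...]`
#' * `region:<label>` (expands via the topology's region map)
#' * `all`, and boolean `and`, `or`, `not` with parentheses;
#'   `and` binds tighter than `or`.
#'
#' @param expr Selection expression string.
#' @param top A [topology()].
#' @return Sorted integer vector of 1-based atom positions (rows of
#'   `top$atoms`). The corresponding 0-based indices are
#'   `top$atoms$index[result]`.
#' @examples
#' # resolve_selection("role:ligand and name:O1", top)
#' # resolve_selection("region:S4 and chain:A", top)
#' @export
resolve_selection <- function(expr, top) {
  stopifnot(inherits(top, "topology"))
  if (!is.character(expr) || length(expr) != 1 || !nzchar(trimws(expr)))
    stop("selection expression must be a non-empty string")
  toks <- sel_tokenize(expr)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  mask <- sel_parse_or(st, top)
  if (st$pos <= length(st$toks))
    stop("trailing tokens in selection: ",
         paste(st$toks[st$pos:length(st$toks)], collapse = " "))
  sort(which(mask))
}

sel_tokenize <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(toks) == 0) stop("empty selection expression")
  toks
}

sel_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

sel_next <- function(st) {
  tok <- sel_peek(st)
  st$pos <- st$pos + 1L
  tok
}

sel_parse_or <- function(st, top) {
  mask <- sel_parse_and(st, top)
  while (identical(sel_peek(st), "or")) {
    sel_next(st)
    mask <- mask | sel_parse_and(st, top)
  }
  mask
}

sel_parse_and <- function(st, top) {
  mask <- sel_parse_unary(st, top)
  while (identical(sel_peek(st), "and")) {
    sel_next(st)
    mask <- mask & sel_parse_unary(st, top)
  }
  mask
}

sel_parse_unary <- function(st, top) {
  tok <- sel_peek(st)
  if (is.na(tok)) stop("unexpected end of selection expression")
  if (tok == "not") {
    sel_next(st)
    return(!sel_parse_unary(st, top))
  }
  if (tok == "(") {
    sel_next(st)
    mask <- sel_parse_or(st, top)
    if (!identical(sel_next(st), ")"))
      stop("unbalanced parentheses in selection")
    return(mask)
  }
  sel_eval_term(sel_next(st), top)
}

sel_eval_term <- function(tok, top) {
  a <- top$atoms
  if (tok == "all") return(rep(TRUE, nrow(a)))
  m <- regmatches(tok, regexec("^([a-z_]+):(.+)$", tok))[[1]]
  if (length(m) != 3)
    stop("malformed selection term '", tok, "'")
  key <- m[2]
  val <- m[3]
  vals <- strsplit(val, ",", fixed = TRUE)[[1]]
  switch(key,
    role = {
      bad <- setdiff(vals, ROLE_LEVELS)
      if (length(bad) > 0)
        stop("unknown role(s) in selection: ", paste(bad, collapse = ", "))
      a$role %in% vals
    },
    chain = a$chain %in% vals,
    resname = toupper(a$resname) %in% toupper(vals),
    element = toupper(a$element) %in% toupper(vals),
    name = {
      mask <- rep(FALSE, nrow(a))
      for (g in vals)
        mask <- mask | grepl(utils::glob2rx(g), a$name)
      mask
    },
    resid = {
      ids <- integer(0)
      for (v in vals) {
        r <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
        if (length(r) == 3) {
          ids <- c(ids, as.integer(r[2]):as.integer(r[3]))
        } else if (grepl("^-?[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else {
          stop("malformed resid term '", v, "'")
        }
      }
      a$resid %in% ids
    },
    region = {
      rm <- top$region_map
      if (is.null(rm))
        stop("selection uses region:", val,
             " but the topology has no region map")
      known <- unique(rm$region)
      if (!val %in% known)
        stop("unknown region label '", val, "'; known labels: ",
             paste(known, collapse = ", "))
      rows <- rm[rm$region == val, , drop = FALSE]
      paste(a$chain, a$resid) %in% paste(rows$chain, rows$resid)
    },
    stop("unknown selection key '", key, "'")
  )
}
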