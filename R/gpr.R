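#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers: `or` joins
#' isozymes, `and` joins members of a complex. The grammar is
#' case-insensitive, supports parentheses, and `and` binds tighter than
#' `or`. An empty or whitespace-only string yields `NULL` (a reaction with
#' no gene association).
#'
#' @param x a single GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return a GPR tree: either `NULL`, or a list with `op` in
#'   `c("gene", "and", "or")`; gene leaves carry `gene`, internal nodes
#'   carry `args` (a list of subtrees).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(x) {
  if (is.null(x) || length(x) == 0 || is.na(x)) return(NULL)
  stopifnot(is.character(x), length(x) == 1)
  s <- trimws(x)
  if (!nzchar(s)) return(NULL)
  toks <- gpr_tokenize(s)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("GPR parse error in '", x, "': unexpected token '",
         st$toks[st$pos], "'")
  }
  tree
}

gpr_tokenize <- function(s) {
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks)) NA_character_ else st$toks[st$pos]
}

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "or") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_and(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(tk <- gpr_peek(st)) && tolower(tk) == "and") {
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- gpr_parse_atom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  tk <- gpr_peek(st)
  if (is.na(tk)) stop("GPR parse error: unexpected end of expression")
  if (tk == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error: missing ')'")
    }
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tk == ")" || tolower(tk) %in% c("and", "or")) {
    stop("GPR parse error: unexpected token '", tk, "'")
  }
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk)
}

#' Render a GPR tree back to a rule string
#'
#' Inverse of [parse_gpr()] up to whitespace and operator case; `NULL`
#' renders as the empty string.
#'
#' @param gpr a GPR tree.
#' @return a single string.
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  switch(gpr$op,
    gene = gpr$gene,
    and = paste(vapply(gpr$args, function(a) {
      s <- deparse_gpr(a)
      if (!is.null(a$op) && a$op == "or") paste0("(", s, ")") else s
    }, character(1)), collapse = " and "),
    or = paste(vapply(gpr$args, deparse_gpr, character(1)),
               collapse = " or "),
    stop("invalid GPR node op: ", gpr$op)
  )
}

#' Genes appearing in a GPR tree
#'
#' @param gpr a GPR tree (possibly `NULL`).
#' @return character vector of unique gene ids (possibly empty).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$op == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR tree against a set of active genes
#'
#' @param gpr a GPR tree.
#' @param active_genes character vector of genes considered present.
#' @return logical; `NULL` trees evaluate to `FALSE`.
#' @export
eval_gpr <- function(gpr, active_genes) {
  if (is.null(gpr)) return(FALSE)
  switch(gpr$op,
    gene = gpr$gene %in% active_genes,
    and = all(vapply(gpr$args, eval_gpr, logical(1),
                     active_genes = active_genes)),
    or = any(vapply(gpr$args, eval_gpr, logical(1),
                    active_genes = active_genes))
  )
}

#' Restrict a GPR to genes with positive evidence
#'
#' When a reaction is kept in a tissue network, only genes whose evidence
#' score is positive are retained in its gene association. Leaves whose
#' gene has score <= 0 (or no score) are dropped; internal nodes with a
#' single surviving child collapse to that child; nodes with none are
#' dropped. The result may be `NULL` (empty association).
#'
#' @param gpr a GPR tree.
#' @param gene_scores named numeric vector of per-gene evidence scores;
#'   genes absent from it are treated as non-positive.
#' @return a pruned GPR tree or `NULL`.
#' @export
prune_gpr <- function(gpr, gene_scores) {
  if (is.null(gpr)) return(NULL)
  if (gpr$op == "gene") {
    sc <- gene_scores[gpr$gene]
    if (length(sc) == 1 && !is.na(sc) && sc > 0) return(gpr)
    return(NULL)
  }
  kept <- Filter(Negate(is.null),
                 lapply(gpr$args, prune_gpr, gene_scores = gene_scores))
  if (length(kept) == 0L) return(NULL)
  if (length(kept) == 1L) return(kept[[1L]])
  list(op = gpr$op, args = kept)
}
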