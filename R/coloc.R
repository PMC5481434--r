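#' Boolean expressions over signal maps
#'
#' Expressions combine named scans with `AND`, `OR` and `NOT` plus
#' parentheses. `NOT` binds tighter than `AND`, which binds tighter than
#' `OR`. In addition to unary `NOT`, the infix form `A NOT B` is accepted
#' as shorthand for `A AND NOT B` ("present in the first but not the
#' second scan"). Evaluation is restricted to the tissue mask: `NOT x`
#' means tissue pixels without `x`.
#'
#' @name coloc-algebra
NULL

.tokenize_expr <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("empty expression")
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  residue <- gsub("\\s", "", gsub(pat, "", text))
  if (nchar(residue) > 0)
    stop("unexpected characters in expression: ", residue)
  toks
}

#' Parse a scan-combination expression
#'
#' @param text expression string, e.g. `"CA199 AND NOT STRA"`.
#' @param scan_names optional character vector; when given, leaf names not
#'   in it are rejected at parse time.
#' @return an AST of class `marker_expression`: nested lists with `kind`
#'   in `"scan"`, `"and"`, `"or"`, `"not"`.
#' @export
parse_expression <- function(text, scan_names = NULL) {
  toks <- .tokenize_expr(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }

  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && toupper(peek()) == "OR") {
      advance()
      node <- list(kind = "or", a = node, b = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_unary()
    while (!is.na(peek()) && toupper(peek()) %in% c("AND", "NOT")) {
      op <- toupper(advance())
      rhs <- parse_unary()
      if (op == "NOT") rhs <- list(kind = "not", a = rhs)
      node <- list(kind = "and", a = node, b = rhs)
    }
    node
  }
  parse_unary <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of expression")
    if (toupper(t) == "NOT") {
      advance()
      return(list(kind = "not", a = parse_unary()))
    }
    if (t == "(") {
      advance()
      node <- parse_or()
      if (is.na(peek()) || peek() != ")") stop("missing closing parenthesis")
      advance()
      return(node)
    }
    if (t == ")" || toupper(t) %in% c("AND", "OR"))
      stop("unexpected token '", t, "'")
    advance()
    if (!is.null(scan_names) && !(t %in% scan_names))
      stop("unknown scan name '", t, "'")
    list(kind = "scan", name = t)
  }

  ast <- parse_or()
  if (!is.na(peek())) stop("trailing tokens after expression: ", peek())
  structure(ast, class = "marker_expression")
}

#' Evaluate a boolean expression over signal maps
#'
#' @param expr a [parse_expression()] result (or expression string).
#' @param maps named list of logical matrices (or `signal_map`s) sharing
#'   one pixel grid.
#' @param tissue tissue mask; all maps are intersected with it and `NOT`
#'   complements within it.
#' @return logical matrix, a subset of the tissue mask.
#' @export
evaluate_expression <- function(expr, maps, tissue) {
  if (is.character(expr)) expr <- parse_expression(expr)
  t <- if (inherits(tissue, "tissue_mask")) tissue$mask else tissue
  maps <- lapply(maps, function(m)
    if (inherits(m, "signal_map")) m$mask else m)
  for (m in maps)
    if (!all(dim(m) == dim(t))) stop("map grids do not match tissue mask")
  ev <- function(node) {
    switch(node$kind,
           scan = {
             if (is.null(maps[[node$name]]))
               stop("unknown scan name '", node$name, "'")
             maps[[node$name]] & t
           },
           and = ev(node$a) & ev(node$b),
           or = ev(node$a) | ev(node$b),
           not = t & !ev(node$a),
           stop("bad AST node"))
  }
  ev(expr)
}

#' Derive the five marker percentages for one tile
#'
#' From the CA19-9 and sTRA signal maps of a tile computes percent of
#' tissue pixels for: total CA19-9, total sTRA, CA19-9-only
#' (CA19-9 AND NOT sTRA), sTRA-only (sTRA AND NOT CA19-9) and dual
#' (CA19-9 AND sTRA). The conservation identities
#' `ca199_only + dual = ca199` and `stra_only + dual = stra` are exact
#' because all five shares use the same tissue denominator.
#'
#' @param ca199_map,stra_map signal maps (or logical matrices), subsets of
#'   the tissue mask.
#' @param tissue tissue mask.
#' @return object of class `marker_quant`: named numeric vector of the five
#'   percentages plus attributes `tissue_pixels` and pixel counts.
#' @export
quantify_markers <- function(ca199_map, stra_map, tissue) {
  t <- if (inherits(tissue, "tissue_mask")) tissue$mask else tissue
  a <- if (inherits(ca199_map, "signal_map")) ca199_map$mask else ca199_map
  b <- if (inherits(stra_map, "signal_map")) stra_map$mask else stra_map
  if (any(a & !t) || any(b & !t))
    stop("signal maps must be contained in the tissue mask")
  masks <- list(ca199 = a, stra = b,
                ca199_only = a & !b, stra_only = b & !a, dual = a & b)
  counts <- vapply(masks, sum, 0L)
  nt <- sum(t)
  pct <- if (nt == 0) counts * 0 else 100 * counts / nt
  # totals as literal sums of their parts so the conservation identities
  # hold bit-exactly, not just to rounding
  pct[["ca199"]] <- pct[["ca199_only"]] + pct[["dual"]]
  pct[["stra"]] <- pct[["stra_only"]] + pct[["dual"]]
  structure(pct, class = "marker_quant", tissue_pixels = nt,
            signal_pixels = counts)
}

#' Aggregate per-tile marker quantities to a core
#'
#' The core value of each marker is the unweighted mean of its per-tile
#' percentages (one value per image, averaged over all images for a core).
#' A tissue-area-weighted mean is available as a sensitivity analysis.
#'
#' @param tiles list of [quantify_markers()] results (one per tile).
#' @param core_id identifier carried into the result.
#' @param presence_threshold percent-of-tissue threshold for the core-level
#'   presence call; strictly greater than (default 1).
#' @param weighting `"equal"` (default) or `"tissue"`.
#' @return object of class `core_quant`: list with `core_id`, `markers`
#'   (the five averaged percentages), `presence` (logical per marker),
#'   `category` and `n_tiles`.
#' @export
aggregate_core <- function(tiles, core_id = NA_character_,
                           presence_threshold = 1,
                           weighting = c("equal", "tissue")) {
  weighting <- match.arg(weighting)
  if (length(tiles) == 0) stop("no tiles to aggregate")
  mat <- do.call(rbind, lapply(tiles, unclass))
  w <- if (weighting == "equal") rep(1, nrow(mat)) else
    vapply(tiles, attr, 0L, which = "tissue_pixels")
  if (sum(w) == 0) w <- rep(1, nrow(mat))
  markers <- colSums(mat * w) / sum(w)
  presence <- markers > presence_threshold
  structure(list(core_id = core_id, markers = markers, presence = presence,
                 category = call_core_category(markers[["ca199"]],
                                               markers[["stra"]],
                                               presence_threshold),
                 n_tiles = length(tiles)),
            class = "core_quant")
}

#' Core-level expression category
#'
#' A core expresses a marker when its averaged percent of tissue pixels is
#' strictly greater than the presence threshold (default 1 percent). The
#' two glycan presence calls give four categories.
#'
#' @param ca199_pct,stra_pct core-averaged percentages, or a `core_quant`
#'   as the first argument.
#' @param presence_threshold strict threshold, default 1.
#' @return one of `"ca199_only_core"`, `"stra_only_core"`, `"both"`,
#'   `"neither"`.
#' @export
call_core_category <- function(ca199_pct, stra_pct = NULL,
                               presence_threshold = 1) {
  if (inherits(ca199_pct, "core_quant")) {
    cq <- ca199_pct
    return(call_core_category(cq$markers[["ca199"]], cq$markers[["stra"]],
                              presence_threshold))
  }
  a <- ca199_pct > presence_threshold
  b <- stra_pct > presence_threshold
  if (a && b) "both" else if (a) "ca199_only_core" else
    if (b) "stra_only_core" else "neither"
}
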