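# Expression trees over the eight window statistics X1..X8.
# A node is either list(type = "t", ix = <1..8>) or
# list(type = "f", fun = <name>, args = list(<nodes>)).

GP_FUNCTIONS <- c(plus = 2L, minus = 2L, times = 2L, sin = 1L, cos = 1L,
                  log = 1L)

#' Build formula-tree nodes
#'
#' @param ix terminal feature index in 1..8 (`X1`..`X8`).
#' @return a `gp_tree` node.
#' @export
gp_terminal <- function(ix) {
  ix <- as.integer(ix)
  if (ix < 1L || ix > 8L) stop("terminal index must be in 1..8", call. = FALSE)
  structure(list(type = "t", ix = ix), class = "gp_tree")
}

#' @rdname gp_terminal
#' @param fun function name, one of plus, minus, times (binary) or
#'   sin, cos, log (unary).
#' @param ... child nodes (one for unary, two for binary functions).
#' @export
gp_node <- function(fun, ...) {
  args <- list(...)
  ar <- GP_FUNCTIONS[fun]
  if (is.na(ar)) stop("unknown function '", fun, "'", call. = FALSE)
  if (length(args) != ar)
    stop(fun, " takes ", ar, " argument(s)", call. = FALSE)
  structure(list(type = "f", fun = fun, args = args), class = "gp_tree")
}

#' Tree shape measures
#' @param tree a `gp_tree`.
#' @return integer depth (a bare terminal has depth 1) or node count.
#' @export
tree_depth <- function(tree) {
  if (tree$type == "t") return(1L)
  1L + max(vapply(tree$args, tree_depth, integer(1)))
}

#' @rdname tree_depth
#' @export
tree_size <- function(tree) {
  if (tree$type == "t") return(1L)
  1L + sum(vapply(tree$args, tree_size, integer(1)))
}

# preorder get / set of the i-th node (1 = root)
get_subtree <- function(tree, i) {
  found <- NULL
  walk <- function(node, count) {
    count <- count + 1L
    if (count == i) { found <<- node; return(count) }
    if (node$type == "f") for (a in node$args) {
      count <- walk(a, count)
      if (!is.null(found)) return(count)
    }
    count
  }
  walk(tree, 0L)
  if (is.null(found)) stop("node index out of range", call. = FALSE)
  found
}

set_subtree <- function(tree, i, new) {
  count <- 0L
  walk <- function(node) {
    count <<- count + 1L
    if (count == i) return(new)
    if (node$type == "f") {
      for (j in seq_along(node$args)) {
        done <- count >= i
        if (!done) node$args[[j]] <- walk(node$args[[j]])
      }
    }
    node
  }
  out <- walk(tree)
  if (count < i) stop("node index out of range", call. = FALSE)
  out
}

#' Evaluate a formula tree on feature vectors
#'
#' Bottom-up, deterministic evaluation. The natural logarithm is protected:
#' `log(x)` is `log(abs(x))` when `abs(x) > 1e-12` and 0 otherwise, so
#' evolved formulas never produce undefined values. Any non-finite value
#' surviving at the root (e.g. overflow of a deep `times` chain) is mapped
#' to 0: the output is always finite.
#'
#' @param tree a `gp_tree`.
#' @param features either a named numeric vector `X1..X8` or an n x 8 matrix
#'   (one row per segment) as from [extract_features_matrix()].
#' @return numeric vector with one scalar per feature row.
#' @examples
#' evaluate_formula(parse_formula("(plus X1 (times X2 X3))"),
#'                  c(X1 = 1, X2 = 2, X3 = 3, X4 = 0, X5 = 0, X6 = 0,
#'                    X7 = 0, X8 = 0))  # 7
#' @export
evaluate_formula <- function(tree, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L,
                                                 dimnames = list(NULL, names(features)))
  if (ncol(features) < 8L)
    stop("feature input must have 8 columns X1..X8", call. = FALSE)
  v <- eval_node(tree, features)
  v[!is.finite(v)] <- 0
  unname(v)
}

eval_node <- function(node, X) {
  if (node$type == "t") return(X[, node$ix])
  a <- eval_node(node$args[[1L]], X)
  switch(node$fun,
    plus  = a + eval_node(node$args[[2L]], X),
    minus = a - eval_node(node$args[[2L]], X),
    times = a * eval_node(node$args[[2L]], X),
    sin   = sin(a),
    cos   = cos(a),
    log   = protected_log(a),
    stop("malformed tree: unknown function '", node$fun, "'", call. = FALSE)
  )
}

protected_log <- function(x) {
  out <- numeric(length(x))
  ok <- abs(x) > 1e-12
  out[ok] <- log(abs(x[ok]))
  out
}

#' Random tree generation
#'
#' `random_tree` grows a single tree by the "grow" or "full" method;
#' `ramped_population` builds a population by ramped half-and-half over
#' depths 2-6 (alternating grow/full across the ramp), the community default
#' for diverse initial populations. Terminals are drawn uniformly from
#' `terminals`.
#'
#' @param max_depth maximum depth (a bare terminal has depth 1).
#' @param method `"grow"` (function/terminal chosen uniformly from the joint
#'   set until the depth bound forces a terminal) or `"full"` (functions down
#'   to the bound).
#' @param terminals integer feature indices eligible as leaves.
#' @return a `gp_tree` (or a list of them for `ramped_population`).
#' @export
random_tree <- function(max_depth, method = c("grow", "full"),
                        terminals = 1:8) {
  method <- match.arg(method)
  stopifnot(max_depth >= 1L, length(terminals) >= 1L)
  if (max_depth == 1L)
    return(gp_terminal(resample(terminals, 1L)))
  fun_names <- names(GP_FUNCTIONS)
  if (method == "grow") {
    n_choices <- length(fun_names) + length(terminals)
    pick <- resample(seq_len(n_choices), 1L)
    if (pick > length(fun_names))
      return(gp_terminal(terminals[pick - length(fun_names)]))
    fun <- fun_names[pick]
  } else {
    fun <- resample(fun_names, 1L)
  }
  kids <- replicate(GP_FUNCTIONS[[fun]],
                    random_tree(max_depth - 1L, method, terminals),
                    simplify = FALSE)
  do.call(gp_node, c(list(fun), kids))
}

#' @rdname random_tree
#' @param n population size.
#' @export
ramped_population <- function(n, terminals = 1:8) {
  depths <- rep_len(2:6, n)
  methods <- rep_len(c("grow", "full"), n)
  lapply(seq_len(n), function(i) random_tree(depths[i], methods[i], terminals))
}

# sample() that never treats a length-1 vector as 1:x
resample <- function(x, size) x[sample.int(length(x), size)]

#' Serialise / parse formulas as prefix s-expressions
#'
#' Text form e.g. `(plus X1 (times X2 X3))`; a bare terminal is `X4`.
#'
#' @param tree a `gp_tree`.
#' @return `deparse_formula` a string; `parse_formula` a `gp_tree`.
#' @export
deparse_formula <- function(tree) {
  if (tree$type == "t") return(paste0("X", tree$ix))
  paste0("(", tree$fun, " ",
         paste(vapply(tree$args, deparse_formula, character(1)),
               collapse = " "), ")")
}

#' @rdname deparse_formula
#' @param text s-expression string.
#' @export
parse_formula <- function(text) {
  toks <- strsplit(gsub("([()])", " \\1 ", text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  pos <- 0L
  nxt <- function() { pos <<- pos + 1L; toks[pos] }
  parse_node <- function() {
    t <- nxt()
    if (is.na(t)) stop("unexpected end of formula", call. = FALSE)
    if (t == "(") {
      fun <- nxt()
      ar <- GP_FUNCTIONS[fun]
      if (is.na(ar)) stop("unknown function '", fun, "'", call. = FALSE)
      kids <- lapply(seq_len(ar), function(i) parse_node())
      if (!identical(nxt(), ")")) stop("expected ')'", call. = FALSE)
      do.call(gp_node, c(list(fun), kids))
    } else if (grepl("^X[1-8]$", t)) {
      gp_terminal(as.integer(substring(t, 2L)))
    } else stop("unexpected token '", t, "'", call. = FALSE)
  }
  out <- parse_node()
  if (pos != length(toks)) stop("trailing tokens after formula", call. = FALSE)
  out
}

#' @export
print.gp_tree <- function(x, ...) {
  cat("<gp_tree> depth", tree_depth(x), "size", tree_size(x), "\n ",
      deparse_formula(x), "\n")
  invisible(x)
}

#' Read / write a formula file
#' @param tree a `gp_tree`.
#' @param path file path.
#' @export
write_formula <- function(tree, path) {
  writeLines(deparse_formula(tree), path)
  invisible(path)
}

#' @rdname write_formula
#' @export
read_formula <- function(path) parse_formula(paste(readLines(path),
                                                   collapse = " "))
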