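# Dependency parses: container, validation, shortest paths, type
# generalization and path-length binning.

#' Construct a dependency parse
#'
#' A parse is a tree over the sentence's token indices: every non-root
#' token has exactly one head, and the edge carries a typed dependency
#' label. The container is parser-agnostic; parses may come from any
#' provider (the synthetic generator emits template parses, and
#' [chain_parse()] gives a naive fallback for free text).
#'
#' @param edges data.frame with columns `head`, `dep` (token indices) and
#'   `type` (dependency label).
#' @param n_tokens number of tokens in the sentence.
#' @param root root token index.
#' @return object of class `rc_parse`.
#' @export
dependency_parse <- function(edges, n_tokens, root) {
  stopifnot(is.data.frame(edges), all(c("head", "dep", "type") %in% names(edges)))
  if (n_tokens < 1L) stop("parse needs at least one token")
  if (root < 1L || root > n_tokens) stop("root index out of bounds")
  if (nrow(edges)) {
    idx <- c(edges$head, edges$dep)
    if (any(idx < 1L | idx > n_tokens)) stop("edge index out of bounds")
    if (any(edges$head == edges$dep)) stop("self-loop edge in parse")
    if (anyDuplicated(edges$dep)) stop("a token may have only one head")
    if (root %in% edges$dep) stop("root must not have a head")
  }
  covered <- sort(unique(c(root, edges$dep)))
  if (!identical(covered, seq_len(n_tokens)))
    stop("parse is not connected over all tokens")
  structure(list(edges = edges, n_tokens = n_tokens, root = root),
            class = "rc_parse")
}

#' A naive chain parse
#'
#' Attaches each token to its predecessor with the generic `dep` label.
#' Path lengths under a chain parse equal token-position distances; this
#' is the dependency-provider fallback when no syntactic parser is wired
#' in.
#'
#' @param n_tokens number of tokens.
#' @return an `rc_parse`.
#' @export
chain_parse <- function(n_tokens) {
  if (n_tokens == 1L) {
    return(dependency_parse(
      data.frame(head = integer(0), dep = integer(0), type = character(0),
                 stringsAsFactors = FALSE), 1L, 1L))
  }
  dependency_parse(
    data.frame(head = seq_len(n_tokens - 1L), dep = 2:n_tokens,
               type = "dep", stringsAsFactors = FALSE),
    n_tokens, 1L)
}

#' Shortest path between two tokens in a dependency parse
#'
#' Breadth-first search over the undirected parse graph. Length is the
#' number of edges. Ties (impossible in a tree but possible in general
#' graphs) break toward the lexicographically smallest token-index
#' sequence because neighbours are expanded in increasing index order.
#'
#' @param parse an `rc_parse`.
#' @param a,b token indices.
#' @return list with `nodes` (ordered token indices, `a` first), `edges`
#'   (data.frame `from`, `to`, `type` along the path) and `length`.
#' @export
shortest_dependency_path <- function(parse, a, b) {
  n <- parse$n_tokens
  stopifnot(a >= 1L, a <= n, b >= 1L, b <= n)
  if (a == b) {
    return(list(nodes = a,
                edges = data.frame(from = integer(0), to = integer(0),
                                   type = character(0), stringsAsFactors = FALSE),
                length = 0L))
  }
  adj <- vector("list", n)
  etype <- new.env(hash = TRUE)
  for (i in seq_len(nrow(parse$edges))) {
    h <- parse$edges$head[i]; d <- parse$edges$dep[i]
    adj[[h]] <- c(adj[[h]], d); adj[[d]] <- c(adj[[d]], h)
    assign(paste(min(h, d), max(h, d)), parse$edges$type[i], envir = etype)
  }
  prev <- rep(NA_integer_, n)
  visited <- rep(FALSE, n); visited[a] <- TRUE
  frontier <- a
  while (length(frontier) && !visited[b]) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in sort(adj[[u]])) {
        if (!visited[v]) {
          visited[v] <- TRUE; prev[v] <- u; nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  if (!visited[b]) stop("tokens ", a, " and ", b, " are disconnected in the parse")
  nodes <- b
  while (nodes[1L] != a) nodes <- c(prev[nodes[1L]], nodes)
  edges <- data.frame(
    from = nodes[-length(nodes)], to = nodes[-1L],
    type = vapply(seq_len(length(nodes) - 1L), function(i) {
      get(paste(min(nodes[i], nodes[i + 1L]), max(nodes[i], nodes[i + 1L])),
          envir = etype)
    }, character(1)),
    stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, length = length(nodes) - 1L)
}

#' Bin a dependency-path length into near/moderate/far
#'
#' Lengths up to 3 are `near`, 4-6 `moderate`, 7 and above `far`; the
#' three bins partition all nonnegative lengths.
#'
#' @param length nonnegative integer path length(s).
#' @return character vector of bin labels.
#' @export
path_bin <- function(length) {
  stopifnot(all(length >= 0))
  ifelse(length <= 3, "near", ifelse(length <= 6, "moderate", "far"))
}

#' Read the dependency-type generalization map
#'
#' Maps specific typed-dependency labels to their generic (second-level)
#' class, e.g. `nsubj`/`nsubjpass`/`csubj` to `subj`. Shipped as an
#' editable TSV with columns `specific` and `generic`.
#'
#' @param path TSV path.
#' @return named character vector `map[specific] == generic`.
#' @export
read_dep_type_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("specific", "generic") %in% names(df)))
  stats::setNames(df$generic, df$specific)
}

#' Generalize dependency types
#'
#' Unmapped labels pass through unchanged.
#'
#' @param type character vector of dependency labels.
#' @param map named vector from [read_dep_type_map()].
#' @return character vector of generic labels.
#' @export
generalize_dep_type <- function(type, map) {
  ifelse(type %in% names(map), unname(map[type]), type)
}
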