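# Shared fixtures: load the bundled resources once per test run, and
# small independent oracles used by the property suites.

.res_cache <- new.env(parent = emptyenv())

test_resources <- function() {
  if (is.null(.res_cache$res)) .res_cache$res <- load_default_resources()
  .res_cache$res
}

# Build a minimal annotated sentence object by hand (bypasses the
# preprocessing chain) for unit tests of the filter and feature stages.
make_sentence <- function(normalized, pos = rep("NN", length(normalized)),
                          is_gene = normalized == "genename",
                          mentions = NULL, pmid = "T1", index = 0L) {
  gm <- if (is.null(mentions)) {
    idx <- which(is_gene)
    data.frame(start = idx, end = idx,
               gene_id = paste0("G", seq_along(idx), recycle0 = TRUE),
               stringsAsFactors = FALSE)
  } else mentions
  structure(list(
    pmid = pmid, index = index, raw = paste(normalized, collapse = " "),
    tokens = data.frame(surface = normalized, pos = pos,
                        normalized = normalized, is_gene = is_gene,
                        stringsAsFactors = FALSE),
    gene_mentions = gm, parse = NULL), class = "rc_sentence")
}

# Independent BFS distance oracle over an undirected edge list.
bfs_distance <- function(edges, n, a, b) {
  if (a == b) return(0L)
  adj <- lapply(seq_len(n), function(i)
    c(edges$dep[edges$head == i], edges$head[edges$dep == i]))
  dist <- rep(NA_integer_, n); dist[a] <- 0L
  frontier <- a
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) for (v in adj[[u]]) if (is.na(dist[v])) {
      dist[v] <- dist[u] + 1L; nxt <- c(nxt, v)
    }
    frontier <- nxt
  }
  dist[b]
}

# Independent relation-closure oracle: enumerate every directed path in
# the (acyclic) relation graph and fold the composition table
# left-to-right along it.
closure_oracle <- function(relations) {
  comp <- function(r1, r2) {
    if (is.na(r1) || is.na(r2)) return(NA_character_)
    if (r2 == "is_a") return(r1)
    if (r1 == "is_a") return(r2)
    if (r1 == "part_of" && r2 == "part_of") return("part_of")
    if ((r1 == "part_of" && r2 == "result_from") ||
        (r1 == "result_from" && r2 == "part_of")) return("result_from")
    NA_character_
  }
  out <- unique(relations[, c("subject", "relation", "object")])
  extend <- function(node, acc_rel, origin) {
    outgoing <- which(relations$subject == node)
    for (i in outgoing) {
      r <- comp(acc_rel, relations$relation[i])
      nxt <- relations$object[i]
      if (!is.na(r)) {
        out <<- unique(rbind(out, data.frame(subject = origin, relation = r,
                                             object = nxt,
                                             stringsAsFactors = FALSE)))
      }
      extend(nxt, r, origin)
    }
  }
  for (i in seq_len(nrow(relations))) {
    extend(relations$object[i], relations$relation[i], relations$subject[i])
  }
  out[order(out$subject, out$relation, out$object), , drop = FALSE]
}

# Random DAG over n nodes with typed edges (edges only from lower to
# higher labels, so paths are finite).
random_relation_dag <- function(n, p = 0.35) {
  rows <- list()
  labels <- LETTERS[seq_len(n)]
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject = labels[i],
        relation = sample(c("is_a", "part_of", "result_from"), 1L),
        object = labels[j], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(subject = character(0), relation = character(0),
                      object = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

rel_key <- function(df) sort(paste(df$subject, df$relation, df$object))
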