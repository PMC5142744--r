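#' Create a Bloom-filter k-mer graph
#'
#' A node graph stores an approximate *set* of canonical k-mers (one bit
#' table per hash function, same deterministic hash family as the counting
#' sketch) with implicit edges between k-mers that overlap by k-1 bases.
#' Membership has no false negatives; false positives occur with
#' probability roughly the product of the table occupancies ([fp_rate()]).
#' Like sketches, graphs have reference semantics and are updated in place.
#'
#' @param spec A [kmer_spec()].
#' @param family Optional [hash_family()]; defaults to
#'   `hash_family(n_tables, table_size)`.
#' @param n_tables,table_size Used when `family` is NULL.
#' @return An object of class `node_graph`.
#' @examples
#' g <- node_graph(kmer_spec(3), table_size = 1e4)
#' add_node(g, "AAA")
#' graph_contains(g, c("AAA", "TTT", "ACG"))
#' @export
node_graph <- function(spec, family = NULL, n_tables = 4, table_size = 1e6) {
  spec <- as_kmer_spec(spec)
  family <- resolve_family(family, n_tables, table_size)
  ptr <- .ng_new(spec$k, spec$canonical, family$table_sizes)
  structure(list(ptr = ptr, spec = spec, family = family),
            class = "node_graph")
}

as_ng <- function(graph) {
  if (!inherits(graph, "node_graph")) {
    stop("expected a 'node_graph' object; see node_graph()", call. = FALSE)
  }
  graph
}

#' @export
print.node_graph <- function(x, ...) {
  info <- .ng_info(x$ptr)
  cat(sprintf("<node_graph> k = %d (%s), %d bit tables\n",
              info$k, if (info$canonical) "canonical" else "stranded",
              length(info$table_sizes)))
  cat(sprintf("  table sizes: %s\n",
              paste(format(info$table_sizes, scientific = FALSE), collapse = ", ")))
  cat(sprintf("  nodes added: %.0f; fp rate: %.3g\n", info$n_added, fp_rate(x)))
  invisible(x)
}

#' Add a k-mer node to the graph
#'
#' Sets the k-mer's bit in every table. In canonical mode, adding a k-mer's
#' reverse complement is a no-op once the k-mer itself is present.
#'
#' @param graph A [node_graph()].
#' @param kmer A single k-mer of length `k`, no ambiguous bases.
#' @return `TRUE` if the k-mer was new (some bit was previously unset),
#'   `FALSE` if it was already present.
#' @export
add_node <- function(graph, kmer) {
  graph <- as_ng(graph)
  .ng_add(graph$ptr, kmer)
}

#' Load all k-mers of sequences into the graph
#'
#' @param graph A [node_graph()].
#' @param seqs Character vector of sequences, or a records data.frame from
#'   [read_records()].
#' @return Number of k-mers that were new, with attribute `skipped_windows`.
#' @export
consume_graph <- function(graph, seqs) {
  graph <- as_ng(graph)
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  stopifnot(is.character(seqs))
  res <- .ng_consume(graph$ptr, seqs)
  structure(res$n_new, skipped_windows = res$skipped)
}

#' Test k-mer presence
#'
#' No false negatives: every k-mer ever added reports `TRUE`. A small
#' fraction of never-added k-mers may also report `TRUE` (see [fp_rate()]).
#'
#' @param graph A [node_graph()].
#' @param kmers Character vector of k-mers.
#' @return Logical vector.
#' @export
graph_contains <- function(graph, kmers) {
  graph <- as_ng(graph)
  .ng_contains(graph$ptr, kmers)
}

#' Present neighbors of a k-mer
#'
#' Enumerates the at most 8 candidate k-mers overlapping the query by k-1
#' bases (four right extensions `suffix + b`, four left extensions
#' `b + prefix`), canonicalizes them, and returns those the graph reports
#' present, sorted lexicographically. The query itself may appear (a
#' self-loop, e.g. for homopolymer k-mers); the query need not be present.
#'
#' @param graph A [node_graph()].
#' @param kmer A single k-mer.
#' @return Character vector of canonical k-mers.
#' @export
graph_neighbors <- function(graph, kmer) {
  graph <- as_ng(graph)
  .ng_neighbors(graph$ptr, kmer)
}

#' Connected component of a seed k-mer
#'
#' Breadth-first traversal over [graph_neighbors()] starting from `seed`,
#' visiting each frontier in lexicographic order so traversals are
#' reproducible, until exhaustion or until `max_nodes` k-mers have been
#' reached.
#'
#' @param graph A [node_graph()].
#' @param seed A k-mer present in the graph (absent seeds raise an error).
#' @param max_nodes Traversal cap (default `Inf`).
#' @return A list with `kmers` (sorted character vector of canonical k-mers
#'   reached, including the seed) and `truncated` (logical: was the cap
#'   hit before exhaustion).
#' @export
connected_component <- function(graph, seed, max_nodes = Inf) {
  graph <- as_ng(graph)
  stopifnot(is.numeric(max_nodes), length(max_nodes) == 1L, max_nodes >= 1)
  .ng_component(graph$ptr, seed, max_nodes)
}

#' Partition reads by shared k-mer connectivity
#'
#' Two reads receive the same partition id exactly when their k-mer sets
#' lie in the same connected component of the graph (each read also links
#' its own k-mers, so a read spans ambiguity gaps within itself). The
#' implementation unions canonical k-mers discovered by traversal over the
#' graph's membership filter, then maps each read through its first k-mer.
#' Ids are dense integers assigned in first-seen read order; reads with
#' zero valid k-mers get the sentinel partition 0. The graph must already
#' contain all reads' k-mers (see [consume_graph()]).
#'
#' @param graph A [node_graph()].
#' @param reads Character vector of sequences, or a records data.frame from
#'   [read_records()].
#' @return An integer vector of partition ids, named by read id when
#'   `reads` is a records data.frame.
#' @export
partition_reads <- function(graph, reads) {
  graph <- as_ng(graph)
  ids <- NULL
  if (is.data.frame(reads)) {
    ids <- reads$id
    reads <- reads$sequence
  }
  stopifnot(is.character(reads))
  part <- .ng_partition(graph$ptr, reads)
  if (!is.null(ids)) names(part) <- ids
  part
}

#' Write read partitions as TSV
#'
#' Writes a two-column table with header `read_id<TAB>partition_id`.
#'
#' @param partitions Named integer vector from [partition_reads()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_partitions <- function(partitions, path) {
  ids <- names(partitions)
  if (is.null(ids)) ids <- as.character(seq_along(partitions))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("read_id\tpartition_id",
               paste(ids, partitions, sep = "\t")), con)
  invisible(path)
}

#' Save / load a node graph
#'
#' Same validated container as [save_sketch()] with magic `"MNG1"`; each
#' table's payload is its packed bit array (size recorded in bits).
#'
#' @param graph A [node_graph()].
#' @param path File path.
#' @return `save_graph()` returns `path` invisibly; `load_graph()` a
#'   `node_graph`.
#' @export
save_graph <- function(graph, path) {
  graph <- as_ng(graph)
  info <- .ng_info(graph$ptr)
  payloads <- lapply(seq_along(info$table_sizes),
                     function(i) .ng_table_bytes(graph$ptr, i))
  save_tables(path, "MNG1", graph$spec, info$table_sizes, payloads,
              info$n_added)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  dat <- load_tables(path, "MNG1", payload_len = function(size) ceiling(size / 8))
  spec <- kmer_spec(dat$k, dat$canonical)
  family <- structure(list(table_sizes = dat$sizes), class = "hash_family")
  graph <- node_graph(spec, family = family)
  for (i in seq_along(dat$payloads)) {
    .ng_set_table_bytes(graph$ptr, i, dat$payloads[[i]], dat$n_consumed)
  }
  graph
}
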