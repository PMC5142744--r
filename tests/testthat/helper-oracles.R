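# Independent oracles used by the tests: plain string manipulation, exact
# dictionary counters and igraph connectivity — deliberately sharing no
# code path with the package's 2-bit/sketch implementation.

oracle_revcomp <- function(s) {
  if (nchar(s) == 0L) return("")
  paste(rev(strsplit(chartr("ACGTacgtNn", "TGCAtgcaNn", s), "")[[1]]),
        collapse = "")
}

# vectorized reverse complement of equal-length upper-case k-mers
oracle_revcomp_vec <- function(x, k) {
  if (length(x) == 0L) return(character(0))
  ch <- chartr("ACGT", "TGCA", x)
  m <- matrix(unlist(strsplit(ch, "", fixed = TRUE), use.names = FALSE),
              nrow = k)
  do.call(paste0, lapply(k:1, function(i) m[i, ]))
}

oracle_canon_vec <- function(x, k) {
  rc <- oracle_revcomp_vec(x, k)
  ifelse(rc < x, rc, x)
}

# all valid (N-free) canonical k-mers of one sequence, in window order;
# attribute "pos" holds their 1-based starts
oracle_kmers <- function(seq, k, canonical = TRUE) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < k) return(structure(character(0), pos = integer(0)))
  starts <- 1:(L - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", km)
  km <- km[ok]
  if (canonical && length(km)) km <- oracle_canon_vec(km, k)
  structure(km, pos = starts[ok])
}

# exact dictionary counts over a stream of sequences (batch
# canonicalization: one matrix pass over all windows)
oracle_counts <- function(seqs, k, canonical = TRUE) {
  km <- unlist(lapply(seqs, function(s) {
    s <- toupper(s)
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- 1:(L - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  km <- km[!grepl("[^ACGT]", km)]
  if (length(km) == 0L) return(table(character(0)))
  if (canonical) km <- oracle_canon_vec(km, k)
  table(km)
}

oracle_lookup <- function(tab, kmers) {
  v <- as.integer(tab[kmers])
  v[is.na(v)] <- 0L
  v
}

# present adjacent canonical k-mers of `kmer` within an exact k-mer set
oracle_neighbors <- function(kmer, kmer_set, k) {
  suf <- substr(kmer, 2L, k)
  pre <- substr(kmer, 1L, k - 1L)
  cand <- unique(oracle_canon_vec(c(paste0(suf, c("A", "C", "G", "T")),
                                    paste0(c("A", "C", "G", "T"), pre)), k))
  sort(intersect(cand, kmer_set))
}

# read partitioning oracle: igraph components over exact k-mer adjacency,
# with each read tied to its own k-mers
oracle_partitions <- function(seqs, k) {
  km_sets <- lapply(seqs, function(s) unique(oracle_kmers(s, k)))
  all_km <- unique(unlist(km_sets, use.names = FALSE))
  edges <- character(0)
  for (x in all_km) {
    nb <- oracle_neighbors(x, all_km, k)
    if (length(nb)) edges <- c(edges, rbind(x, nb))
  }
  read_v <- paste0("read::", seq_along(seqs))
  for (i in seq_along(seqs)) {
    if (length(km_sets[[i]])) {
      edges <- c(edges, rbind(read_v[[i]], km_sets[[i]]))
    }
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  g <- g + igraph::vertices(setdiff(c(read_v, all_km), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  out <- integer(length(seqs))
  seen <- integer(0)
  nxt <- 1L
  for (i in seq_along(seqs)) {
    if (length(km_sets[[i]]) == 0L) { out[[i]] <- 0L; next }
    m <- comp[[read_v[[i]]]]
    j <- match(m, seen)
    if (is.na(j)) { seen <- c(seen, m); out[[i]] <- nxt; nxt <- nxt + 1L }
    else out[[i]] <- j
  }
  out
}

# surviving length under trim-at-first-low-k-mer against exact counts;
# NA_integer_ means "unchanged", 0 means "discarded"
oracle_trim_len <- function(seq, k, tab, min_count, min_length = k) {
  km <- oracle_kmers(seq, k)
  if (length(km) == 0L) return(NA_integer_)
  cnt <- oracle_lookup(tab, km)
  low <- which(cnt < min_count)
  if (length(low) == 0L) return(NA_integer_)
  keep_len <- as.integer(attr(km, "pos")[low[[1]]] + k - 2L)
  if (keep_len < min_length) 0L else keep_len
}

# streaming diginorm oracle with an exact dictionary counter
oracle_diginorm_keep <- function(seqs, k, C) {
  counts <- new.env(parent = emptyenv())
  keep <- logical(length(seqs))
  for (i in seq_along(seqs)) {
    km <- oracle_kmers(seqs[[i]], k)
    if (length(km) == 0L) next
    cnt <- vapply(km, function(x) get0(x, counts, ifnotfound = 0L), 0L,
                  USE.NAMES = FALSE)
    med <- sort(cnt)[length(cnt) %/% 2L + 1L]
    if (med < C) {
      keep[[i]] <- TRUE
      for (x in km) assign(x, get0(x, counts, ifnotfound = 0L) + 1L, counts)
    }
  }
  keep
}

# random k-mer strings (for collision/fp probes), independent of the seed
# machinery under test
random_kmers <- function(n, k) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = k)
  unique(do.call(paste0, lapply(seq_len(k), function(i) m[i, ])))
}

# small sketch/graph fixtures used across files
tiny_spec <- function(k = 5) kmer_spec(k)
tiny_sketch <- function(k = 5, table_size = 1e4, n_tables = 4) {
  countmin_sketch(kmer_spec(k), n_tables = n_tables, table_size = table_size)
}
tiny_graph <- function(k = 5, table_size = 1e4, n_tables = 4) {
  node_graph(kmer_spec(k), n_tables = n_tables, table_size = table_size)
}
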