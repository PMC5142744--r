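// Core k-mer machinery: 2-bit encoding, canonicalization, the fixed hash
// family, the CountMin sketch and the Bloom-filter node graph. Everything
// here is deterministic: no randomized seeding anywhere, so sketch contents
// and traversals reproduce bit-exactly across runs and platforms.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <algorithm>
#include <unordered_set>
#include <unordered_map>

using namespace Rcpp;

// ---- encoding ------------------------------------------------------------

// A=0, C=1, G=2, T=3 (case-insensitive); -1 for N/anything else.
static inline int base2bit(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static inline bool is_ambiguous(char c) {
    return c == 'N' || c == 'n';
}

static const char BASES[4] = {'A', 'C', 'G', 'T'};

// Most-significant base first, so numeric order on codes equals
// lexicographic order on the decoded strings (A<C<G<T).
static uint64_t encode_kmer(const std::string &kmer) {
    uint64_t code = 0;
    for (size_t i = 0; i < kmer.size(); ++i) {
        int b = base2bit(kmer[i]);
        if (b < 0) {
            if (is_ambiguous(kmer[i]))
                stop("k-mer contains ambiguous base 'N' at position %d", (int)(i + 1));
            stop("invalid alphabet: character '%c' at position %d (allowed: A, C, G, T, N)",
                 kmer[i], (int)(i + 1));
        }
        code = (code << 2) | (uint64_t)b;
    }
    return code;
}

static std::string decode_kmer(uint64_t code, int k) {
    std::string out((size_t)k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        out[(size_t)i] = BASES[code & 3ULL];
        code >>= 2;
    }
    return out;
}

static inline uint64_t revcomp_code(uint64_t code, int k) {
    uint64_t rc = 0;
    for (int i = 0; i < k; ++i) {
        rc = (rc << 2) | (3ULL - (code & 3ULL));
        code >>= 2;
    }
    return rc;
}

static inline uint64_t canonical_code(uint64_t code, int k, bool canonical) {
    if (!canonical) return code;
    uint64_t rc = revcomp_code(code, k);
    return rc < code ? rc : code;
}

// splitmix64 finalizer: fixed constants, no per-run seeding.
static inline uint64_t mix64(uint64_t z) {
    z += 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
}

static void check_k(int k) {
    if (k < 1 || k > 32)
        stop("k must be between 1 and 32 (got %d): k-mers are packed 2 bits per base into a 64-bit word",
             k);
}

// Enumerate canonical codes of all valid (N-free) windows of `seq`.
// pos1 gets the 1-based window starts; returns the number of windows
// skipped because they covered a non-ACGT character.
static uint64_t scan_kmers(const std::string &seq, int k, bool canonical,
                           std::vector<uint64_t> &codes, std::vector<int> *pos1) {
    codes.clear();
    if (pos1) pos1->clear();
    const long L = (long)seq.size();
    if (L < k) return 0;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    uint64_t fwd = 0;
    long last_bad = -1;  // index of last non-ACGT character seen
    uint64_t skipped = 0;
    for (long i = 0; i < L; ++i) {
        int b = base2bit(seq[(size_t)i]);
        if (b < 0) {
            last_bad = i;
            fwd = 0;
        } else {
            fwd = ((fwd << 2) | (uint64_t)b) & mask;
        }
        long start = i - k + 1;
        if (start < 0) continue;
        if (last_bad >= start) {
            ++skipped;
            continue;
        }
        uint64_t code = canonical ? canonical_code(fwd, k, true) : fwd;
        codes.push_back(code);
        if (pos1) pos1->push_back((int)start + 1);
    }
    return skipped;
}

// ---- exported k-mer primitives -------------------------------------------

// [[Rcpp::export(name = ".rc_cpp")]]
CharacterVector rc_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        if (CharacterVector::is_na(seqs[j])) { out[j] = NA_STRING; continue; }
        std::string s = as<std::string>(seqs[j]);
        std::string r(s.size(), 'N');
        for (size_t i = 0; i < s.size(); ++i) {
            char c = s[s.size() - 1 - i];
            int b = base2bit(c);
            if (b >= 0) {
                r[i] = BASES[3 - b];
            } else if (is_ambiguous(c)) {
                r[i] = 'N';
            } else {
                stop("invalid alphabet: character '%c' at position %d (allowed: A, C, G, T, N)",
                     c, (int)(s.size() - i));
            }
        }
        out[j] = r;
    }
    return out;
}

// [[Rcpp::export(name = ".canonical_cpp")]]
CharacterVector canonical_cpp(CharacterVector kmers, int k, bool canonical) {
    check_k(k);
    CharacterVector out(kmers.size());
    for (R_xlen_t j = 0; j < kmers.size(); ++j) {
        std::string s = as<std::string>(kmers[j]);
        if ((int)s.size() != k)
            stop("k-mer length %d does not match k = %d", (int)s.size(), k);
        uint64_t code = encode_kmer(s);
        out[j] = decode_kmer(canonical_code(code, k, canonical), k);
    }
    return out;
}

// [[Rcpp::export(name = ".iter_kmers_cpp")]]
List iter_kmers_cpp(std::string seq, int k, bool canonical) {
    check_k(k);
    std::vector<uint64_t> codes;
    std::vector<int> pos1;
    uint64_t skipped = scan_kmers(seq, k, canonical, codes, &pos1);
    CharacterVector kmers(codes.size());
    for (size_t i = 0; i < codes.size(); ++i) kmers[(R_xlen_t)i] = decode_kmer(codes[i], k);
    return List::create(_["pos"] = wrap(pos1), _["kmer"] = kmers,
                        _["skipped"] = (double)skipped);
}

// [[Rcpp::export(name = ".hash_indices_cpp")]]
NumericVector hash_indices_cpp(std::string kmer, int k, bool canonical,
                               NumericVector table_sizes) {
    check_k(k);
    if ((int)kmer.size() != k)
        stop("k-mer length %d does not match k = %d", (int)kmer.size(), k);
    uint64_t code = canonical_code(encode_kmer(kmer), k, canonical);
    uint64_t h = mix64(code);
    NumericVector out(table_sizes.size());
    for (R_xlen_t i = 0; i < table_sizes.size(); ++i) {
        uint64_t p = (uint64_t)table_sizes[i];
        out[i] = (double)(h % p);
    }
    return out;
}

// ---- CountMin sketch -----------------------------------------------------

class CountMin {
public:
    int k;
    bool canonical;
    std::vector<uint64_t> sizes;
    std::vector<std::vector<uint8_t>> tables;
    uint64_t n_consumed;         // k-mers added
    uint64_t n_skipped_windows;  // windows dropped for ambiguous bases

    CountMin(int k_, bool canonical_, const std::vector<uint64_t> &sizes_)
        : k(k_), canonical(canonical_), sizes(sizes_),
          n_consumed(0), n_skipped_windows(0) {
        check_k(k);
        for (size_t i = 0; i < sizes.size(); ++i)
            tables.push_back(std::vector<uint8_t>((size_t)sizes[i], 0));
    }

    int add_code(uint64_t code) {
        uint64_t h = mix64(code);
        int mn = 256;
        for (size_t i = 0; i < tables.size(); ++i) {
            uint8_t &cell = tables[i][(size_t)(h % sizes[i])];
            if (cell < 255) ++cell;
            if ((int)cell < mn) mn = (int)cell;
        }
        ++n_consumed;
        return mn;
    }

    int get_code(uint64_t code) const {
        uint64_t h = mix64(code);
        int mn = 256;
        for (size_t i = 0; i < tables.size(); ++i) {
            int v = (int)tables[i][(size_t)(h % sizes[i])];
            if (v < mn) mn = v;
        }
        return mn;
    }
};

static CountMin *cms(SEXP xp) {
    XPtr<CountMin> p(xp);
    return p.get();
}

// [[Rcpp::export(name = ".cms_new")]]
SEXP cms_new(int k, bool canonical, NumericVector table_sizes) {
    std::vector<uint64_t> sizes;
    for (R_xlen_t i = 0; i < table_sizes.size(); ++i)
        sizes.push_back((uint64_t)table_sizes[i]);
    XPtr<CountMin> p(new CountMin(k, canonical, sizes), true);
    return p;
}

// [[Rcpp::export(name = ".cms_add")]]
int cms_add(SEXP xp, std::string kmer) {
    CountMin *s = cms(xp);
    if ((int)kmer.size() != s->k)
        stop("k-mer length %d does not match k = %d", (int)kmer.size(), s->k);
    uint64_t code = canonical_code(encode_kmer(kmer), s->k, s->canonical);
    return s->add_code(code);
}

// [[Rcpp::export(name = ".cms_get")]]
IntegerVector cms_get(SEXP xp, CharacterVector kmers) {
    CountMin *s = cms(xp);
    IntegerVector out(kmers.size());
    for (R_xlen_t j = 0; j < kmers.size(); ++j) {
        std::string km = as<std::string>(kmers[j]);
        if ((int)km.size() != s->k)
            stop("k-mer length %d does not match k = %d", (int)km.size(), s->k);
        out[j] = s->get_code(canonical_code(encode_kmer(km), s->k, s->canonical));
    }
    return out;
}

// [[Rcpp::export(name = ".cms_consume")]]
List cms_consume(SEXP xp, CharacterVector seqs) {
    CountMin *s = cms(xp);
    std::vector<uint64_t> codes;
    double added = 0;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        std::string seq = as<std::string>(seqs[j]);
        uint64_t skipped = scan_kmers(seq, s->k, s->canonical, codes, NULL);
        s->n_skipped_windows += skipped;
        for (size_t i = 0; i < codes.size(); ++i) s->add_code(codes[i]);
        added += (double)codes.size();
    }
    return List::create(_["added"] = added,
                        _["skipped"] = (double)s->n_skipped_windows);
}

// Counts of all valid windows, with their 1-based start positions.
// Query-only: the sketch is not modified.
// [[Rcpp::export(name = ".cms_kmer_counts")]]
List cms_kmer_counts(SEXP xp, std::string seq) {
    CountMin *s = cms(xp);
    std::vector<uint64_t> codes;
    std::vector<int> pos1;
    scan_kmers(seq, s->k, s->canonical, codes, &pos1);
    IntegerVector counts(codes.size());
    for (size_t i = 0; i < codes.size(); ++i)
        counts[(R_xlen_t)i] = s->get_code(codes[i]);
    return List::create(_["pos"] = wrap(pos1), _["count"] = counts);
}

// Median/mean/sd of the count spectrum of one sequence. Median is the
// upper median: element floor(n/2) (0-based) of the sorted count list.
// sd is the population standard deviation (0 for n == 1).
// [[Rcpp::export(name = ".cms_median")]]
NumericVector cms_median(SEXP xp, std::string seq) {
    CountMin *s = cms(xp);
    std::vector<uint64_t> codes;
    scan_kmers(seq, s->k, s->canonical, codes, NULL);
    size_t n = codes.size();
    if (n == 0)
        stop("sequence yields no valid k-mers at k = %d", s->k);
    std::vector<int> counts(n);
    double sum = 0, sumsq = 0;
    for (size_t i = 0; i < n; ++i) {
        counts[i] = s->get_code(codes[i]);
        sum += counts[i];
        sumsq += (double)counts[i] * counts[i];
    }
    std::sort(counts.begin(), counts.end());
    double med = (double)counts[n / 2];
    double mean = sum / (double)n;
    double var = sumsq / (double)n - mean * mean;
    if (var < 0) var = 0;
    return NumericVector::create(med, mean, std::sqrt(var), (double)n);
}

// Histogram over bins 0..255 of the sketch abundance of every distinct
// canonical k-mer occurring in `seqs` (each distinct k-mer counted once,
// tracked with an exact set).
// [[Rcpp::export(name = ".cms_abund_dist")]]
NumericVector cms_abund_dist(SEXP xp, CharacterVector seqs) {
    CountMin *s = cms(xp);
    std::unordered_set<uint64_t> seen;
    std::vector<uint64_t> codes;
    NumericVector hist(256);
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        std::string seq = as<std::string>(seqs[j]);
        scan_kmers(seq, s->k, s->canonical, codes, NULL);
        for (size_t i = 0; i < codes.size(); ++i) {
            if (seen.insert(codes[i]).second)
                hist[s->get_code(codes[i])] += 1;
        }
    }
    return hist;
}

// [[Rcpp::export(name = ".cms_info")]]
List cms_info(SEXP xp) {
    CountMin *s = cms(xp);
    NumericVector sizes(s->sizes.size()), occ(s->sizes.size());
    for (size_t i = 0; i < s->sizes.size(); ++i) {
        sizes[(R_xlen_t)i] = (double)s->sizes[i];
        uint64_t nz = 0;
        for (size_t j = 0; j < s->tables[i].size(); ++j)
            if (s->tables[i][j] != 0) ++nz;
        occ[(R_xlen_t)i] = (double)nz / (double)s->sizes[i];
    }
    return List::create(_["k"] = s->k, _["canonical"] = s->canonical,
                        _["table_sizes"] = sizes, _["occupancy"] = occ,
                        _["n_consumed"] = (double)s->n_consumed,
                        _["n_skipped_windows"] = (double)s->n_skipped_windows);
}

// [[Rcpp::export(name = ".cms_table_bytes")]]
RawVector cms_table_bytes(SEXP xp, int i) {
    CountMin *s = cms(xp);
    const std::vector<uint8_t> &t = s->tables[(size_t)(i - 1)];
    RawVector out((R_xlen_t)t.size());
    std::copy(t.begin(), t.end(), out.begin());
    return out;
}

// [[Rcpp::export(name = ".cms_set_table_bytes")]]
void cms_set_table_bytes(SEXP xp, int i, RawVector bytes, double n_consumed) {
    CountMin *s = cms(xp);
    std::vector<uint8_t> &t = s->tables[(size_t)(i - 1)];
    if ((size_t)bytes.size() != t.size())
        stop("table %d payload has %d bytes, expected %d", i,
             (int)bytes.size(), (int)t.size());
    std::copy(bytes.begin(), bytes.end(), t.begin());
    s->n_consumed = (uint64_t)n_consumed;
}

// ---- Bloom-filter node graph ---------------------------------------------

class NodeGraph {
public:
    int k;
    bool canonical;
    std::vector<uint64_t> sizes;             // sizes in bits
    std::vector<std::vector<uint8_t>> bits;  // packed, ceil(size/8) bytes
    uint64_t n_added;                        // adds that were new

    NodeGraph(int k_, bool canonical_, const std::vector<uint64_t> &sizes_)
        : k(k_), canonical(canonical_), sizes(sizes_), n_added(0) {
        check_k(k);
        for (size_t i = 0; i < sizes.size(); ++i)
            bits.push_back(std::vector<uint8_t>((size_t)((sizes[i] + 7) / 8), 0));
    }

    bool contains_code(uint64_t code) const {
        uint64_t h = mix64(code);
        for (size_t i = 0; i < bits.size(); ++i) {
            uint64_t idx = h % sizes[i];
            if (!(bits[i][(size_t)(idx >> 3)] & (1 << (idx & 7)))) return false;
        }
        return true;
    }

    bool add_code(uint64_t code) {
        uint64_t h = mix64(code);
        bool was_present = true;
        for (size_t i = 0; i < bits.size(); ++i) {
            uint64_t idx = h % sizes[i];
            uint8_t &byte = bits[i][(size_t)(idx >> 3)];
            uint8_t m = (uint8_t)(1 << (idx & 7));
            if (!(byte & m)) { was_present = false; byte |= m; }
        }
        if (!was_present) ++n_added;
        return !was_present;
    }

    // Canonical codes of the (at most 8) k-mers overlapping `code` by k-1.
    void neighbor_codes(uint64_t code, std::vector<uint64_t> &out) const {
        out.clear();
        const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
        uint64_t suff = (code << 2) & mask;       // suffix(k-1) + b
        uint64_t pref = code >> 2;                // b + prefix(k-1)
        for (uint64_t b = 0; b < 4; ++b) {
            out.push_back(canonical_code(suff | b, k, canonical));
            out.push_back(canonical_code(pref | (b << (2 * (k - 1))), k, canonical));
        }
        std::sort(out.begin(), out.end());
        out.erase(std::unique(out.begin(), out.end()), out.end());
    }
};

static NodeGraph *ngp(SEXP xp) {
    XPtr<NodeGraph> p(xp);
    return p.get();
}

// [[Rcpp::export(name = ".ng_new")]]
SEXP ng_new(int k, bool canonical, NumericVector table_sizes) {
    std::vector<uint64_t> sizes;
    for (R_xlen_t i = 0; i < table_sizes.size(); ++i)
        sizes.push_back((uint64_t)table_sizes[i]);
    XPtr<NodeGraph> p(new NodeGraph(k, canonical, sizes), true);
    return p;
}

static uint64_t ng_code(const NodeGraph *g, const std::string &kmer) {
    if ((int)kmer.size() != g->k)
        stop("k-mer length %d does not match k = %d", (int)kmer.size(), g->k);
    return canonical_code(encode_kmer(kmer), g->k, g->canonical);
}

// [[Rcpp::export(name = ".ng_add")]]
bool ng_add(SEXP xp, std::string kmer) {
    NodeGraph *g = ngp(xp);
    return g->add_code(ng_code(g, kmer));
}

// [[Rcpp::export(name = ".ng_consume")]]
List ng_consume(SEXP xp, CharacterVector seqs) {
    NodeGraph *g = ngp(xp);
    std::vector<uint64_t> codes;
    double n_new = 0, skipped = 0;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        std::string seq = as<std::string>(seqs[j]);
        skipped += (double)scan_kmers(seq, g->k, g->canonical, codes, NULL);
        for (size_t i = 0; i < codes.size(); ++i)
            if (g->add_code(codes[i])) n_new += 1;
    }
    return List::create(_["n_new"] = n_new, _["skipped"] = skipped);
}

// [[Rcpp::export(name = ".ng_contains")]]
LogicalVector ng_contains(SEXP xp, CharacterVector kmers) {
    NodeGraph *g = ngp(xp);
    LogicalVector out(kmers.size());
    for (R_xlen_t j = 0; j < kmers.size(); ++j)
        out[j] = g->contains_code(ng_code(g, as<std::string>(kmers[j])));
    return out;
}

// [[Rcpp::export(name = ".ng_neighbors")]]
CharacterVector ng_neighbors(SEXP xp, std::string kmer) {
    NodeGraph *g = ngp(xp);
    std::vector<uint64_t> cand;
    g->neighbor_codes(ng_code(g, kmer), cand);
    std::vector<std::string> hits;
    for (size_t i = 0; i < cand.size(); ++i)
        if (g->contains_code(cand[i])) hits.push_back(decode_kmer(cand[i], g->k));
    return wrap(hits);  // cand already sorted => lexicographic output
}

// Breadth-first traversal from `seed` with lexicographic ordering inside
// each frontier; stops once `max_nodes` k-mers have been reached.
// [[Rcpp::export(name = ".ng_component")]]
List ng_component(SEXP xp, std::string seed, double max_nodes) {
    NodeGraph *g = ngp(xp);
    uint64_t s = ng_code(g, seed);
    if (!g->contains_code(s))
        stop("seed k-mer '%s' is not present in the graph", seed.c_str());
    std::unordered_set<uint64_t> visited;
    visited.insert(s);
    std::vector<uint64_t> frontier(1, s), next, cand;
    bool truncated = false;
    while (!frontier.empty() && !truncated) {
        std::sort(frontier.begin(), frontier.end());
        next.clear();
        for (size_t i = 0; i < frontier.size() && !truncated; ++i) {
            g->neighbor_codes(frontier[i], cand);
            for (size_t j = 0; j < cand.size(); ++j) {
                if (!g->contains_code(cand[j])) continue;
                if (visited.count(cand[j])) continue;
                if ((double)visited.size() >= max_nodes) { truncated = true; break; }
                visited.insert(cand[j]);
                next.push_back(cand[j]);
            }
        }
        frontier.swap(next);
    }
    std::vector<uint64_t> nodes(visited.begin(), visited.end());
    std::sort(nodes.begin(), nodes.end());
    CharacterVector kmers(nodes.size());
    for (size_t i = 0; i < nodes.size(); ++i)
        kmers[(R_xlen_t)i] = decode_kmer(nodes[i], g->k);
    return List::create(_["kmers"] = kmers, _["truncated"] = truncated);
}

// Union-find partitioning: every read links its own k-mers, and k-mers
// adjacent in the graph (by k-1 overlap, membership per the Bloom filter)
// are linked; traversal closure extends through any k-mer the filter
// reports present. Returns one dense partition id per read, numbered in
// first-seen read order; reads without valid k-mers get 0.
// [[Rcpp::export(name = ".ng_partition")]]
IntegerVector ng_partition(SEXP xp, CharacterVector seqs) {
    NodeGraph *g = ngp(xp);
    std::unordered_map<uint64_t, int> id;
    std::vector<int> parent;
    std::vector<uint64_t> worklist;

    // union-find helpers on integer node slots
    struct UF {
        std::vector<int> &p;
        UF(std::vector<int> &p_) : p(p_) {}
        int find(int x) {
            while (p[(size_t)x] != x) { p[(size_t)x] = p[(size_t)p[(size_t)x]]; x = p[(size_t)x]; }
            return x;
        }
        void unite(int a, int b) {
            a = find(a); b = find(b);
            if (a != b) p[(size_t)b] = a;
        }
    } uf(parent);

    std::vector<std::vector<uint64_t>> read_codes(seqs.size());
    std::vector<uint64_t> codes;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        std::string seq = as<std::string>(seqs[j]);
        scan_kmers(seq, g->k, g->canonical, codes, NULL);
        read_codes[(size_t)j] = codes;
        int prev = -1;
        for (size_t i = 0; i < codes.size(); ++i) {
            std::unordered_map<uint64_t, int>::iterator it = id.find(codes[i]);
            int slot;
            if (it == id.end()) {
                slot = (int)parent.size();
                parent.push_back(slot);
                id[codes[i]] = slot;
                worklist.push_back(codes[i]);
            } else slot = it->second;
            if (prev >= 0) uf.unite(prev, slot);
            prev = slot;
        }
    }

    // traversal closure over graph adjacency
    std::vector<uint64_t> cand;
    size_t head = 0;
    while (head < worklist.size()) {
        uint64_t x = worklist[head++];
        int sx = id[x];
        g->neighbor_codes(x, cand);
        for (size_t i = 0; i < cand.size(); ++i) {
            if (!g->contains_code(cand[i])) continue;
            std::unordered_map<uint64_t, int>::iterator it = id.find(cand[i]);
            int sy;
            if (it == id.end()) {
                sy = (int)parent.size();
                parent.push_back(sy);
                id[cand[i]] = sy;
                worklist.push_back(cand[i]);
            } else sy = it->second;
            uf.unite(sx, sy);
        }
    }

    IntegerVector out(seqs.size());
    std::unordered_map<int, int> label;
    int next_label = 1;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) {
        if (read_codes[(size_t)j].empty()) { out[j] = 0; continue; }
        int root = uf.find(id[read_codes[(size_t)j][0]]);
        std::unordered_map<int, int>::iterator it = label.find(root);
        if (it == label.end()) { label[root] = next_label; out[j] = next_label; ++next_label; }
        else out[j] = it->second;
    }
    return out;
}

// [[Rcpp::export(name = ".ng_info")]]
List ng_info(SEXP xp) {
    NodeGraph *g = ngp(xp);
    NumericVector sizes(g->sizes.size()), occ(g->sizes.size());
    for (size_t i = 0; i < g->sizes.size(); ++i) {
        sizes[(R_xlen_t)i] = (double)g->sizes[i];
        uint64_t set_bits = 0;
        for (size_t j = 0; j < g->bits[i].size(); ++j) {
            uint8_t b = g->bits[i][j];
            while (b) { set_bits += b & 1; b >>= 1; }
        }
        occ[(R_xlen_t)i] = (double)set_bits / (double)g->sizes[i];
    }
    return List::create(_["k"] = g->k, _["canonical"] = g->canonical,
                        _["table_sizes"] = sizes, _["occupancy"] = occ,
                        _["n_added"] = (double)g->n_added);
}

// [[Rcpp::export(name = ".ng_table_bytes")]]
RawVector ng_table_bytes(SEXP xp, int i) {
    NodeGraph *g = ngp(xp);
    const std::vector<uint8_t> &t = g->bits[(size_t)(i - 1)];
    RawVector out((R_xlen_t)t.size());
    std::copy(t.begin(), t.end(), out.begin());
    return out;
}

// [[Rcpp::export(name = ".ng_set_table_bytes")]]
void ng_set_table_bytes(SEXP xp, int i, RawVector bytes, double n_added) {
    NodeGraph *g = ngp(xp);
    std::vector<uint8_t> &t = g->bits[(size_t)(i - 1)];
    if ((size_t)bytes.size() != t.size())
        stop("table %d payload has %d bytes, expected %d", i,
             (int)bytes.size(), (int)t.size());
    std::copy(bytes.begin(), bytes.end(), t.begin());
    g->n_added = (uint64_t)n_added;
}
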