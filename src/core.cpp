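// Core engines: VF2 subgraph matching, connected-subgraph enumeration with
// tree hashing, and the varint posting-list codec. All hashing uses fixed
// 64-bit integer arithmetic so results are identical across platforms.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>

using namespace Rcpp;

static const uint64_t MASK36 = (1ULL << 36) - 1;

// splitmix64 finalizer: the fixed public avalanche mix behind every hash here
static inline uint64_t mix64(uint64_t x) {
    x += 0x9E3779B97F4A7C15ULL;
    x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
    x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
    return x ^ (x >> 31);
}

static inline uint64_t comb(uint64_t a, uint64_t b) {
    return mix64(a ^ (b * 0xC2B2AE3D27D4EB4FULL));
}

// atom label: element, formal charge and aromatic flag; isotopes and hydrogen
// counts are deliberately excluded (the matcher compares them only
// conditionally, so putting them in fingerprint labels would break the
// zero-false-negative screening guarantee)
static inline uint64_t atomLabel(int elem, int charge, bool arom) {
    return mix64((static_cast<uint64_t>(static_cast<uint32_t>(elem)) << 20) ^
                 (static_cast<uint64_t>(static_cast<uint32_t>(charge + 128)) << 8) ^
                 (arom ? 1ULL : 0ULL) ^ (0xA5A5ULL << 40));
}

static inline uint64_t bondLabel(int order, bool arom) {
    return arom ? 0x1717ULL : static_cast<uint64_t>(order);
}

// ---------------------------------------------------------------------------
// VF2-style matcher
// ---------------------------------------------------------------------------

struct MolView {
    int na;
    const int *elem, *chg, *iso, *h;
    const int *arom, *hexp;                 // logicals as int
    std::vector<std::vector<int>> adj;      // neighbour atom (0-based)
    std::vector<std::vector<int>> adjOrder; // parallel: bond order
    std::vector<std::vector<int>> adjArom;  // parallel: bond aromatic flag
};

static MolView makeView(const IntegerVector& elem, const IntegerVector& chg,
                        const IntegerVector& iso, const LogicalVector& arom,
                        const IntegerVector& h, const LogicalVector& hexp,
                        const IntegerVector& bf, const IntegerVector& bt,
                        const IntegerVector& bo, const LogicalVector& ba) {
    MolView m;
    m.na = elem.size();
    m.elem = elem.begin(); m.chg = chg.begin(); m.iso = iso.begin();
    m.h = h.begin(); m.arom = arom.begin(); m.hexp = hexp.begin();
    m.adj.assign(m.na, {});
    m.adjOrder.assign(m.na, {});
    m.adjArom.assign(m.na, {});
    for (int i = 0; i < bf.size(); ++i) {
        int a = bf[i], b = bt[i];
        m.adj[a].push_back(b); m.adjOrder[a].push_back(bo[i]); m.adjArom[a].push_back(ba[i]);
        m.adj[b].push_back(a); m.adjOrder[b].push_back(bo[i]); m.adjArom[b].push_back(ba[i]);
    }
    return m;
}

struct Vf2 {
    const MolView *q, *t;
    bool chargeSensitive, isotopeSensitive, findAll;
    double limit;          // 0 = unlimited
    double states = 0, found = 0;
    bool exceeded = false;
    std::vector<int> order, parent;  // parent: query atom already ordered, or -1
    std::vector<int> qmap, tused;

    bool atomCompat(int qa, int ta) const {
        if (q->elem[qa] != t->elem[ta]) return false;
        if (chargeSensitive && q->chg[qa] != t->chg[ta]) return false;
        if (isotopeSensitive && q->iso[qa] >= 0 && q->iso[qa] != t->iso[ta]) return false;
        if ((q->arom[qa] != 0) != (t->arom[ta] != 0)) return false;
        if (q->hexp[qa] && t->h[ta] < q->h[qa]) return false;
        return true;
    }

    // aromatic query bond needs an aromatic target bond; otherwise equal order
    bool bondCompat(int qArom, int qOrder, int tArom, int tOrder) const {
        if (qArom) return tArom != 0;
        return tArom == 0 && qOrder == tOrder;
    }

    void buildOrder() {
        int n = q->na;
        std::vector<char> used(n, 0);
        order.reserve(n); parent.reserve(n);
        for (int k = 0; k < n; ++k) {
            int best = -1; bool bestAdj = false; size_t bestDeg = 0;
            for (int a = 0; a < n; ++a) {
                if (used[a]) continue;
                bool adjacent = false;
                for (int nb : q->adj[a]) if (used[nb]) { adjacent = true; break; }
                if (best < 0 || (adjacent && !bestAdj) ||
                    (adjacent == bestAdj && q->adj[a].size() > bestDeg)) {
                    best = a; bestAdj = adjacent; bestDeg = q->adj[a].size();
                }
            }
            int par = -1;
            for (int nb : q->adj[best]) if (used[nb]) { par = nb; break; }
            order.push_back(best); parent.push_back(par);
            used[best] = 1;
        }
    }

    bool feasible(int qa, int ta) {
        if (!atomCompat(qa, ta)) return false;
        for (size_t j = 0; j < q->adj[qa].size(); ++j) {
            int nb = q->adj[qa][j];
            if (qmap[nb] < 0) continue;
            int img = qmap[nb];
            bool ok = false;
            for (size_t i = 0; i < t->adj[ta].size(); ++i) {
                if (t->adj[ta][i] == img &&
                    bondCompat(q->adjArom[qa][j], q->adjOrder[qa][j],
                               t->adjArom[ta][i], t->adjOrder[ta][i])) { ok = true; break; }
            }
            if (!ok) return false;
        }
        return true;
    }

    void search(int k) {
        if (exceeded) return;
        if (k == (int)order.size()) { found += 1; return; }
        int qa = order[k];
        if (parent[k] >= 0) {
            int img = qmap[parent[k]];
            for (int ta : t->adj[img]) {
                if (tryAssign(qa, ta, k)) return;
            }
        } else {
            for (int ta = 0; ta < t->na; ++ta) {
                if (tryAssign(qa, ta, k)) return;
            }
        }
    }

    // returns true when the whole search should stop
    bool tryAssign(int qa, int ta, int k) {
        if (exceeded) return true;
        if (tused[ta]) return false;
        states += 1;
        if (limit > 0 && states > limit) { exceeded = true; return true; }
        if (!feasible(qa, ta)) return false;
        qmap[qa] = ta; tused[ta] = 1;
        search(k + 1);
        qmap[qa] = -1; tused[ta] = 0;
        return (!findAll && found > 0);
    }

    void run() {
        buildOrder();
        qmap.assign(q->na, -1);
        tused.assign(t->na, 0);
        if (q->na == 0) { found = 1; return; }  // empty query embeds trivially
        if (q->na > t->na) return;
        search(0);
    }
};

// [[Rcpp::export]]
List cpp_match(IntegerVector qelem, IntegerVector qchg, IntegerVector qiso,
               LogicalVector qarom, IntegerVector qh, LogicalVector qhexp,
               IntegerVector qbf, IntegerVector qbt, IntegerVector qbo, LogicalVector qba,
               IntegerVector telem, IntegerVector tchg, IntegerVector tiso,
               LogicalVector tarom, IntegerVector th, LogicalVector thexp,
               IntegerVector tbf, IntegerVector tbt, IntegerVector tbo, LogicalVector tba,
               bool chargeSensitive, bool isotopeSensitive,
               bool findAll, double limit) {
    MolView q = makeView(qelem, qchg, qiso, qarom, qh, qhexp, qbf, qbt, qbo, qba);
    MolView t = makeView(telem, tchg, tiso, tarom, th, thexp, tbf, tbt, tbo, tba);
    Vf2 vf;
    vf.q = &q; vf.t = &t;
    vf.chargeSensitive = chargeSensitive; vf.isotopeSensitive = isotopeSensitive;
    vf.findAll = findAll; vf.limit = limit;
    vf.run();
    return List::create(_["count"] = vf.found,
                        _["exceeded"] = vf.exceeded,
                        _["states"] = vf.states);
}

// ---------------------------------------------------------------------------
// Tree hashing of connected subgraphs with at most one ring
// ---------------------------------------------------------------------------

struct SubgraphHasher {
    int na;                              // atoms in the whole molecule
    const int *elem, *chg;
    const int *arom;
    const int *bf, *bt, *bo;
    const int *ba;

    // scratch, sized to the molecule once
    std::vector<int> localId;            // atom -> local id or -1
    std::vector<int> atomsBuf;

    SubgraphHasher(int na_, const int* elem_, const int* chg_, const int* arom_,
                   const int* bf_, const int* bt_, const int* bo_, const int* ba_)
        : na(na_), elem(elem_), chg(chg_), arom(arom_),
          bf(bf_), bt(bt_), bo(bo_), ba(ba_), localId(na_, -1) {}

    // bonds: 0-based bond indices; returns 64-bit structural hash.
    // status: 0 ok, 1 disconnected, 2 more than one ring
    uint64_t hash(const std::vector<int>& bonds, int& status) {
        atomsBuf.clear();
        for (int b : bonds) {
            for (int a : {bf[b], bt[b]}) {
                if (localId[a] < 0) { localId[a] = (int)atomsBuf.size(); atomsBuf.push_back(a); }
            }
        }
        int nA = (int)atomsBuf.size(), nB = (int)bonds.size();
        std::vector<std::vector<std::pair<int,int>>> adj(nA); // (local nb, bond)
        for (int b : bonds) {
            int u = localId[bf[b]], v = localId[bt[b]];
            adj[u].push_back({v, b});
            adj[v].push_back({u, b});
        }
        // connectivity check
        std::vector<char> seen(nA, 0);
        std::vector<int> stack{0};
        seen[0] = 1; int nSeen = 1;
        while (!stack.empty()) {
            int u = stack.back(); stack.pop_back();
            for (auto& pr : adj[u]) if (!seen[pr.first]) { seen[pr.first] = 1; ++nSeen; stack.push_back(pr.first); }
        }
        for (int a : atomsBuf) localId[a] = -1;  // reset scratch
        if (nSeen != nA) { status = 1; return 0; }
        int rings = nB - nA + 1;
        if (rings > 1) { status = 2; return 0; }
        status = 0;

        std::vector<uint64_t> h(nA);
        std::vector<int> deg(nA);
        std::vector<char> alive(nA, 1);
        for (int i = 0; i < nA; ++i) {
            int a = atomsBuf[i];
            h[i] = atomLabel(elem[a], chg[a], arom[a] != 0);
            deg[i] = (int)adj[i].size();
        }
        int nAlive = nA;
        std::vector<int> leaves;
        std::vector<std::vector<uint64_t>> contrib(nA);

        auto stripRound = [&]() {
            leaves.clear();
            for (int i = 0; i < nA; ++i) if (alive[i] && deg[i] == 1) leaves.push_back(i);
            for (int l : leaves) {
                for (auto& pr : adj[l]) {
                    if (alive[pr.first] && deg[pr.first] > 0) {
                        // pr.first may itself be a leaf this round; contributions
                        // still fold symmetrically because both fold into each
                        // other only when nAlive would drop below the guard
                        contrib[pr.first].push_back(comb(h[l], bondLabel(bo[pr.second], ba[pr.second] != 0)));
                    }
                }
            }
            for (int l : leaves) { alive[l] = 0; --nAlive; }
            for (int i = 0; i < nA; ++i) {
                if (!contrib[i].empty()) {
                    if (alive[i]) {
                        std::sort(contrib[i].begin(), contrib[i].end());
                        for (uint64_t c : contrib[i]) h[i] = comb(h[i], c);
                    }
                    contrib[i].clear();
                }
                if (alive[i]) {
                    int d = 0;
                    for (auto& pr : adj[i]) if (alive[pr.first]) ++d;
                    deg[i] = d;
                }
            }
        };

        const uint64_t TAG1 = 0x51D3A7B2ULL, TAG2 = 0x72E5C9F1ULL;
        if (rings == 0) {
            while (nAlive > 2) stripRound();
            if (nAlive == 1) {
                for (int i = 0; i < nA; ++i) if (alive[i]) return comb(TAG1, h[i]);
            }
            // two centres joined by one remaining bond: symmetric fold
            int c1 = -1, c2 = -1;
            for (int i = 0; i < nA; ++i) if (alive[i]) { if (c1 < 0) c1 = i; else c2 = i; }
            uint64_t lbl = 0;
            for (auto& pr : adj[c1]) if (pr.first == c2) lbl = bondLabel(bo[pr.second], ba[pr.second] != 0);
            uint64_t lo = std::min(h[c1], h[c2]), hi = std::max(h[c1], h[c2]);
            return comb(comb(comb(TAG2, lbl), lo), hi);
        }

        // exactly one ring: strip leaves fully, then canonical cyclic hash
        bool any = true;
        while (any) {
            any = false;
            for (int i = 0; i < nA; ++i) if (alive[i] && deg[i] == 1) { any = true; break; }
            if (any) stripRound();
        }
        std::vector<int> cyc;      // local atom ids around the ring
        std::vector<uint64_t> lbl; // bond label cyc[i] -- cyc[i+1]
        int start = -1;
        for (int i = 0; i < nA; ++i) if (alive[i]) { start = i; break; }
        int prev = -1, cur = start;
        do {
            cyc.push_back(cur);
            int nxt = -1; uint64_t l = 0;
            for (auto& pr : adj[cur]) {
                if (alive[pr.first] && pr.first != prev) { nxt = pr.first; l = bondLabel(bo[pr.second], ba[pr.second] != 0); break; }
            }
            if (nxt == -1) { // ring of size 2 cannot occur (no parallel bonds)
                for (auto& pr : adj[cur]) if (alive[pr.first]) { nxt = pr.first; l = bondLabel(bo[pr.second], ba[pr.second] != 0); }
            }
            lbl.push_back(l);
            prev = cur; cur = nxt;
        } while (cur != start);
        int k = (int)cyc.size();
        // lexically minimal rotation over both directions on (atom hash, bond label)
        std::vector<std::pair<uint64_t,uint64_t>> best, cand;
        for (int dir = 0; dir < 2; ++dir) {
            for (int s = 0; s < k; ++s) {
                cand.clear();
                for (int j = 0; j < k; ++j) {
                    int i = dir == 0 ? (s + j) % k : ((s - j) % k + k) % k;
                    // bond following atom i in traversal direction
                    int bi = dir == 0 ? i : (((i - 1) % k) + k) % k;
                    cand.push_back({h[cyc[i]], lbl[bi]});
                }
                if (best.empty() || cand < best) best = cand;
            }
        }
        uint64_t r = 0xCAFEBABE1234ULL;
        for (auto& pr : best) { r = comb(r, pr.first); r = comb(r, pr.second); }
        return r;
    }
};

static inline uint64_t fold36(uint64_t h, int kindCode) {
    return mix64(h ^ (static_cast<uint64_t>(kindCode) * 0x9E3779B97F4A7C15ULL)) & MASK36;
}

// [[Rcpp::export]]
NumericVector cpp_tree_hash36(int nAtoms, IntegerVector elem, IntegerVector chg,
                              LogicalVector arom,
                              IntegerVector bf, IntegerVector bt,
                              IntegerVector bo, LogicalVector ba,
                              IntegerVector subgraphBonds, int kindCode) {
    SubgraphHasher hs(nAtoms, elem.begin(), chg.begin(), arom.begin(),
                      bf.begin(), bt.begin(), bo.begin(), ba.begin());
    std::vector<int> bonds(subgraphBonds.begin(), subgraphBonds.end());
    int status = 0;
    uint64_t h = hs.hash(bonds, status);
    if (status == 1) stop("subgraph is disconnected");
    if (status == 2) stop("subgraph has more than one ring");
    return NumericVector::create(static_cast<double>(fold36(h, kindCode)));
}

// [[Rcpp::export]]
NumericVector cpp_atom_type_hash(IntegerVector elem, IntegerVector chg,
                                 LogicalVector arom) {
    int n = elem.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i)
        out[i] = static_cast<double>(fold36(atomLabel(elem[i], chg[i], arom[i] != 0), 1));
    return out;
}

// FeatureId.value: base 36-bit hash (already kind-mixed) folded with the
// multiplicity tier through the same avalanche mix
// [[Rcpp::export]]
NumericVector cpp_feature_id(NumericVector base36, IntegerVector tier) {
    int n = base36.size();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        uint64_t b = static_cast<uint64_t>(base36[i]);
        uint64_t t = static_cast<uint64_t>(tier[i]);
        if (t == 1) out[i] = static_cast<double>(b);  // tier-1 id is the base hash
        else out[i] = static_cast<double>(mix64(b ^ (t * 0xD6E8FEB86659FD93ULL)) & MASK36);
    }
    return out;
}

// ---------------------------------------------------------------------------
// ESU enumeration of connected bond subgraphs with <= 1 ring
// ---------------------------------------------------------------------------

struct Esu {
    int na, nb, maxBonds;
    std::vector<std::vector<int>> bondAdj;   // bonds sharing an atom
    const int *bf, *bt;
    SubgraphHasher* hasher;

    std::vector<char> inS, adjS;             // over bonds
    std::vector<int> atomUse;                // per atom: #subgraph bonds touching it
    std::vector<int> S;
    int rings = 0;

    std::vector<double> outHash;
    std::vector<std::vector<int>> outBonds;

    void emit() {
        int status = 0;
        uint64_t h = hasher->hash(S, status);
        // enumeration guarantees connected and <=1 ring
        outHash.push_back(static_cast<double>(fold36(h, 3)));
        outBonds.push_back(S);
    }

    void extend(std::vector<int>& ext, int vmin) {
        emit();
        if ((int)S.size() == maxBonds) return;
        while (!ext.empty()) {
            int w = ext.back(); ext.pop_back();
            int a = bf[w], b = bt[w];
            int newRings = rings + (atomUse[a] > 0 && atomUse[b] > 0 ? 1 : 0);
            if (newRings > 1) continue;
            // build extension for the recursive call
            std::vector<int> ext2 = ext;
            for (int u : bondAdj[w]) {
                if (u > vmin && !inS[u] && !adjS[u]) ext2.push_back(u);
            }
            // apply w
            std::vector<int> touched;
            inS[w] = 1; S.push_back(w);
            ++atomUse[a]; ++atomUse[b];
            int savedRings = rings; rings = newRings;
            for (int u : bondAdj[w]) if (!adjS[u]) { adjS[u] = 1; touched.push_back(u); }
            extend(ext2, vmin);
            // undo
            for (int u : touched) adjS[u] = 0;
            rings = savedRings;
            --atomUse[a]; --atomUse[b];
            S.pop_back(); inS[w] = 0;
        }
    }

    void run() {
        inS.assign(nb, 0); adjS.assign(nb, 0);
        atomUse.assign(na, 0);
        for (int v = 0; v < nb; ++v) {
            std::vector<int> ext;
            adjS[v] = 1;
            std::vector<int> touched{v};
            for (int u : bondAdj[v]) {
                if (u > v) ext.push_back(u);
                if (!adjS[u]) { adjS[u] = 1; touched.push_back(u); }
            }
            inS[v] = 1; S.assign(1, v);
            ++atomUse[bf[v]]; ++atomUse[bt[v]];
            rings = 0;
            extend(ext, v);
            --atomUse[bf[v]]; --atomUse[bt[v]];
            S.clear(); inS[v] = 0;
            for (int u : touched) adjS[u] = 0;
        }
    }
};

// [[Rcpp::export]]
List cpp_subgraph_features(int nAtoms, IntegerVector elem, IntegerVector chg,
                           LogicalVector arom,
                           IntegerVector bf, IntegerVector bt,
                           IntegerVector bo, LogicalVector ba, int maxBonds) {
    SubgraphHasher hs(nAtoms, elem.begin(), chg.begin(), arom.begin(),
                      bf.begin(), bt.begin(), bo.begin(), ba.begin());
    Esu esu;
    esu.na = nAtoms; esu.nb = bf.size(); esu.maxBonds = maxBonds;
    esu.bf = bf.begin(); esu.bt = bt.begin();
    esu.hasher = &hs;
    // bond adjacency via shared atoms
    std::vector<std::vector<int>> atomBonds(nAtoms);
    for (int b = 0; b < esu.nb; ++b) { atomBonds[bf[b]].push_back(b); atomBonds[bt[b]].push_back(b); }
    esu.bondAdj.assign(esu.nb, {});
    for (int a = 0; a < nAtoms; ++a) {
        for (int i = 0; i < (int)atomBonds[a].size(); ++i)
            for (int j = 0; j < (int)atomBonds[a].size(); ++j)
                if (i != j) esu.bondAdj[atomBonds[a][i]].push_back(atomBonds[a][j]);
    }
    for (auto& v : esu.bondAdj) {
        std::sort(v.begin(), v.end());
        v.erase(std::unique(v.begin(), v.end()), v.end());
    }
    if (esu.nb > 0 && maxBonds >= 1) esu.run();

    int n = (int)esu.outHash.size();
    NumericVector hash(n);
    List bonds(n);
    for (int i = 0; i < n; ++i) {
        hash[i] = esu.outHash[i];
        IntegerVector bb(esu.outBonds[i].size());
        for (size_t j = 0; j < esu.outBonds[i].size(); ++j) bb[j] = esu.outBonds[i][j] + 1;
        bonds[i] = bb;
    }
    return List::create(_["hash"] = hash, _["bonds"] = bonds);
}

// ---------------------------------------------------------------------------
// varint delta codec for posting lists (LEB128 on deltas)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
RawVector cpp_varint_encode(IntegerVector sorted) {
    std::vector<uint8_t> out;
    uint32_t prev = 0;
    for (int i = 0; i < sorted.size(); ++i) {
        uint32_t x = static_cast<uint32_t>(sorted[i]);
        uint32_t d = (i == 0) ? x : x - prev;
        prev = x;
        while (d >= 0x80) { out.push_back((d & 0x7F) | 0x80); d >>= 7; }
        out.push_back(d);
    }
    RawVector r(out.size());
    std::copy(out.begin(), out.end(), r.begin());
    return r;
}

// [[Rcpp::export]]
IntegerVector cpp_varint_decode(RawVector raw) {
    std::vector<int> out;
    uint32_t prev = 0;
    size_t i = 0, n = raw.size();
    while (i < n) {
        uint32_t d = 0; int shift = 0;
        bool done = false;
        while (i < n) {
            uint8_t b = raw[i++];
            d |= static_cast<uint32_t>(b & 0x7F) << shift;
            if (!(b & 0x80)) { done = true; break; }
            shift += 7;
        }
        if (!done) stop("truncated varint stream");
        prev = out.empty() ? d : prev + d;
        out.push_back(static_cast<int>(prev));
    }
    return wrap(out);
}
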