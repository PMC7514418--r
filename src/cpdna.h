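// Core engine: context models, substitution-tolerant context models,
// stochastic repeat models, class mixing, competitive class selection,
// integer range coder and the container codec.
//
// Everything here must behave identically during compression and
// decompression: per-step update order is fixed, all randomness flows
// through the portable RNG below, and the coder only ever sees integer
// frequency tables (total 2^16), so bitstreams are platform-exact.

#ifndef CPDNA_H
#define CPDNA_H

#include <cstdint>
#include <cstring>
#include <cstdlib>
#include <cmath>
#include <vector>
#include <string>
#include <unordered_map>
#include <stdexcept>
#include <algorithm>

namespace cpdna {

// ---------------------------------------------------------------------------
// Portable RNG: xorshift64* seeded through one splitmix64 round.
// State transition (documented contract, serialized seed in the header):
//   s ^= s >> 12; s ^= s << 25; s ^= s >> 27; output = s * 0x2545F4914F6CDD1D
// ---------------------------------------------------------------------------
struct Rng {
    uint64_t s;
    explicit Rng(uint64_t seed = 0) { reseed(seed); }
    void reseed(uint64_t seed) {
        uint64_t z = seed + 0x9E3779B97F4A7C15ULL;
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        s = z ^ (z >> 31);
        if (s == 0) s = 0x9E3779B97F4A7C15ULL;
    }
    uint64_t next() {
        uint64_t x = s;
        x ^= x >> 12; x ^= x << 25; x ^= x >> 27;
        s = x;
        return x * 0x2545F4914F6CDD1DULL;
    }
    // uniform draw in [0, n), rejection sampled so there is no modulo bias
    uint64_t below(uint64_t n) {
        if (n <= 1) return 0;
        uint64_t lim = UINT64_MAX - (UINT64_MAX % n);
        uint64_t v;
        do { v = next(); } while (v >= lim);
        return v % n;
    }
    // 53-bit uniform double in [0,1)
    double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

// ---------------------------------------------------------------------------
// Bases: A=0, C=1, G=2, T=3; complement(x) = 3 - x.
// ---------------------------------------------------------------------------
inline int base_code(char c) {
    switch (c) {
        case 'A': case 'a': return 0;
        case 'C': case 'c': return 1;
        case 'G': case 'g': return 2;
        case 'T': case 't': return 3;
    }
    return -1;
}
inline char base_char(int b) { return "ACGT"[b & 3]; }
inline int comp(int b) { return 3 - b; }

// 2-bit packed sequence; base j sits in bits [2*(j%4), 2*(j%4)+1] of byte j/4
struct PackedSeq {
    std::vector<uint8_t> data;
    size_t n = 0;
    void reserve(size_t m) { data.reserve((m + 3) / 4); }
    void push(int b) {
        size_t byte = n >> 2;
        if (byte >= data.size()) data.push_back(0);
        data[byte] |= (uint8_t)((b & 3) << ((n & 3) * 2));
        ++n;
    }
    int get(size_t i) const { return (data[i >> 2] >> ((i & 3) * 2)) & 3; }
    void clear() { data.clear(); n = 0; }
};

inline PackedSeq pack_string(const std::string& s) {
    PackedSeq p;
    p.reserve(s.size());
    for (char c : s) {
        int b = base_code(c);
        if (b < 0) throw std::runtime_error(std::string("non-ACGT character '") + c + "' in sequence");
        p.push(b);
    }
    return p;
}
inline std::string unpack_string(const PackedSeq& p) {
    std::string s(p.n, 'A');
    for (size_t i = 0; i < p.n; ++i) s[i] = base_char(p.get(i));
    return s;
}

// ---------------------------------------------------------------------------
// Laplace-style estimator: P(s) = (c_s + alpha) / (sum_c + 4*alpha).
// alpha -> inf gives the uniform distribution, alpha -> 0 the frequency one.
// ---------------------------------------------------------------------------
inline void estimate4(const uint32_t c[4], double alpha, double out[4]) {
    double tot = (double)c[0] + c[1] + c[2] + c[3] + 4.0 * alpha;
    for (int j = 0; j < 4; ++j) out[j] = ((double)c[j] + alpha) / tot;
}

// saturating counter update: halve all four before incrementing past cmax
inline void bump4(uint8_t c[4], int sym, int cmax) {
    if ((int)c[sym] + 1 > cmax) for (int j = 0; j < 4; ++j) c[j] >>= 1;
    c[sym]++;
}

// ---------------------------------------------------------------------------
// Counter storage: dense table (4^k contexts x 4 counters) or a bounded
// cache-hash (2^hash_bits buckets, at most max_coll entries each, round-robin
// FIFO replacement so only the latest contexts per bucket are retained).
// ---------------------------------------------------------------------------
struct CounterStore {
    bool dense = true;
    int k = 0, counter_max = 255;
    // dense storage (calloc so untouched pages stay cheap)
    uint8_t* table = nullptr;
    size_t tsize = 0;
    // cache-hash storage
    int hash_bits = 16, max_coll = 4;
    struct Slot { uint64_t key; uint8_t c[4]; uint8_t used; uint8_t pad[3]; };
    std::vector<Slot> slots;
    std::vector<uint8_t> heads; // per-bucket FIFO insertion cursor

    CounterStore() = default;
    CounterStore(const CounterStore&) = delete;
    CounterStore& operator=(const CounterStore&) = delete;
    CounterStore(CounterStore&& o) noexcept { move_from(o); }
    CounterStore& operator=(CounterStore&& o) noexcept {
        release(); move_from(o); return *this;
    }
    ~CounterStore() { release(); }
    void move_from(CounterStore& o) {
        dense = o.dense; k = o.k; counter_max = o.counter_max;
        table = o.table; tsize = o.tsize; o.table = nullptr; o.tsize = 0;
        hash_bits = o.hash_bits; max_coll = o.max_coll;
        slots = std::move(o.slots); heads = std::move(o.heads);
    }
    void release() { if (table) { std::free(table); table = nullptr; } }

    void init(int k_, bool dense_, int hash_bits_, int max_coll_, int cmax) {
        release();
        k = k_; dense = dense_; counter_max = cmax;
        if (dense) {
            if (k > 12) throw std::runtime_error("dense counter table limited to k <= 12");
            tsize = ((size_t)1) << (2 * (k + 1)); // 4^(k+1) counter slots
            table = (uint8_t*)std::calloc(tsize, 1);
            if (!table) throw std::runtime_error("counter table allocation failed");
        } else {
            hash_bits = hash_bits_; max_coll = max_coll_;
            slots.assign(((size_t)1 << hash_bits) * (size_t)max_coll, Slot{0, {0,0,0,0}, 0, {0,0,0}});
            heads.assign((size_t)1 << hash_bits, 0);
        }
    }

    static uint64_t mix64(uint64_t x) {
        x ^= x >> 33; x *= 0xFF51AFD7ED558CCDULL;
        x ^= x >> 33; x *= 0xC4CEB9FE1A85EC53ULL;
        x ^= x >> 33;
        return x;
    }

    // read-only lookup; unseen/evicted contexts read as all-zero counts
    void get(uint64_t ctx, uint32_t out[4]) const {
        if (dense) {
            const uint8_t* p = table + ctx * 4;
            out[0] = p[0]; out[1] = p[1]; out[2] = p[2]; out[3] = p[3];
            return;
        }
        size_t b = mix64(ctx) & (((size_t)1 << hash_bits) - 1);
        const Slot* s = &slots[b * max_coll];
        for (int j = 0; j < max_coll; ++j)
            if (s[j].used && s[j].key == ctx) {
                out[0] = s[j].c[0]; out[1] = s[j].c[1]; out[2] = s[j].c[2]; out[3] = s[j].c[3];
                return;
            }
        out[0] = out[1] = out[2] = out[3] = 0;
    }

    void bump(uint64_t ctx, int sym) {
        if (dense) { bump4(table + ctx * 4, sym, counter_max); return; }
        size_t b = mix64(ctx) & (((size_t)1 << hash_bits) - 1);
        Slot* s = &slots[b * max_coll];
        for (int j = 0; j < max_coll; ++j)
            if (s[j].used && s[j].key == ctx) { bump4(s[j].c, sym, counter_max); return; }
        // miss: claim the cursor slot (free slots are taken in order, then the
        // cursor wraps and the oldest entry is evicted)
        uint8_t& h = heads[b];
        Slot& t = s[h];
        t.key = ctx; t.used = 1;
        t.c[0] = t.c[1] = t.c[2] = t.c[3] = 0;
        bump4(t.c, sym, counter_max);
        h = (uint8_t)((h + 1) % max_coll);
    }

    uint64_t digest() const {
        uint64_t h = 0xCBF29CE484222325ULL;
        auto eat = [&h](const uint8_t* p, size_t m) {
            for (size_t i = 0; i < m; ++i) { h ^= p[i]; h *= 0x100000001B3ULL; }
        };
        if (dense) eat(table, tsize);
        else {
            eat(reinterpret_cast<const uint8_t*>(slots.data()), slots.size() * sizeof(Slot));
            eat(heads.data(), heads.size());
        }
        return h;
    }
};

// ---------------------------------------------------------------------------
// Finite context model of order k with optional inverted-repeat sub-program.
// ir_mode: 0 forward only; 1 ir_only (predicts and trains on reverse-
// complement events only); 2 both (trains both event kinds, predicts forward).
// ---------------------------------------------------------------------------
enum IrMode { IR_FORWARD = 0, IR_ONLY = 1, IR_BOTH = 2 };

struct CMParams {
    int k = 2;
    uint32_t alpha_num = 1, alpha_den = 1;
    int gamma_pm = 800;          // forgetting factor, permille
    int ir_mode = IR_FORWARD;
    bool dense = true;           // dense table vs cache-hash
    int hash_bits = 16, max_coll = 4, counter_max = 255;
    bool has_stcm = false;
    int stcm_max_subs = 5, stcm_t = 8, stcm_l = 32;
    double alpha() const { return (double)alpha_num / (double)alpha_den; }
    double gamma() const { return gamma_pm / 1000.0; }
};

struct ContextModel {
    CMParams p;
    CounterStore store;
    uint64_t fctx = 0, irctx = 0, mask = 0;

    void init(const CMParams& par) {
        p = par;
        if (p.k < 1 || p.k > 24) throw std::runtime_error("context order k must be in 1..24");
        if (p.alpha_num == 0 || p.alpha_den == 0) throw std::runtime_error("alpha must be positive");
        if (p.gamma_pm < 0 || p.gamma_pm > 999) throw std::runtime_error("gamma must be in [0,1)");
        store.init(p.k, p.dense, p.hash_bits, p.max_coll, p.counter_max);
        mask = (p.k >= 32) ? ~0ULL : ((1ULL << (2 * p.k)) - 1);
        fctx = irctx = 0;
    }

    // prediction for position i; prev_k = x_{i-k} (or -1 while unavailable)
    void predict(double out[4], int prev_k) const {
        double a = p.alpha();
        if (p.ir_mode == IR_ONLY) {
            if (prev_k < 0) { out[0] = out[1] = out[2] = out[3] = 0.25; return; }
            // score candidate s by the count the matching IR event would have
            // trained: context RC(x_{i-k+1..i-1} s), symbol complement(x_{i-k})
            uint32_t sc[4];
            uint64_t base = irctx >> 2;
            int shift = 2 * (p.k - 1);
            for (int s4 = 0; s4 < 4; ++s4) {
                uint64_t ctx = base | ((uint64_t)comp(s4) << shift);
                uint32_t c[4];
                store.get(ctx, c);
                sc[s4] = c[comp(prev_k)];
            }
            estimate4(sc, a, out);
            return;
        }
        uint32_t c[4];
        store.get(fctx, c);
        estimate4(c, a, out);
    }

    // after the true symbol of position i is known; prev_k = x_{i-k} or -1.
    // The forward event always trains; IR modes additionally train the
    // reverse-complement image, which is what the RC query can hit later.
    void update(int sym, int prev_k) {
        store.bump(fctx, sym);
        fctx = ((fctx << 2) | (uint64_t)sym) & mask;
        irctx = (irctx >> 2) | ((uint64_t)comp(sym) << (2 * (p.k - 1)));
        if (p.ir_mode != IR_FORWARD && prev_k >= 0)
            store.bump(irctx, comp(prev_k)); // IR event of window x_{i-k..i}
    }
};

// ---------------------------------------------------------------------------
// Substitution-tolerant context model. Shares the host CM's counter store
// (single writer: only the host updates counters). Keeps a private "edited"
// context in which mispredicted symbols are replaced by the model's own most
// probable symbol, up to a substitution budget; a hit/fail ring of length l
// gates the model on/off against fail threshold t.
// ---------------------------------------------------------------------------
struct Stcm {
    int k = 0, max_subs = 5, t = 8, l = 32;
    uint64_t ectx = 0, mask = 0;
    int subs_left = 5;
    std::vector<uint8_t> hist; // 1 = fail
    int hpos = 0, hcount = 0, nfails = 0;
    int last_top = 0;

    void init(int k_, int max_subs_, int t_, int l_) {
        k = k_; max_subs = max_subs_; t = t_; l = l_;
        if (max_subs < 1) throw std::runtime_error("stcm max_subs must be >= 1");
        if (t <= 0 || t > l) throw std::runtime_error("stcm needs 0 < t <= l");
        mask = (1ULL << (2 * k)) - 1;
        ectx = 0; subs_left = max_subs;
        hist.assign(l, 0); hpos = hcount = nfails = 0;
        last_top = 0;
    }
    bool active() const { return nfails <= t; }

    void predict(const CounterStore& store, double alpha, double out[4]) {
        uint32_t c[4];
        store.get(ectx, c);
        estimate4(c, alpha, out);
        // the gating always tracks the underlying context prediction --
        // otherwise a switched-off model could never earn its way back on
        last_top = 0;
        for (int j = 1; j < 4; ++j) if (out[j] > out[last_top]) last_top = j; // ties -> lowest code
        if (!active()) out[0] = out[1] = out[2] = out[3] = 0.25;
    }

    // host_ctx = host's true last-k context after the current symbol was pushed
    void update(int true_sym, uint64_t host_ctx) {
        bool hit = (last_top == true_sym);
        if (hcount == l) nfails -= hist[hpos]; else ++hcount;
        hist[hpos] = hit ? 0 : 1;
        nfails += hist[hpos];
        hpos = (hpos + 1) % l;
        if (hit) {
            ectx = ((ectx << 2) | (uint64_t)true_sym) & mask;
            if (hcount == l && nfails == 0) subs_left = max_subs;
        } else if (subs_left > 0) {
            ectx = ((ectx << 2) | (uint64_t)last_top) & mask; // substitution
            --subs_left;
        } else {
            ectx = host_ctx; // give up: resynchronize on the true history
            subs_left = max_subs;
        }
    }
};

// ---------------------------------------------------------------------------
// Stochastic repeat models. A k-mer position index over the already coded
// sequence stores, per k-mer, up to max_pos positions of the base following
// each occurrence (FIFO). Instances ("copy experts") predict the base at
// their pointer (complemented and walking backward for inverted repeats).
// ---------------------------------------------------------------------------
struct RMParams {
    int kr = 11, rpn = 16;
    uint32_t a_hit_num = 1, a_hit_den = 1, a_miss_num = 1, a_miss_den = 1;
    int deact_pm = 500;   // deactivate when hit estimate q drops below this
    int gamma_pm = 200;   // small: repeat weights must adapt fast
    bool ir = true;
    int max_pos = 16;
    double a_hit() const { return (double)a_hit_num / a_hit_den; }
    double a_miss() const { return (double)a_miss_num / a_miss_den; }
    double deact() const { return deact_pm / 1000.0; }
    double gamma() const { return gamma_pm / 1000.0; }
};

struct RInst {
    int64_t ptr = 0;
    uint64_t hits = 0, fails = 0;
    double w = 0;
    bool ir = false;
    bool alive = true;
    bool dying = false; // deactivated this step; slot frees next step
    int pred = 0;
    double q = 0.5;
};

struct PosList {
    std::vector<uint32_t> p;
    uint32_t head = 0;
};

struct RepeatGroup {
    RMParams c;
    std::unordered_map<uint64_t, PosList> index;
    std::vector<RInst> inst;
    uint64_t kmer = 0, irkmer = 0, kmask = 0;
    int64_t kfill = 0; // symbols absorbed into the rolling k-mers

    void init(const RMParams& par) {
        c = par;
        if (c.kr < 4 || c.kr > 28) throw std::runtime_error("repeat k-mer size must be in 4..28");
        if (c.rpn < 1) throw std::runtime_error("rpn must be >= 1");
        if (c.deact_pm <= 0 || c.deact_pm >= 1000) throw std::runtime_error("deactivation threshold must be in (0,1)");
        kmask = (1ULL << (2 * c.kr)) - 1;
        kmer = irkmer = 0; kfill = 0;
        index.clear(); inst.clear();
    }

    void index_add(uint64_t key, uint32_t pos) {
        PosList& L = index[key];
        if ((int)L.p.size() < c.max_pos) L.p.push_back(pos);
        else { L.p[L.head] = pos; L.head = (L.head + 1) % c.max_pos; } // FIFO
    }

    int n_occupied() const {
        int m = 0;
        for (const RInst& r : inst) if (r.alive || r.dying) ++m;
        return m;
    }

    // uniform stochastic start among the stored positions of the current k-mer
    void try_spawn(Rng& rng, std::vector<RInst*>& born) {
        if (kfill < c.kr) return;
        int used = n_occupied();
        if (used < c.rpn) {
            auto it = index.find(kmer);
            if (it != index.end() && !it->second.p.empty()) {
                uint32_t pos = it->second.p[rng.below(it->second.p.size())];
                inst.push_back(RInst{});
                RInst& r = inst.back();
                r.ptr = pos; r.ir = false; r.q = c.a_hit() / (c.a_hit() + c.a_miss());
                born.push_back(&r);
                ++used;
            }
        }
        if (c.ir && used < c.rpn) {
            auto it = index.find(irkmer);
            if (it != index.end() && !it->second.p.empty()) {
                int64_t pos = (int64_t)it->second.p[rng.below(it->second.p.size())];
                int64_t ptr = pos - c.kr - 1; // continuation of the IR copy, walking back
                if (ptr >= 0) {
                    inst.push_back(RInst{});
                    RInst& r = inst.back();
                    r.ptr = ptr; r.ir = true; r.q = c.a_hit() / (c.a_hit() + c.a_miss());
                    born.push_back(&r);
                }
            }
        }
    }

    void absorb(int sym) { // roll the forward and reverse-complement k-mers
        kmer = ((kmer << 2) | (uint64_t)sym) & kmask;
        irkmer = (irkmer >> 2) | ((uint64_t)comp(sym) << (2 * (c.kr - 1)));
        ++kfill;
    }

    void compact() {
        size_t j = 0;
        for (size_t i = 0; i < inst.size(); ++i) {
            if (inst[i].dying) { inst[i].alive = false; inst[i].dying = false; continue; }
            if (inst[i].alive) inst[j++] = inst[i];
        }
        inst.resize(j);
    }
};

// per-instance distribution: mass q on the copied base, (1-q)/3 elsewhere
inline void repeat_dist(int pred, double q, double out[4]) {
    double rest = (1.0 - q) / 3.0;
    out[0] = out[1] = out[2] = out[3] = rest;
    out[pred] = q;
}

// ---------------------------------------------------------------------------
// Soft-blending mixer: P(x) = sum_m w_m P_m(x); after each symbol
// w_m <- normalize(max(w_m, eps)^gamma_m * P_m(true)), eps = 1e-12.
// ---------------------------------------------------------------------------
const double W_FLOOR = 1e-12;

inline void mix_update(std::vector<double>& w, const std::vector<double>& gamma,
                       const double* ptrue) {
    size_t m = w.size();
    double tot = 0;
    for (size_t j = 0; j < m; ++j) {
        double v = std::pow(w[j], gamma[j]) * ptrue[j];
        if (v < W_FLOOR) v = W_FLOOR;
        w[j] = v;
        tot += v;
    }
    if (tot <= 0) { for (size_t j = 0; j < m; ++j) w[j] = 1.0 / m; return; }
    for (size_t j = 0; j < m; ++j) w[j] /= tot;
}

// ---------------------------------------------------------------------------
// Competitive prediction context model: binary order-k_c model over the
// history of which class won each base (0 = context models, 1 = repeats).
// ---------------------------------------------------------------------------
struct Cpcm {
    int k = 5;
    uint32_t alpha_num = 1, alpha_den = 1;
    uint32_t ctx = 0, mask = 0;
    std::vector<uint8_t> counts; // 2^k contexts x 2
    void init(int k_, uint32_t an, uint32_t ad) {
        k = k_; alpha_num = an; alpha_den = ad;
        if (k < 1 || k > 20) throw std::runtime_error("cpcm order must be in 1..20");
        if (an == 0 || ad == 0) throw std::runtime_error("cpcm alpha must be positive");
        mask = (k >= 32) ? ~0u : ((1u << k) - 1);
        ctx = 0;
        counts.assign(((size_t)1 << k) * 2, 0);
    }
    double alpha() const { return (double)alpha_num / alpha_den; }
    int select(double* p0_out = nullptr) const {
        double a = alpha();
        double c0 = counts[(size_t)ctx * 2], c1 = counts[(size_t)ctx * 2 + 1];
        double p0 = (c0 + a) / (c0 + c1 + 2 * a);
        if (p0_out) *p0_out = p0;
        return (1.0 - p0 > p0) ? 1 : 0; // ties -> class 0
    }
    void record(int winner) {
        uint8_t* c = &counts[(size_t)ctx * 2];
        if ((int)c[winner] + 1 > 255) { c[0] >>= 1; c[1] >>= 1; }
        c[winner]++;
        ctx = ((ctx << 1) | (uint32_t)winner) & mask;
    }
};

// ---------------------------------------------------------------------------
// Frequency quantization: largest-remainder rounding of a probability vector
// to integers summing to exactly 2^16, every entry >= 1; ties broken by
// symbol code order so both sides of the codec agree bit-for-bit.
// ---------------------------------------------------------------------------
const uint32_t F_TOTAL = 65536;

inline void quantize4(const double p[4], uint32_t f[4]) {
    double rem[4];
    int64_t sum = 0;
    for (int j = 0; j < 4; ++j) {
        double s = p[j] * (double)F_TOTAL;
        if (s < 0) s = 0;
        double fl = std::floor(s);
        if (fl > (double)F_TOTAL) fl = (double)F_TOTAL;
        f[j] = (uint32_t)fl;
        rem[j] = s - fl;
        sum += f[j];
    }
    int order[4] = {0, 1, 2, 3}; // stable sort keeps code order on ties
    std::stable_sort(order, order + 4, [&rem](int a, int b) { return rem[a] > rem[b]; });
    int64_t give = (int64_t)F_TOTAL - sum;
    int oi = 0;
    while (give > 0) { f[order[oi % 4]]++; ++oi; --give; }
    while (give < 0) { // over-allocation (fp drift): shave the largest entries
        int big = 0;
        for (int j = 1; j < 4; ++j) if (f[j] > f[big]) big = j;
        if (f[big] > 1) { f[big]--; ++give; } else break;
    }
    for (int j = 0; j < 4; ++j) { // floor-at-1, funded by the largest entry
        if (f[j] == 0) {
            int big = 0;
            for (int t = 1; t < 4; ++t) if (f[t] > f[big]) big = t;
            f[big]--; f[j] = 1;
        }
    }
}

// ---------------------------------------------------------------------------
// Byte-wise carry-propagating range coder (32-bit range, 64-bit low).
// ---------------------------------------------------------------------------
const uint32_t RC_TOP = 1u << 24;

struct RangeEncoder {
    std::vector<uint8_t>& out;
    uint64_t low = 0;
    uint32_t range = 0xFFFFFFFFu;
    uint8_t cache = 0;
    int64_t cache_size = 1;
    explicit RangeEncoder(std::vector<uint8_t>& sink) : out(sink) {}
    void shift_low() {
        if ((uint32_t)low < 0xFF000000u || (low >> 32) != 0) {
            uint8_t carry = (uint8_t)(low >> 32);
            uint8_t tmp = cache;
            do { out.push_back((uint8_t)(tmp + carry)); tmp = 0xFF; } while (--cache_size != 0);
            cache = (uint8_t)(low >> 24);
        }
        ++cache_size;
        low = (uint32_t)((uint32_t)low << 8); // 32-bit wrap: top byte lives in cache
    }
    void encode(uint32_t cum, uint32_t freq, uint32_t total) {
        range /= total;
        low += (uint64_t)cum * range;
        range *= freq;
        while (range < RC_TOP) { range <<= 8; shift_low(); }
    }
    void flush() { for (int i = 0; i < 5; ++i) shift_low(); }
};

struct RangeDecoder {
    const uint8_t* in;
    size_t pos = 0, len = 0;
    uint32_t range = 0xFFFFFFFFu, code = 0, r_ = 0;
    bool overrun = false;
    void attach(const uint8_t* buf, size_t m) {
        in = buf; len = m; pos = 0; range = 0xFFFFFFFFu; code = 0; overrun = false;
        for (int i = 0; i < 5; ++i) code = (code << 8) | next_byte();
    }
    uint8_t next_byte() {
        if (pos >= len) { overrun = true; return 0; }
        return in[pos++];
    }
    uint32_t decode_freq(uint32_t total) {
        r_ = range / total;
        uint32_t t = code / r_;
        return t >= total ? total - 1 : t;
    }
    void decode_update(uint32_t cum, uint32_t freq) {
        code -= cum * r_;
        range = r_ * freq;
        while (range < RC_TOP) { code = (code << 8) | next_byte(); range <<= 8; }
    }
};

// ---------------------------------------------------------------------------
// CRC32 (IEEE, reflected) for header integrity.
// ---------------------------------------------------------------------------
inline uint32_t crc32(const uint8_t* p, size_t n, uint32_t seed = 0) {
    static uint32_t tab[256];
    static bool ready = false;
    if (!ready) {
        for (uint32_t i = 0; i < 256; ++i) {
            uint32_t c = i;
            for (int j = 0; j < 8; ++j) c = (c & 1) ? (0xEDB88320u ^ (c >> 1)) : (c >> 1);
            tab[i] = c;
        }
        ready = true;
    }
    uint32_t c = seed ^ 0xFFFFFFFFu;
    for (size_t i = 0; i < n; ++i) c = tab[(c ^ p[i]) & 0xFF] ^ (c >> 8);
    return c ^ 0xFFFFFFFFu;
}

// ---------------------------------------------------------------------------
// Codec configuration + bit-exact header (integer-only side information).
// ---------------------------------------------------------------------------
struct CodecConfig {
    std::vector<CMParams> cms;
    std::vector<RMParams> rms;
    int cpcm_k = 5;
    uint32_t cpcm_alpha_num = 1, cpcm_alpha_den = 1;

    void validate() const {
        size_t experts = cms.size() + rms.size();
        for (const CMParams& m : cms) if (m.has_stcm) ++experts;
        if (cms.empty() && rms.empty())
            throw std::runtime_error("configuration needs at least one model");
        (void)experts;
    }
};

struct ByteWriter {
    std::vector<uint8_t> b;
    void u8(uint8_t v) { b.push_back(v); }
    void u16(uint16_t v) { for (int i = 0; i < 2; ++i) b.push_back((uint8_t)(v >> (8 * i))); }
    void u32(uint32_t v) { for (int i = 0; i < 4; ++i) b.push_back((uint8_t)(v >> (8 * i))); }
    void u64(uint64_t v) { for (int i = 0; i < 8; ++i) b.push_back((uint8_t)(v >> (8 * i))); }
};
struct ByteReader {
    const uint8_t* p; size_t n, pos = 0;
    ByteReader(const uint8_t* p_, size_t n_) : p(p_), n(n_) {}
    void need(size_t m) const { if (pos + m > n) throw std::runtime_error("truncated container"); }
    uint8_t u8() { need(1); return p[pos++]; }
    uint16_t u16() { need(2); uint16_t v = 0; for (int i = 0; i < 2; ++i) v |= (uint16_t)p[pos++] << (8 * i); return v; }
    uint32_t u32() { need(4); uint32_t v = 0; for (int i = 0; i < 4; ++i) v |= (uint32_t)p[pos++] << (8 * i); return v; }
    uint64_t u64() { need(8); uint64_t v = 0; for (int i = 0; i < 8; ++i) v |= (uint64_t)p[pos++] << (8 * i); return v; }
};

inline void write_header(ByteWriter& w, const CodecConfig& cfg, uint64_t n, uint64_t seed) {
    w.u8('C'); w.u8('P'); w.u8('D'); w.u8('1');
    w.u8(1); // format version
    w.u8(0); // flags (reserved)
    w.u64(n);
    w.u64(seed);
    w.u8((uint8_t)cfg.cms.size());
    for (const CMParams& m : cfg.cms) {
        w.u8((uint8_t)m.k);
        w.u32(m.alpha_num); w.u32(m.alpha_den);
        w.u16((uint16_t)m.gamma_pm);
        w.u8((uint8_t)m.ir_mode);
        w.u8(m.dense ? 0 : 1);
        w.u8((uint8_t)m.hash_bits);
        w.u8((uint8_t)m.max_coll);
        w.u8((uint8_t)m.counter_max);
        w.u8(m.has_stcm ? 1 : 0);
        if (m.has_stcm) {
            w.u8((uint8_t)m.stcm_max_subs);
            w.u16((uint16_t)m.stcm_t);
            w.u16((uint16_t)m.stcm_l);
        }
    }
    w.u8((uint8_t)cfg.rms.size());
    for (const RMParams& m : cfg.rms) {
        w.u8((uint8_t)m.kr);
        w.u16((uint16_t)m.rpn);
        w.u16((uint16_t)m.a_hit_num); w.u16((uint16_t)m.a_hit_den);
        w.u16((uint16_t)m.a_miss_num); w.u16((uint16_t)m.a_miss_den);
        w.u16((uint16_t)m.deact_pm);
        w.u16((uint16_t)m.gamma_pm);
        w.u8(m.ir ? 1 : 0);
        w.u16((uint16_t)m.max_pos);
    }
    w.u8((uint8_t)cfg.cpcm_k);
    w.u32(cfg.cpcm_alpha_num); w.u32(cfg.cpcm_alpha_den);
    w.u32(crc32(w.b.data(), w.b.size()));
}

inline CodecConfig read_header(ByteReader& r, uint64_t& n, uint64_t& seed) {
    size_t start = r.pos;
    if (r.u8() != 'C' || r.u8() != 'P' || r.u8() != 'D' || r.u8() != '1')
        throw std::runtime_error("bad magic: not a cpdna container");
    if (r.u8() != 1) throw std::runtime_error("unsupported container version");
    r.u8(); // flags
    n = r.u64();
    seed = r.u64();
    CodecConfig cfg;
    int ncm = r.u8();
    for (int i = 0; i < ncm; ++i) {
        CMParams m;
        m.k = r.u8();
        m.alpha_num = r.u32(); m.alpha_den = r.u32();
        m.gamma_pm = r.u16();
        m.ir_mode = r.u8();
        m.dense = (r.u8() == 0);
        m.hash_bits = r.u8();
        m.max_coll = r.u8();
        m.counter_max = r.u8();
        m.has_stcm = (r.u8() == 1);
        if (m.has_stcm) {
            m.stcm_max_subs = r.u8();
            m.stcm_t = r.u16();
            m.stcm_l = r.u16();
        }
        cfg.cms.push_back(m);
    }
    int nrm = r.u8();
    for (int i = 0; i < nrm; ++i) {
        RMParams m;
        m.kr = r.u8();
        m.rpn = r.u16();
        m.a_hit_num = r.u16(); m.a_hit_den = r.u16();
        m.a_miss_num = r.u16(); m.a_miss_den = r.u16();
        m.deact_pm = r.u16();
        m.gamma_pm = r.u16();
        m.ir = (r.u8() == 1);
        m.max_pos = r.u16();
        cfg.rms.push_back(m);
    }
    cfg.cpcm_k = r.u8();
    cfg.cpcm_alpha_num = r.u32(); cfg.cpcm_alpha_den = r.u32();
    uint32_t want = crc32(r.p + start, r.pos - start);
    uint32_t got = r.u32();
    if (want != got) throw std::runtime_error("header checksum mismatch");
    cfg.validate();
    return cfg;
}

// ---------------------------------------------------------------------------
// Engine: the per-base pipeline shared by compressor and decompressor.
// Fixed step order (decoder synchronization depends on it):
//   predict both classes -> CPCM select -> quantize -> code ->
//   weight updates -> CM counter updates (forward + IR) -> STCM updates ->
//   repeat instance updates -> history append -> spawn attempts ->
//   k-mer index add -> repeat weight renormalization -> CPCM record.
// ---------------------------------------------------------------------------
struct EngineDetails {
    bool enabled = false;
    int checkpoint_every = 10000;
    std::vector<double> bits;       // -log2 of the coded (quantized) probability
    std::vector<uint8_t> selected;  // class sent to the coder
    std::vector<uint8_t> winners;   // class that predicted the true base best
    std::vector<uint64_t> checkpoints;
};

struct Engine {
    CodecConfig cfg;
    std::vector<ContextModel> cms;
    std::vector<Stcm> stcms;           // parallel to experts of type STCM
    // CM-class expert table: (cm index, is_stcm); STCMs follow their host
    struct Expert { int cm; bool stcm; int stcm_idx; };
    std::vector<Expert> experts;
    std::vector<double> wcm, gcm;      // CM-class mixer state
    std::vector<RepeatGroup> rgs;
    Cpcm cpcm;
    Rng rng;
    PackedSeq hist;

    // scratch per step
    std::vector<double> expdist;       // E x 4
    std::vector<RInst*> act;           // active instances this step
    std::vector<double> rdist;         // |act| x 4 probabilities of true? full dists
    double pcm[4], prm[4];
    int sel = 0;
    uint32_t freq[4];

    void init(const CodecConfig& c, uint64_t seed, uint64_t n_hint) {
        cfg = c;
        cfg.validate();
        cms.clear(); stcms.clear(); experts.clear(); rgs.clear();
        for (size_t i = 0; i < cfg.cms.size(); ++i) {
            cms.emplace_back();
            cms.back().init(cfg.cms[i]);
            experts.push_back(Expert{(int)i, false, -1});
            if (cfg.cms[i].has_stcm) {
                stcms.emplace_back();
                stcms.back().init(cfg.cms[i].k, cfg.cms[i].stcm_max_subs,
                                  cfg.cms[i].stcm_t, cfg.cms[i].stcm_l);
                experts.push_back(Expert{(int)i, true, (int)stcms.size() - 1});
            }
        }
        size_t E = experts.size();
        wcm.assign(E, E ? 1.0 / E : 0.0);
        gcm.resize(E);
        for (size_t e = 0; e < E; ++e) gcm[e] = cfg.cms[experts[e].cm].gamma();
        for (const RMParams& m : cfg.rms) {
            rgs.emplace_back();
            rgs.back().init(m);
        }
        cpcm.init(cfg.cpcm_k, cfg.cpcm_alpha_num, cfg.cpcm_alpha_den);
        rng.reseed(seed);
        hist.clear();
        hist.reserve(n_hint);
        expdist.assign(E * 4, 0.25);
    }

    void predict(size_t i) {
        size_t E = experts.size();
        // CM class
        if (E) {
            for (size_t e = 0; e < E; ++e) {
                const Expert& ex = experts[e];
                ContextModel& m = cms[ex.cm];
                int prev_k = ((int64_t)i - m.p.k >= 0) ? hist.get(i - m.p.k) : -1;
                if (ex.stcm) stcms[ex.stcm_idx].predict(m.store, m.p.alpha(), &expdist[e * 4]);
                else m.predict(&expdist[e * 4], prev_k);
            }
            for (int j = 0; j < 4; ++j) {
                double s = 0;
                for (size_t e = 0; e < E; ++e) s += wcm[e] * expdist[e * 4 + j];
                pcm[j] = s;
            }
        } else {
            pcm[0] = pcm[1] = pcm[2] = pcm[3] = 0.25;
        }
        // repeat class
        act.clear();
        for (RepeatGroup& g : rgs)
            for (RInst& r : g.inst)
                if (r.alive && !r.dying) {
                    r.pred = r.ir ? comp(hist.get((size_t)r.ptr)) : hist.get((size_t)r.ptr);
                    double ah = g.c.a_hit(), am = g.c.a_miss();
                    r.q = ((double)r.hits + ah) / ((double)r.hits + (double)r.fails + ah + am);
                    act.push_back(&r);
                }
        if (act.empty()) {
            prm[0] = prm[1] = prm[2] = prm[3] = 0.25;
        } else {
            prm[0] = prm[1] = prm[2] = prm[3] = 0;
            for (RInst* r : act) {
                double rest = (1.0 - r->q) / 3.0;
                for (int j = 0; j < 4; ++j) prm[j] += r->w * (j == r->pred ? r->q : rest);
            }
        }
        sel = cpcm.select();
        quantize4(sel ? prm : pcm, freq);
    }

    // gamma for an instance is its group's gamma_r; find via group scan
    void update(size_t i, int sym, EngineDetails* det) {
        size_t E = experts.size();
        // Eq.-style weight updates with the pre-quantization probabilities
        if (E) {
            std::vector<double> pt(E);
            for (size_t e = 0; e < E; ++e) pt[e] = expdist[e * 4 + sym];
            mix_update(wcm, gcm, pt.data());
        }
        // repeat instance weights (floor, power by group gamma, multiply)
        for (RepeatGroup& g : rgs) {
            double gam = g.c.gamma();
            for (RInst& r : g.inst) {
                if (!(r.alive && !r.dying)) continue;
                double p = (sym == r.pred) ? r.q : (1.0 - r.q) / 3.0;
                double v = std::pow(r.w, gam) * p;
                if (v < W_FLOOR) v = W_FLOOR;
                r.w = v;
            }
        }
        int winner = (prm[sym] > pcm[sym]) ? 1 : 0;
        // CM counter + context updates, then STCMs (which need the new context)
        for (size_t ci = 0; ci < cms.size(); ++ci) {
            ContextModel& m = cms[ci];
            int prev_k = ((int64_t)i - m.p.k >= 0) ? hist.get(i - m.p.k) : -1;
            m.update(sym, prev_k);
        }
        for (size_t e = 0; e < E; ++e)
            if (experts[e].stcm)
                stcms[experts[e].stcm_idx].update(sym, cms[experts[e].cm].fctx);
        // repeat instance updates
        for (RepeatGroup& g : rgs) {
            double ah = g.c.a_hit(), am = g.c.a_miss(), th = g.c.deact();
            for (RInst& r : g.inst) {
                if (!(r.alive && !r.dying)) continue;
                if (sym == r.pred) ++r.hits; else ++r.fails;
                r.ptr += r.ir ? -1 : 1;
                double q = ((double)r.hits + ah) / ((double)r.hits + (double)r.fails + ah + am);
                bool oob = r.ir ? (r.ptr < 0) : (r.ptr > (int64_t)i);
                if (q < th || oob) r.dying = true; // slot frees next step
            }
        }
        hist.push(sym);
        for (RepeatGroup& g : rgs) g.absorb(sym);
        // spawn (before indexing the current k-mer: draws stay causal), then index
        std::vector<RInst*> born;
        for (RepeatGroup& g : rgs) g.try_spawn(rng, born);
        for (RepeatGroup& g : rgs)
            if (g.kfill >= g.c.kr) g.index_add(g.kmer, (uint32_t)(i + 1));
        // renormalize repeat weights over survivors + newborns
        {
            int nact = 0;
            for (RepeatGroup& g : rgs)
                for (RInst& r : g.inst) if (r.alive && !r.dying) ++nact;
            for (RInst* r : born) r->w = 1.0 / nact;
            double tot = 0;
            for (RepeatGroup& g : rgs)
                for (RInst& r : g.inst) if (r.alive && !r.dying) tot += r.w;
            if (tot > 0)
                for (RepeatGroup& g : rgs)
                    for (RInst& r : g.inst) if (r.alive && !r.dying) r.w /= tot;
            for (RepeatGroup& g : rgs) g.compact();
        }
        cpcm.record(winner);
        if (det && det->enabled) {
            det->bits.push_back(-std::log2((double)freq[sym] / F_TOTAL));
            det->selected.push_back((uint8_t)sel);
            det->winners.push_back((uint8_t)winner);
            if (det->checkpoint_every > 0 && (i + 1) % (size_t)det->checkpoint_every == 0)
                det->checkpoints.push_back(state_checksum(i + 1));
        }
    }

    uint64_t state_checksum(size_t step) const {
        uint64_t h = 0xCBF29CE484222325ULL;
        auto eat64 = [&h](uint64_t v) {
            for (int i = 0; i < 8; ++i) { h ^= (v >> (8 * i)) & 0xFF; h *= 0x100000001B3ULL; }
        };
        auto eatd = [&](double d) { uint64_t v; std::memcpy(&v, &d, 8); eat64(v); };
        eat64(step);
        eat64(rng.s);
        for (double v : wcm) eatd(v);
        for (const ContextModel& m : cms) {
            eat64(m.fctx); eat64(m.irctx); eat64(m.store.digest());
        }
        for (const Stcm& s : stcms) {
            eat64(s.ectx); eat64((uint64_t)s.subs_left);
            eat64((uint64_t)s.nfails); eat64((uint64_t)s.hcount); eat64((uint64_t)s.hpos);
        }
        for (const RepeatGroup& g : rgs) {
            eat64(g.kmer); eat64(g.irkmer);
            for (const RInst& r : g.inst) {
                if (!r.alive) continue;
                eat64((uint64_t)r.ptr); eat64(r.hits); eat64(r.fails);
                eatd(r.w); eat64(r.ir ? 1 : 0);
            }
        }
        eat64(cpcm.ctx);
        {
            uint64_t hh = 0xCBF29CE484222325ULL;
            for (uint8_t b : cpcm.counts) { hh ^= b; hh *= 0x100000001B3ULL; }
            eat64(hh);
        }
        return h;
    }
};

// ---------------------------------------------------------------------------
// Container-level compress / decompress.
// ---------------------------------------------------------------------------
inline std::vector<uint8_t> compress(const PackedSeq& seq, const CodecConfig& cfg,
                                     uint64_t seed, EngineDetails* det = nullptr,
                                     size_t* header_bytes = nullptr) {
    if (seq.n == 0) throw std::runtime_error("cannot compress an empty sequence");
    ByteWriter w;
    write_header(w, cfg, seq.n, seed);
    if (header_bytes) *header_bytes = w.b.size();
    Engine eng;
    eng.init(cfg, seed, seq.n);
    RangeEncoder rc(w.b);
    for (size_t i = 0; i < seq.n; ++i) {
        eng.predict(i);
        int sym = seq.get(i);
        uint32_t cum = 0;
        for (int j = 0; j < sym; ++j) cum += eng.freq[j];
        rc.encode(cum, eng.freq[sym], F_TOTAL);
        eng.update(i, sym, det);
    }
    rc.flush();
    return std::move(w.b);
}

inline PackedSeq decompress(const uint8_t* buf, size_t m, EngineDetails* det = nullptr) {
    ByteReader r(buf, m);
    uint64_t n = 0, seed = 0;
    CodecConfig cfg = read_header(r, n, seed);
    Engine eng;
    eng.init(cfg, seed, n);
    RangeDecoder rc;
    rc.attach(buf + r.pos, m - r.pos);
    PackedSeq out;
    out.reserve(n);
    for (size_t i = 0; i < n; ++i) {
        eng.predict(i);
        uint32_t t = rc.decode_freq(F_TOTAL);
        uint32_t cum = 0;
        int sym = 0;
        while (sym < 3 && cum + eng.freq[sym] <= t) { cum += eng.freq[sym]; ++sym; }
        rc.decode_update(cum, eng.freq[sym]);
        eng.update(i, sym, det);
        out.push(sym);
    }
    if (rc.overrun) throw std::runtime_error("truncated container payload");
    return out;
}

} // namespace cpdna

#endif
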