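#include <Rcpp.h>
#include "cpdna.h"

using namespace Rcpp;
using namespace cpdna;

// ---------------------------------------------------------------- sequences

// [[Rcpp::export]]
List cpp_pack(std::string s) {
    PackedSeq p = pack_string(s);
    RawVector raw(p.data.size());
    std::copy(p.data.begin(), p.data.end(), raw.begin());
    return List::create(_["data"] = raw, _["length"] = (double)p.n);
}

// [[Rcpp::export]]
std::string cpp_unpack(RawVector data, double n) {
    PackedSeq p;
    p.data.assign(data.begin(), data.end());
    p.n = (size_t)n;
    if (p.data.size() != (p.n + 3) / 4) stop("packed buffer size does not match length");
    return unpack_string(p);
}

// [[Rcpp::export]]
std::string cpp_get_bases(RawVector data, double n, NumericVector idx) {
    PackedSeq p;
    p.data.assign(data.begin(), data.end());
    p.n = (size_t)n;
    std::string out(idx.size(), 'A');
    for (R_xlen_t i = 0; i < idx.size(); ++i) {
        double j = idx[i];
        if (j < 1 || j > (double)p.n) stop("index out of range");
        out[i] = base_char(p.get((size_t)j - 1));
    }
    return out;
}

// Upcase and drop every non-ACGT character, reporting how many were removed.
// [[Rcpp::export]]
List cpp_filter_acgt(std::string s) {
    PackedSeq p;
    p.reserve(s.size());
    double removed = 0;
    for (char c : s) {
        int b = base_code(c);
        if (b < 0) { removed += 1; continue; }
        p.push(b);
    }
    RawVector raw(p.data.size());
    std::copy(p.data.begin(), p.data.end(), raw.begin());
    return List::create(_["data"] = raw, _["length"] = (double)p.n,
                        _["removed"] = removed);
}

// ------------------------------------------------------------- fcm helpers

// [[Rcpp::export]]
NumericVector cpp_estimator(IntegerVector counts, double alpha) {
    if (counts.size() != 4) stop("counts must have length 4");
    if (alpha <= 0) stop("alpha must be positive");
    uint32_t c[4];
    for (int j = 0; j < 4; ++j) {
        if (counts[j] < 0) stop("counts must be nonnegative");
        c[j] = (uint32_t)counts[j];
    }
    double out[4];
    estimate4(c, alpha, out);
    return NumericVector::create(out[0], out[1], out[2], out[3]);
}

// [[Rcpp::export]]
IntegerVector cpp_bump_counts(IntegerVector counts, int sym, int counter_max) {
    if (counts.size() != 4) stop("counts must have length 4");
    if (sym < 0 || sym > 3) stop("symbol code must be in 0..3");
    uint8_t c[4];
    for (int j = 0; j < 4; ++j) c[j] = (uint8_t)counts[j];
    bump4(c, sym, counter_max);
    return IntegerVector::create(c[0], c[1], c[2], c[3]);
}

static uint64_t ctx_to_int(const std::string& ctx) {
    uint64_t v = 0;
    for (char ch : ctx) {
        int b = base_code(ch);
        if (b < 0) Rcpp::stop("context must be an ACGT string");
        v = (v << 2) | (uint64_t)b;
    }
    return v;
}

// [[Rcpp::export]]
List cpp_ir_event(std::string window) {
    // window = x_{i-k..i}; returns the reverse-complement event it trains
    if (window.size() < 2) stop("window needs at least 2 symbols");
    int k = (int)window.size() - 1;
    std::string ctx(k, 'A');
    for (int j = 0; j < k; ++j) ctx[j] = base_char(comp(base_code(window[window.size() - 1 - j])));
    char sym = base_char(comp(base_code(window[0])));
    return List::create(_["context"] = ctx, _["symbol"] = std::string(1, sym));
}

// ------------------------------------------------------- counter store API

// [[Rcpp::export]]
SEXP cpp_store_new(int k, bool dense, int hash_bits, int max_coll, int counter_max) {
    XPtr<CounterStore> xp(new CounterStore(), true);
    xp->init(k, dense, hash_bits, max_coll, counter_max);
    return xp;
}

// [[Rcpp::export]]
void cpp_store_bump(SEXP store, std::string ctx, int sym) {
    XPtr<CounterStore> xp(store);
    if ((int)ctx.size() != xp->k) stop("context length must equal k");
    xp->bump(ctx_to_int(ctx), sym);
}

// [[Rcpp::export]]
IntegerVector cpp_store_counts(SEXP store, std::string ctx) {
    XPtr<CounterStore> xp(store);
    if ((int)ctx.size() != xp->k) stop("context length must equal k");
    uint32_t c[4];
    xp->get(ctx_to_int(ctx), c);
    return IntegerVector::create(c[0], c[1], c[2], c[3]);
}

// ------------------------------------------------- config parsing from R

static CMParams cm_from_list(List m) {
    CMParams p;
    p.k = as<int>(m["k"]);
    p.alpha_num = (uint32_t)as<double>(m["alpha_num"]);
    p.alpha_den = (uint32_t)as<double>(m["alpha_den"]);
    p.gamma_pm = as<int>(m["gamma_pm"]);
    p.ir_mode = as<int>(m["ir_mode"]);
    p.dense = as<bool>(m["dense"]);
    p.hash_bits = as<int>(m["hash_bits"]);
    p.max_coll = as<int>(m["max_coll"]);
    p.counter_max = as<int>(m["counter_max"]);
    if (m.containsElementNamed("stcm") && !Rf_isNull(m["stcm"])) {
        List s = m["stcm"];
        p.has_stcm = true;
        p.stcm_max_subs = as<int>(s["max_subs"]);
        p.stcm_t = as<int>(s["t"]);
        p.stcm_l = as<int>(s["l"]);
    }
    return p;
}

static RMParams rm_from_list(List m) {
    RMParams p;
    p.kr = as<int>(m["k"]);
    p.rpn = as<int>(m["rpn"]);
    p.a_hit_num = (uint32_t)as<double>(m["a_hit_num"]);
    p.a_hit_den = (uint32_t)as<double>(m["a_hit_den"]);
    p.a_miss_num = (uint32_t)as<double>(m["a_miss_num"]);
    p.a_miss_den = (uint32_t)as<double>(m["a_miss_den"]);
    p.deact_pm = as<int>(m["deact_pm"]);
    p.gamma_pm = as<int>(m["gamma_pm"]);
    p.ir = as<bool>(m["ir"]);
    p.max_pos = as<int>(m["max_pos"]);
    return p;
}

static CodecConfig cfg_from_list(List cfg) {
    CodecConfig c;
    List cms = cfg["cms"];
    for (R_xlen_t i = 0; i < cms.size(); ++i) c.cms.push_back(cm_from_list(cms[i]));
    List rms = cfg["rms"];
    for (R_xlen_t i = 0; i < rms.size(); ++i) c.rms.push_back(rm_from_list(rms[i]));
    c.cpcm_k = as<int>(cfg["cpcm_k"]);
    c.cpcm_alpha_num = (uint32_t)as<double>(cfg["cpcm_alpha_num"]);
    c.cpcm_alpha_den = (uint32_t)as<double>(cfg["cpcm_alpha_den"]);
    c.validate();
    return c;
}

static List cm_to_list(const CMParams& p) {
    List s = R_NilValue;
    if (p.has_stcm)
        s = List::create(_["max_subs"] = p.stcm_max_subs, _["t"] = p.stcm_t, _["l"] = p.stcm_l);
    return List::create(
        _["k"] = p.k, _["alpha_num"] = (double)p.alpha_num, _["alpha_den"] = (double)p.alpha_den,
        _["gamma_pm"] = p.gamma_pm, _["ir_mode"] = p.ir_mode, _["dense"] = p.dense,
        _["hash_bits"] = p.hash_bits, _["max_coll"] = p.max_coll,
        _["counter_max"] = p.counter_max, _["stcm"] = s);
}

static List rm_to_list(const RMParams& p) {
    return List::create(
        _["k"] = p.kr, _["rpn"] = p.rpn,
        _["a_hit_num"] = (double)p.a_hit_num, _["a_hit_den"] = (double)p.a_hit_den,
        _["a_miss_num"] = (double)p.a_miss_num, _["a_miss_den"] = (double)p.a_miss_den,
        _["deact_pm"] = p.deact_pm, _["gamma_pm"] = p.gamma_pm,
        _["ir"] = p.ir, _["max_pos"] = p.max_pos);
}

// ------------------------------------------------------------- model scans

// Streaming predict-then-update of a single context model over a sequence;
// returns the n x 4 matrix of predictive distributions.
// [[Rcpp::export]]
NumericMatrix cpp_cm_scan(List cm_cfg, std::string seq) {
    CMParams par = cm_from_list(cm_cfg);
    ContextModel m;
    m.init(par);
    PackedSeq s = pack_string(seq);
    NumericMatrix out(s.n, 4);
    double d[4];
    for (size_t i = 0; i < s.n; ++i) {
        int prev_k = ((int64_t)i - par.k >= 0) ? s.get(i - par.k) : -1;
        m.predict(d, prev_k);
        for (int j = 0; j < 4; ++j) out(i, j) = d[j];
        m.update(s.get(i), prev_k);
    }
    return out;
}

// Weighted CM-class mixture (context models + attached STCMs) over a
// sequence: the exact expert set, estimator, and weight updates the codec
// uses, without the repeat class, selection, or coding.
// [[Rcpp::export]]
List cpp_cm_class_scan(List cm_cfgs, std::string seq) {
    CodecConfig cfg;
    for (R_xlen_t i = 0; i < cm_cfgs.size(); ++i) cfg.cms.push_back(cm_from_list(cm_cfgs[i]));
    cfg.cpcm_k = 2;
    Engine eng;
    eng.init(cfg, 0, seq.size());
    PackedSeq s = pack_string(seq);
    NumericMatrix mixed(s.n, 4);
    for (size_t i = 0; i < s.n; ++i) {
        eng.predict(i);
        for (int j = 0; j < 4; ++j) mixed(i, j) = eng.pcm[j];
        eng.update(i, s.get(i), nullptr);
    }
    NumericVector wfin(eng.wcm.begin(), eng.wcm.end());
    return List::create(_["mixed"] = mixed, _["weights"] = wfin);
}

// ---------------------------------------------------------------- STCM API

struct StcmTracker {
    ContextModel cm;
    Stcm st;
    PackedSeq hist;
};

// [[Rcpp::export]]
SEXP cpp_stcm_new(List cm_cfg) {
    CMParams par = cm_from_list(cm_cfg);
    if (!par.has_stcm) stop("configuration has no attached STCM");
    XPtr<StcmTracker> xp(new StcmTracker(), true);
    xp->cm.init(par);
    xp->st.init(par.k, par.stcm_max_subs, par.stcm_t, par.stcm_l);
    return xp;
}

// [[Rcpp::export]]
List cpp_stcm_step(SEXP tracker, std::string base) {
    XPtr<StcmTracker> xp(tracker);
    int sym = base_code(base[0]);
    if (sym < 0) stop("base must be one of ACGT");
    double d[4];
    xp->st.predict(xp->cm.store, xp->cm.p.alpha(), d);
    int top = xp->st.last_top;
    bool was_active = xp->st.active();
    size_t i = xp->hist.n;
    int prev_k = ((int64_t)i - xp->cm.p.k >= 0) ? xp->hist.get(i - xp->cm.p.k) : -1;
    xp->cm.update(sym, prev_k);
    xp->st.update(sym, xp->cm.fctx);
    xp->hist.push(sym);
    std::string ectx(xp->cm.p.k, 'A');
    for (int j = 0; j < xp->cm.p.k; ++j)
        ectx[j] = base_char((int)((xp->st.ectx >> (2 * (xp->cm.p.k - 1 - j))) & 3));
    return List::create(
        _["dist"] = NumericVector::create(d[0], d[1], d[2], d[3]),
        _["top"] = top,
        _["active"] = was_active,
        _["active_after"] = xp->st.active(),
        _["hit"] = (top == sym),
        _["subs_left"] = xp->st.subs_left,
        _["fails_in_window"] = xp->st.nfails,
        _["edited_context"] = ectx);
}

// ------------------------------------------------------------- repeats API

struct RmTracker {
    RepeatGroup g;
    Rng rng;
    PackedSeq hist;
    explicit RmTracker(uint64_t seed) : rng(seed) {}

    // mirror of the engine's repeat-side step; returns mixture before update
    List step(int sym) {
        size_t i = hist.n;
        std::vector<RInst*> act;
        for (RInst& r : g.inst)
            if (r.alive && !r.dying) {
                r.pred = r.ir ? comp(hist.get((size_t)r.ptr)) : hist.get((size_t)r.ptr);
                double ah = g.c.a_hit(), am = g.c.a_miss();
                r.q = ((double)r.hits + ah) / ((double)r.hits + (double)r.fails + ah + am);
                act.push_back(&r);
            }
        double prm[4] = {0.25, 0.25, 0.25, 0.25};
        if (!act.empty()) {
            prm[0] = prm[1] = prm[2] = prm[3] = 0;
            for (RInst* r : act) {
                double rest = (1.0 - r->q) / 3.0;
                for (int j = 0; j < 4; ++j) prm[j] += r->w * (j == r->pred ? r->q : rest);
            }
        }
        double gam = g.c.gamma();
        for (RInst* r : act) {
            double p = (sym == r->pred) ? r->q : (1.0 - r->q) / 3.0;
            double v = std::pow(r->w, gam) * p;
            r->w = (v < W_FLOOR) ? W_FLOOR : v;
        }
        double ah = g.c.a_hit(), am = g.c.a_miss(), th = g.c.deact();
        for (RInst* r : act) {
            if (sym == r->pred) ++r->hits; else ++r->fails;
            r->ptr += r->ir ? -1 : 1;
            double q = ((double)r->hits + ah) / ((double)r->hits + (double)r->fails + ah + am);
            bool oob = r->ir ? (r->ptr < 0) : (r->ptr > (int64_t)i);
            if (q < th || oob) r->dying = true;
        }
        hist.push(sym);
        g.absorb(sym);
        std::vector<RInst*> born;
        g.try_spawn(rng, born);
        if (g.kfill >= g.c.kr) g.index_add(g.kmer, (uint32_t)(i + 1));
        int nact = 0;
        for (RInst& r : g.inst) if (r.alive && !r.dying) ++nact;
        for (RInst* r : born) r->w = 1.0 / nact;
        double tot = 0;
        for (RInst& r : g.inst) if (r.alive && !r.dying) tot += r.w;
        if (tot > 0) for (RInst& r : g.inst) if (r.alive && !r.dying) r.w /= tot;
        g.compact();
        return List::create(
            _["dist"] = NumericVector::create(prm[0], prm[1], prm[2], prm[3]),
            _["n_active"] = (int)act.size());
    }
};

// [[Rcpp::export]]
SEXP cpp_rm_new(List rm_cfg, double seed) {
    XPtr<RmTracker> xp(new RmTracker((uint64_t)seed), true);
    xp->g.init(rm_from_list(rm_cfg));
    return xp;
}

// [[Rcpp::export]]
List cpp_rm_step(SEXP tracker, std::string base) {
    XPtr<RmTracker> xp(tracker);
    int sym = base_code(base[0]);
    if (sym < 0) stop("base must be one of ACGT");
    return xp->step(sym);
}

// [[Rcpp::export]]
IntegerVector cpp_rm_positions(SEXP tracker, std::string kmer) {
    XPtr<RmTracker> xp(tracker);
    if ((int)kmer.size() != xp->g.c.kr) stop("k-mer length must equal the group's k");
    auto it = xp->g.index.find(ctx_to_int(kmer));
    if (it == xp->g.index.end()) return IntegerVector(0);
    // report in insertion (oldest-first) order
    const PosList& L = it->second;
    IntegerVector out(L.p.size());
    size_t m = L.p.size();
    for (size_t j = 0; j < m; ++j)
        out[j] = (int)L.p[(L.head + j) % m];
    return out;
}

// [[Rcpp::export]]
List cpp_rm_instances(SEXP tracker) {
    XPtr<RmTracker> xp(tracker);
    std::vector<double> ptr, hits, fails, w, q;
    std::vector<bool> ir;
    for (const RInst& r : xp->g.inst) {
        if (!r.alive) continue;
        ptr.push_back((double)r.ptr); hits.push_back((double)r.hits);
        fails.push_back((double)r.fails); w.push_back(r.w);
        double ah = xp->g.c.a_hit(), am = xp->g.c.a_miss();
        q.push_back((r.hits + ah) / (r.hits + r.fails + ah + am));
        ir.push_back(r.ir);
    }
    return List::create(_["ptr"] = wrap(ptr), _["hits"] = wrap(hits),
                        _["fails"] = wrap(fails), _["weight"] = wrap(w),
                        _["q"] = wrap(q), _["ir"] = wrap(ir));
}

// Repeat-class-only scan: per-base -log2 of the mixture probability of the
// true symbol, plus the active-instance trace.
// [[Rcpp::export]]
List cpp_rm_scan(List rm_cfg, std::string seq, double seed) {
    RmTracker tr((uint64_t)seed);
    tr.g.init(rm_from_list(rm_cfg));
    PackedSeq s = pack_string(seq);
    NumericVector bits(s.n);
    IntegerVector nact(s.n);
    for (size_t i = 0; i < s.n; ++i) {
        List st = tr.step(s.get(i));
        NumericVector d = st["dist"];
        bits[i] = -std::log2(d[s.get(i)]);
        nact[i] = as<int>(st["n_active"]);
    }
    return List::create(_["bits"] = bits, _["n_active"] = nact);
}

// ---------------------------------------------------------------- mixer

// [[Rcpp::export]]
NumericVector cpp_mix(NumericMatrix dists, NumericVector w) {
    if (dists.nrow() != w.size()) stop("one weight per distribution is required");
    if (dists.ncol() != 4) stop("distributions must have 4 columns");
    NumericVector out(4);
    for (int j = 0; j < 4; ++j) {
        double s = 0;
        for (int m = 0; m < dists.nrow(); ++m) s += w[m] * dists(m, j);
        out[j] = s;
    }
    return out;
}

// [[Rcpp::export]]
NumericVector cpp_mix_update(NumericVector w, NumericVector gamma, NumericVector p_true) {
    if (w.size() != gamma.size() || w.size() != p_true.size())
        stop("w, gamma and p_true must have equal length");
    std::vector<double> wv(w.begin(), w.end()), gv(gamma.begin(), gamma.end());
    mix_update(wv, gv, REAL(p_true));
    return NumericVector(wv.begin(), wv.end());
}

// ---------------------------------------------------------------- CPCM

// [[Rcpp::export]]
SEXP cpp_cpcm_new(int k, double alpha_num, double alpha_den) {
    XPtr<Cpcm> xp(new Cpcm(), true);
    xp->init(k, (uint32_t)alpha_num, (uint32_t)alpha_den);
    return xp;
}

// [[Rcpp::export]]
List cpp_cpcm_select(SEXP m) {
    XPtr<Cpcm> xp(m);
    double p0 = 0;
    int cl = xp->select(&p0);
    return List::create(_["class"] = cl, _["p0"] = p0, _["p1"] = 1.0 - p0);
}

// [[Rcpp::export]]
void cpp_cpcm_record(SEXP m, int winner) {
    XPtr<Cpcm> xp(m);
    if (winner != 0 && winner != 1) stop("winner must be 0 or 1");
    xp->record(winner);
}

// [[Rcpp::export]]
std::string cpp_cpcm_context(SEXP m) {
    XPtr<Cpcm> xp(m);
    std::string s(xp->k, '0');
    for (int j = 0; j < xp->k; ++j)
        s[j] = ((xp->ctx >> (xp->k - 1 - j)) & 1) ? '1' : '0';
    return s;
}

// [[Rcpp::export]]
IntegerVector cpp_cpcm_counts(SEXP m, std::string bits) {
    XPtr<Cpcm> xp(m);
    if ((int)bits.size() != xp->k) stop("context length must equal the cpcm order");
    uint32_t ctx = 0;
    for (char c : bits) {
        if (c != '0' && c != '1') stop("context must be a 0/1 string");
        ctx = (ctx << 1) | (uint32_t)(c == '1');
    }
    return IntegerVector::create(xp->counts[(size_t)ctx * 2], xp->counts[(size_t)ctx * 2 + 1]);
}

// [[Rcpp::export]]
int cpp_winner(double p_cm_true, double p_rm_true) {
    return (p_rm_true > p_cm_true) ? 1 : 0;
}

// ---------------------------------------------------------------- coder

// [[Rcpp::export]]
IntegerVector cpp_quantize(NumericVector p) {
    if (p.size() != 4) stop("distribution must have length 4");
    double s = p[0] + p[1] + p[2] + p[3];
    if (std::abs(s - 1.0) > 1e-6) stop("distribution must sum to 1");
    for (int j = 0; j < 4; ++j) if (p[j] <= 0) stop("distribution entries must be positive");
    double d[4] = {p[0], p[1], p[2], p[3]};
    uint32_t f[4];
    quantize4(d, f);
    return IntegerVector::create((int)f[0], (int)f[1], (int)f[2], (int)f[3]);
}

// [[Rcpp::export]]
RawVector cpp_rc_encode(IntegerVector syms, IntegerMatrix freqs) {
    if (freqs.ncol() != 4 || freqs.nrow() != syms.size())
        stop("freqs must be a length(syms) x 4 matrix");
    std::vector<uint8_t> out;
    RangeEncoder rc(out);
    for (R_xlen_t i = 0; i < syms.size(); ++i) {
        int sym = syms[i];
        if (sym < 0 || sym > 3) stop("symbol codes must be in 0..3");
        uint32_t f[4], tot = 0, cum = 0;
        for (int j = 0; j < 4; ++j) { f[j] = (uint32_t)freqs(i, j); tot += f[j]; }
        if (tot != F_TOTAL) stop("frequency rows must sum to 65536");
        for (int j = 0; j < sym; ++j) cum += f[j];
        rc.encode(cum, f[sym], F_TOTAL);
    }
    rc.flush();
    RawVector res(out.size());
    std::copy(out.begin(), out.end(), res.begin());
    return res;
}

// [[Rcpp::export]]
IntegerVector cpp_rc_decode(RawVector bytes, IntegerMatrix freqs, int n) {
    if (freqs.ncol() != 4 || freqs.nrow() != n) stop("freqs must be an n x 4 matrix");
    std::vector<uint8_t> buf(bytes.begin(), bytes.end());
    RangeDecoder rc;
    rc.attach(buf.data(), buf.size());
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        uint32_t f[4], tot = 0;
        for (int j = 0; j < 4; ++j) { f[j] = (uint32_t)freqs(i, j); tot += f[j]; }
        if (tot != F_TOTAL) stop("frequency rows must sum to 65536");
        uint32_t t = rc.decode_freq(F_TOTAL);
        uint32_t cum = 0;
        int sym = 0;
        while (sym < 3 && cum + f[sym] <= t) { cum += f[sym]; ++sym; }
        rc.decode_update(cum, f[sym]);
        out[i] = sym;
    }
    return out;
}

// ---------------------------------------------------------------- codec

static std::string hex64(uint64_t v) {
    char buf[17];
    std::snprintf(buf, sizeof buf, "%016llx", (unsigned long long)v);
    return std::string(buf);
}

static List details_to_list(const EngineDetails& det) {
    CharacterVector cks(det.checkpoints.size());
    for (size_t i = 0; i < det.checkpoints.size(); ++i) cks[i] = hex64(det.checkpoints[i]);
    return List::create(
        _["bits"] = NumericVector(det.bits.begin(), det.bits.end()),
        _["selected"] = IntegerVector(det.selected.begin(), det.selected.end()),
        _["winner"] = IntegerVector(det.winners.begin(), det.winners.end()),
        _["checkpoints"] = cks);
}

// [[Rcpp::export]]
List cpp_compress(List cfg, RawVector data, double n, double seed,
                  bool details, int checkpoint_every) {
    CodecConfig c = cfg_from_list(cfg);
    PackedSeq s;
    s.data.assign(data.begin(), data.end());
    s.n = (size_t)n;
    EngineDetails det;
    det.enabled = details;
    det.checkpoint_every = checkpoint_every;
    size_t hdr = 0;
    std::vector<uint8_t> out = compress(s, c, (uint64_t)seed,
                                        details ? &det : nullptr, &hdr);
    RawVector stream(out.size());
    std::copy(out.begin(), out.end(), stream.begin());
    List res = List::create(_["stream"] = stream, _["header_bytes"] = (double)hdr);
    if (details) res["details"] = details_to_list(det);
    return res;
}

// [[Rcpp::export]]
List cpp_decompress(RawVector stream, bool details, int checkpoint_every) {
    std::vector<uint8_t> buf(stream.begin(), stream.end());
    EngineDetails det;
    det.enabled = details;
    det.checkpoint_every = checkpoint_every;
    PackedSeq s = decompress(buf.data(), buf.size(), details ? &det : nullptr);
    RawVector data(s.data.size());
    std::copy(s.data.begin(), s.data.end(), data.begin());
    List res = List::create(_["data"] = data, _["length"] = (double)s.n);
    if (details) res["details"] = details_to_list(det);
    return res;
}

// [[Rcpp::export]]
List cpp_parse_header(RawVector stream) {
    std::vector<uint8_t> buf(stream.begin(), stream.end());
    ByteReader r(buf.data(), buf.size());
    uint64_t n = 0, seed = 0;
    CodecConfig c = read_header(r, n, seed);
    List cms(c.cms.size()), rms(c.rms.size());
    for (size_t i = 0; i < c.cms.size(); ++i) cms[i] = cm_to_list(c.cms[i]);
    for (size_t i = 0; i < c.rms.size(); ++i) rms[i] = rm_to_list(c.rms[i]);
    return List::create(
        _["length"] = (double)n, _["seed"] = (double)seed,
        _["cms"] = cms, _["rms"] = rms,
        _["cpcm_k"] = c.cpcm_k,
        _["cpcm_alpha_num"] = (double)c.cpcm_alpha_num,
        _["cpcm_alpha_den"] = (double)c.cpcm_alpha_den,
        _["header_bytes"] = (double)r.pos);
}

// ---------------------------------------------------------------- fixtures

static std::string rc_string(const std::string& s) {
    std::string out(s.size(), 'A');
    for (size_t i = 0; i < s.size(); ++i)
        out[i] = base_char(comp(base_code(s[s.size() - 1 - i])));
    return out;
}

// [[Rcpp::export]]
std::string cpp_mutate(std::string s, double rate, double seed) {
    if (rate < 0 || rate > 1) stop("substitution rate must be in [0,1]");
    Rng rng((uint64_t)seed);
    for (char& c : s) {
        int b = base_code(c);
        if (b < 0) stop("sequence must be ACGT only");
        if (rng.unif() < rate) c = base_char((b + 1 + (int)rng.below(3)) % 4);
    }
    return s;
}

// [[Rcpp::export]]
std::string cpp_gen_fixture(std::string kind, double n_, std::string unit,
                            int unit_len, int copies, double sub_rate, double seed) {
    size_t n = (size_t)n_;
    Rng rng((uint64_t)seed);
    auto rand_str = [&rng](size_t m) {
        std::string s(m, 'A');
        for (size_t i = 0; i < m; ++i) s[i] = base_char((int)rng.below(4));
        return s;
    };
    std::string out;
    if (kind == "random") {
        out = rand_str(n);
    } else if (kind == "tandem") {
        if (unit.empty()) unit = rand_str((size_t)unit_len);
        for (char c : unit) if (base_code(c) < 0) stop("unit must be ACGT only");
        if (unit.size() * (size_t)copies < n)
            stop("tandem spec inconsistent: unit_len * copies < n");
        out.reserve(n);
        while (out.size() < n) out += unit;
        out.resize(n);
    } else if (kind == "dispersed") {
        if (unit.empty()) unit = rand_str((size_t)unit_len);
        out = rand_str(n);
        if (unit.size() > n) stop("dispersed spec inconsistent: unit longer than n");
        for (int c = 0; c < copies; ++c) {
            size_t pos = rng.below(n - unit.size() + 1);
            out.replace(pos, unit.size(), unit);
        }
    } else if (kind == "inverted") {
        std::string S = rand_str((n + 1) / 2);
        out = S + rc_string(S);
        out.resize(n);
    } else {
        stop("unknown fixture kind");
    }
    if (sub_rate > 0) {
        // continue the same deterministic stream for the mutation pass
        for (char& c : out) {
            int b = base_code(c);
            if (rng.unif() < sub_rate) c = base_char((b + 1 + (int)rng.below(3)) % 4);
        }
    }
    return out;
}
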