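// Numerical core of the association model: forward/backward passes through
// the layered multi-head attention encoder, the joint objective
// (cross-entropy + intra/inter contrastive terms) and the Adam loop with
// early stopping on validation AUC.  All randomness (negative sampling,
// batch order, contrastive negative layers) is drawn on the R side and
// passed in, so runs are bit-reproducible given the R seed.
//
// Performance note: the per-head query/key/value projections are linear in
// the entity (and relation) embeddings, so they are computed once per batch
// for every entity (QE = E * Wq_head, QR = R * Wq_rel, KA = E * Wk,
// VA = E * Wv) and looked up per triple; the small per-layer attention
// kernels then run over a reusable workspace.  Gradients flow back through
// the same factorization (one GEMM per projection per batch).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct GraphPack {
  ivec bh, br, bt, boff, sd, soff;
  int L, n_anchor, n_microbe, max_block;
};

GraphPack parse_pack(const List &p) {
  GraphPack g;
  g.bh = as<ivec>(p["bh"]);
  g.br = as<ivec>(p["br"]);
  g.bt = as<ivec>(p["bt"]);
  g.boff = as<ivec>(p["boff"]);
  g.sd = as<ivec>(p["sd"]);
  g.soff = as<ivec>(p["soff"]);
  g.L = as<int>(p["L"]);
  g.n_anchor = as<int>(p["n_anchor"]);
  g.n_microbe = as<int>(p["n_microbe"]);
  g.max_block = 0;
  for (uword i = 0; i + 1 < g.boff.n_elem; ++i)
    g.max_block = std::max(g.max_block, (int)(g.boff[i + 1] - g.boff[i]));
  return g;
}

struct Params {
  mat E, R, Wq, Wk, Wv, Wo;
  int H, dh, dim;
};

// Entity/relation-level projections shared by all triples of a batch.
struct Precomp {
  mat QE, QR, KA, VA;  // n_ent x H*dh (QR: n_rel x H*dh)
  void compute(const Params &P) {
    QE = P.E * P.Wq.rows(0, P.dim - 1);
    QR = P.R * P.Wq.rows(P.dim, 2 * P.dim - 1);
    KA = P.E * P.Wk;
    VA = P.E * P.Wv;
  }
};

// Reusable row-major scratch for one layer's attention kernel.
struct Workspace {
  std::vector<double> q, k, v, A, w, o, dq, dk, dv, dw, doh;
  void reserve(int max_n, int HD) {
    doh.resize(HD);
    q.resize((size_t)max_n * HD);
    k.resize((size_t)max_n * HD);
    v.resize((size_t)max_n * HD);
    A.resize((size_t)max_n * max_n);
    w.resize(max_n);
    dw.resize(max_n);
    o.resize(HD);
    dq.resize((size_t)max_n * HD);
    dk.resize((size_t)max_n * HD);
    dv.resize((size_t)max_n * HD);
  }
};

// Gather compact per-triple q/k/v rows for one block.
inline void gather_block(const GraphPack &g, const Precomp &pre, int b0,
                         int n, int HD, Workspace &ws) {
  for (int i = 0; i < n; ++i) {
    const int h = g.bh[b0 + i], r = g.br[b0 + i], t = g.bt[b0 + i];
    for (int c = 0; c < HD; ++c) {
      ws.q[(size_t)i * HD + c] = pre.QE(h, c) + pre.QR(r, c);
      ws.k[(size_t)i * HD + c] = pre.KA(t, c);
      ws.v[(size_t)i * HD + c] = pre.VA(t, c);
    }
  }
}

// Attention over one layer's triples: per head, every triple is both query
// and key, rows are softmax-normalized, and the query axis is mean-pooled,
// i.e. o_h = sum_j w_j v_j with w_j = mean_i alpha_ij.  Fills ws.o (and,
// when keep_attn, ws.A and ws.w per head for the backward pass caller).
inline void attn_forward_head(int n, int dh, double scale, const double *q,
                              const double *k, const double *v, int HD,
                              double *A, double *w, double *oh) {
  for (int i = 0; i < n; ++i) {
    double *Ai = A + (size_t)i * n;
    double mx = -1e300;
    for (int j = 0; j < n; ++j) {
      double s = 0;
      const double *qi = q + (size_t)i * HD, *kj = k + (size_t)j * HD;
      for (int c = 0; c < dh; ++c) s += qi[c] * kj[c];
      s *= scale;
      Ai[j] = s;
      if (s > mx) mx = s;
    }
    double Z = 0;
    for (int j = 0; j < n; ++j) {
      Ai[j] = std::exp(Ai[j] - mx);
      Z += Ai[j];
    }
    for (int j = 0; j < n; ++j) Ai[j] /= Z;
  }
  for (int j = 0; j < n; ++j) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += A[(size_t)i * n + j];
    w[j] = s / n;
  }
  for (int c = 0; c < dh; ++c) oh[c] = 0;
  for (int j = 0; j < n; ++j) {
    const double *vj = v + (size_t)j * HD;
    for (int c = 0; c < dh; ++c) oh[c] += w[j] * vj[c];
  }
}

// Layer vectors of one anchor: rows 0..L local (0 = seed mean), rows
// L+1..2L+1 non-local.
void encode_anchor(const GraphPack &g, const Params &P, const Precomp &pre,
                   int a, bool use_att, mat &Lv, Workspace &ws) {
  const int L = g.L, dim = P.dim, HD = P.H * P.dh;
  const double scale = 1.0 / std::sqrt((double)P.dh);
  Lv.zeros(2 * (L + 1), dim);
  for (int c = 0; c < 2; ++c) {
    const int grp = a * 2 + c;
    const int s0 = g.soff[grp], s1 = g.soff[grp + 1];
    if (s1 > s0) {
      rowvec m(dim, fill::zeros);
      for (int i = s0; i < s1; ++i) m += P.E.row(g.sd[i]);
      Lv.row(c * (L + 1)) = m / (s1 - s0);
    }
    for (int l = 1; l <= L; ++l) {
      const int B = (a * 2 + c) * L + (l - 1);
      const int b0 = g.boff[B], n = g.boff[B + 1] - b0;
      if (n == 0) continue;
      const int row = c * (L + 1) + l;
      if (!use_att) {
        rowvec m(dim, fill::zeros);
        for (int i = 0; i < n; ++i) m += P.E.row(g.bt[b0 + i]);
        Lv.row(row) = m / n;
        continue;
      }
      gather_block(g, pre, b0, n, HD, ws);
      for (int h = 0; h < P.H; ++h)
        attn_forward_head(n, P.dh, scale, ws.q.data() + h * P.dh,
                          ws.k.data() + h * P.dh, ws.v.data() + h * P.dh,
                          HD, ws.A.data(), ws.w.data(),
                          ws.o.data() + h * P.dh);
      // output projection: Wo is (H*dh x dim), column-major
      for (int d = 0; d < dim; ++d) {
        double s = 0;
        const double *col = P.Wo.colptr(d);
        for (int cc = 0; cc < HD; ++cc) s += ws.o[cc] * col[cc];
        Lv(row, d) = s;
      }
    }
  }
}

// Gradient accumulators; the projection-level pieces (dQE etc.) are turned
// into weight/embedding gradients once per batch.
struct Grads {
  mat E, R, Wo;
  mat dQE, dQR, dKA, dVA;
  void zero(const Params &P) {
    E.zeros(size(P.E));
    R.zeros(size(P.R));
    Wo.zeros(size(P.Wo));
    dQE.zeros(P.E.n_rows, P.H * P.dh);
    dQR.zeros(P.R.n_rows, P.H * P.dh);
    dKA.zeros(P.E.n_rows, P.H * P.dh);
    dVA.zeros(P.E.n_rows, P.H * P.dh);
  }
};

// Backward pass for one anchor given d(loss)/d(layer vectors); forward
// intermediates are recomputed per block.
void backward_anchor(const GraphPack &g, const Params &P, const Precomp &pre,
                     int a, bool use_att, const mat &G, Grads &gr,
                     Workspace &ws) {
  const int L = g.L, dim = P.dim, HD = P.H * P.dh;
  const double scale = 1.0 / std::sqrt((double)P.dh);
  for (int c = 0; c < 2; ++c) {
    const int grp = a * 2 + c;
    const int s0 = g.soff[grp], s1 = g.soff[grp + 1];
    if (s1 > s0) {
      const rowvec g0 = G.row(c * (L + 1)) / (s1 - s0);
      if (any(g0 != 0))
        for (int i = s0; i < s1; ++i) gr.E.row(g.sd[i]) += g0;
    }
    for (int l = 1; l <= L; ++l) {
      const rowvec gl = G.row(c * (L + 1) + l);
      if (!any(gl != 0)) continue;
      const int B = (a * 2 + c) * L + (l - 1);
      const int b0 = g.boff[B], n = g.boff[B + 1] - b0;
      if (n == 0) continue;
      if (!use_att) {
        const rowvec gt = gl / n;
        for (int i = 0; i < n; ++i) gr.E.row(g.bt[b0 + i]) += gt;
        continue;
      }
      gather_block(g, pre, b0, n, HD, ws);
      std::fill(ws.dq.begin(), ws.dq.begin() + (size_t)n * HD, 0.0);
      std::fill(ws.dk.begin(), ws.dk.begin() + (size_t)n * HD, 0.0);
      std::fill(ws.dv.begin(), ws.dv.begin() + (size_t)n * HD, 0.0);
      for (int h = 0; h < P.H; ++h) {
        const int off = h * P.dh;
        attn_forward_head(n, P.dh, scale, ws.q.data() + off,
                          ws.k.data() + off, ws.v.data() + off, HD,
                          ws.A.data(), ws.w.data(), ws.o.data() + off);
        // d(out)/d(o): out = o * Wo
        double *doh = ws.doh.data();
        for (int cc = 0; cc < P.dh; ++cc) {
          double s = 0;
          for (int d = 0; d < dim; ++d) s += P.Wo(off + cc, d) * gl[d];
          doh[cc] = s;
        }
        // o_h = sum_j w_j v_j
        for (int j = 0; j < n; ++j) {
          const double *vj = ws.v.data() + (size_t)j * HD + off;
          double s = 0;
          for (int cc = 0; cc < P.dh; ++cc) s += doh[cc] * vj[cc];
          ws.dw[j] = s;
          double *dvj = ws.dv.data() + (size_t)j * HD + off;
          for (int cc = 0; cc < P.dh; ++cc) dvj[cc] += ws.w[j] * doh[cc];
        }
        // w_j = mean_i A_ij; softmax backward row by row
        for (int i = 0; i < n; ++i) {
          const double *Ai = ws.A.data() + (size_t)i * n;
          double rowdot = 0;
          for (int j = 0; j < n; ++j) rowdot += ws.dw[j] * Ai[j];
          rowdot /= n;
          const double *qi = ws.q.data() + (size_t)i * HD + off;
          double *dqi = ws.dq.data() + (size_t)i * HD + off;
          for (int j = 0; j < n; ++j) {
            const double dS = Ai[j] * (ws.dw[j] / n - rowdot) * scale;
            if (dS == 0) continue;
            const double *kj = ws.k.data() + (size_t)j * HD + off;
            double *dkj = ws.dk.data() + (size_t)j * HD + off;
            for (int cc = 0; cc < P.dh; ++cc) {
              dqi[cc] += dS * kj[cc];
              dkj[cc] += dS * qi[cc];
            }
          }
        }
        // dWo for this head's slice
        for (int d = 0; d < dim; ++d) {
          double *col = gr.Wo.colptr(d);
          for (int cc = 0; cc < P.dh; ++cc)
            col[off + cc] += ws.o[off + cc] * gl[d];
        }
      }
      for (int i = 0; i < n; ++i) {
        const int hh = g.bh[b0 + i], rr = g.br[b0 + i], tt = g.bt[b0 + i];
        for (int cc = 0; cc < HD; ++cc) {
          gr.dQE(hh, cc) += ws.dq[(size_t)i * HD + cc];
          gr.dQR(rr, cc) += ws.dq[(size_t)i * HD + cc];
          gr.dKA(tt, cc) += ws.dk[(size_t)i * HD + cc];
          gr.dVA(tt, cc) += ws.dv[(size_t)i * HD + cc];
        }
      }
    }
  }
}

struct AdamState {
  mat m, v;
  void init(const mat &W) {
    m.zeros(size(W));
    v.zeros(size(W));
  }
};

void adam_step(mat &W, const mat &g, AdamState &s, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  s.m = b1 * s.m + (1 - b1) * g;
  s.v = b2 * s.v + (1 - b2) * (g % g);
  const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  W -= lr * (s.m / c1) / (sqrt(s.v / c2) + eps);
}

double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// Tie-aware ROC AUC via the rank statistic (average ranks on ties).
double rank_auc(const vec &scores, const ivec &labels) {
  const int n = scores.n_elem;
  uvec ord = stable_sort_index(scores);
  vec ranks(n);
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && scores[ord[j + 1]] == scores[ord[i]]) ++j;
    const double r = (i + j) / 2.0 + 1.0;
    for (int k = i; k <= j; ++k) ranks[ord[k]] = r;
    i = j + 1;
  }
  double sum_pos = 0;
  int n_pos = 0;
  for (int k = 0; k < n; ++k)
    if (labels[k] == 1) {
      sum_pos += ranks[k];
      ++n_pos;
    }
  const int n_neg = n - n_pos;
  if (n_pos == 0 || n_neg == 0) return NA_REAL;
  return (sum_pos - n_pos * (n_pos + 1) / 2.0) / ((double)n_pos * n_neg);
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_encode_anchors(List pack, arma::mat E, arma::mat R,
                             arma::mat Wq, arma::mat Wk, arma::mat Wv,
                             arma::mat Wo, int n_heads, bool use_att) {
  GraphPack g = parse_pack(pack);
  Params P{E, R, Wq, Wk, Wv, Wo, n_heads, (int)E.n_cols / n_heads,
           (int)E.n_cols};
  Precomp pre;
  pre.compute(P);
  Workspace ws;
  ws.reserve(g.max_block, P.H * P.dh);
  const int rows = 2 * (g.L + 1);
  mat out(g.n_anchor, rows * P.dim);
  mat Lv;
  for (int a = 0; a < g.n_anchor; ++a) {
    encode_anchor(g, P, pre, a, use_att, Lv, ws);
    out.row(a) = vectorise(Lv.t()).t();  // row-major concat of layer rows
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train_model(List pack, arma::mat E, arma::mat R, arma::mat Wq,
                     arma::mat Wk, arma::mat Wv, arma::mat Wo,
                     List epoch_pairs, IntegerMatrix intra_neg,
                     IntegerVector val_pm, IntegerVector val_pd,
                     IntegerVector val_nm, IntegerVector val_nd, List opts) {
  GraphPack g = parse_pack(pack);
  const int H = as<int>(opts["n_heads"]);
  Params P{E, R, Wq, Wk, Wv, Wo, H, (int)E.n_cols / H, (int)E.n_cols};
  const double lr = as<double>(opts["lr"]);
  const int batch_size = as<int>(opts["batch_size"]);
  const int max_epochs = as<int>(opts["max_epochs"]);
  const int patience = as<int>(opts["patience"]);
  const double tau = as<double>(opts["tau"]);
  const double w_intra = as<double>(opts["w_intra"]);
  const double w_inter = as<double>(opts["w_inter"]);
  const bool use_att = as<bool>(opts["use_att"]);
  const bool use_intra = as<bool>(opts["use_intra"]);
  const bool use_inter = as<bool>(opts["use_inter"]);
  const int L = g.L, dim = P.dim;
  const int n_rows = 2 * (L + 1);

  AdamState aE, aR, aWq, aWk, aWv, aWo;
  aE.init(P.E); aR.init(P.R); aWq.init(P.Wq);
  aWk.init(P.Wk); aWv.init(P.Wv); aWo.init(P.Wo);
  Grads gr;
  Precomp pre;
  Workspace ws;
  ws.reserve(g.max_block, H * P.dh);
  int t = 0;

  const int n_val = val_pm.size() + val_nm.size();
  vec val_scores(n_val);
  ivec val_labels(n_val);
  for (int i = 0; i < val_pm.size(); ++i) val_labels[i] = 1;
  for (int i = 0; i < val_nm.size(); ++i) val_labels[val_pm.size() + i] = 0;

  std::vector<double> hist_loss, hist_auc;
  double best_auc = -1.0;
  int best_epoch = 0, wait = 0;
  Params best = P;

  std::vector<mat> Lvs(g.n_anchor);
  std::vector<int> slot(g.n_anchor, -1);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    const IntegerMatrix pr = epoch_pairs[epoch];
    const int n_pairs = pr.nrow();
    double epoch_loss = 0;
    int n_batches = 0;
    for (int b0 = 0; b0 < n_pairs; b0 += batch_size) {
      const int b1 = std::min(b0 + batch_size, n_pairs);
      const int nb = b1 - b0;
      if (use_att) pre.compute(P);
      // unique anchors of this batch
      std::vector<int> anchors;
      for (int i = b0; i < b1; ++i) {
        const int am = pr(i, 0) - 1;
        const int ad = g.n_microbe + pr(i, 1) - 1;
        if (slot[am] < 0) { slot[am] = anchors.size(); anchors.push_back(am); }
        if (slot[ad] < 0) { slot[ad] = anchors.size(); anchors.push_back(ad); }
      }
      const int na = anchors.size();
      std::vector<mat> Lv(na), G(na);
      for (int j = 0; j < na; ++j) {
        encode_anchor(g, P, pre, anchors[j], use_att, Lv[j], ws);
        G[j].zeros(n_rows, dim);
      }
      double loss = 0;
      for (int i = b0; i < b1; ++i) {
        const int jm = slot[pr(i, 0) - 1];
        const int jd = slot[g.n_microbe + pr(i, 1) - 1];
        const double s = accu(Lv[jm] % Lv[jd]);
        const double yh = sigmoid(s);
        const double y = pr(i, 2);
        loss += -(y * std::log(std::max(yh, 1e-12)) +
                  (1 - y) * std::log(std::max(1 - yh, 1e-12)));
        const double gp = (yh - y) / nb;
        G[jm] += gp * Lv[jd];
        G[jd] += gp * Lv[jm];
      }
      loss /= nb;
      if (use_intra && L >= 2) {
        for (int j = 0; j < na; ++j)
          for (int c = 0; c < 2; ++c) {
            const int base = c * (L + 1);
            const int negl = intra_neg(epoch, anchors[j] * 2 + c);
            if (negl < 2) continue;
            const rowvec a = Lv[j].row(base), p = Lv[j].row(base + 1),
                         nn = Lv[j].row(base + negl);
            const double z1 = dot(a, p) / tau, z2 = dot(a, nn) / tau;
            const double m = std::max(z1, z2);
            const double e1 = std::exp(z1 - m), e2 = std::exp(z2 - m);
            const double p1 = e1 / (e1 + e2), p2 = e2 / (e1 + e2);
            loss += w_intra * -std::log(std::max(p1, 1e-300));
            G[j].row(base) += w_intra * ((p1 - 1) * p + p2 * nn) / tau;
            G[j].row(base + 1) += w_intra * (p1 - 1) * a / tau;
            G[j].row(base + negl) += w_intra * p2 * a / tau;
          }
      }
      if (use_inter) {
        vec z(L + 1);
        for (int j = 0; j < na; ++j)
          for (int k = 0; k <= L; ++k) {
            const rowvec lk = Lv[j].row(k);
            for (int jj = 0; jj <= L; ++jj)
              z[jj] = dot(lk, Lv[j].row(L + 1 + jj)) / tau;
            const double m = z.max();
            const vec ez = exp(z - m);
            const double Z = accu(ez);
            const vec pz = ez / Z;
            loss += w_inter * -(z[k] - m - std::log(Z));
            rowvec dl(dim, fill::zeros);
            for (int jj = 0; jj <= L; ++jj)
              dl += pz[jj] * Lv[j].row(L + 1 + jj);
            dl -= Lv[j].row(L + 1 + k);
            G[j].row(k) += w_inter * dl / tau;
            for (int jj = 0; jj <= L; ++jj)
              G[j].row(L + 1 + jj) +=
                  w_inter * (pz[jj] - (jj == k ? 1.0 : 0.0)) * lk / tau;
          }
      }
      gr.zero(P);
      for (int j = 0; j < na; ++j)
        backward_anchor(g, P, pre, anchors[j], use_att, G[j], gr, ws);
      ++t;
      if (use_att) {
        // fold the projection-level gradients into weight/embedding grads
        mat gWq(size(P.Wq));
        gWq.rows(0, dim - 1) = P.E.t() * gr.dQE;
        gWq.rows(dim, 2 * dim - 1) = P.R.t() * gr.dQR;
        const mat gWk = P.E.t() * gr.dKA;
        const mat gWv = P.E.t() * gr.dVA;
        gr.E += gr.dQE * P.Wq.rows(0, dim - 1).t() + gr.dKA * P.Wk.t() +
                gr.dVA * P.Wv.t();
        gr.R += gr.dQR * P.Wq.rows(dim, 2 * dim - 1).t();
        adam_step(P.Wq, gWq, aWq, lr, t);
        adam_step(P.Wk, gWk, aWk, lr, t);
        adam_step(P.Wv, gWv, aWv, lr, t);
        adam_step(P.Wo, gr.Wo, aWo, lr, t);
      }
      adam_step(P.E, gr.E, aE, lr, t);
      adam_step(P.R, gr.R, aR, lr, t);
      epoch_loss += loss;
      ++n_batches;
      for (int j = 0; j < na; ++j) slot[anchors[j]] = -1;
    }
    // validation AUC with current parameters
    if (use_att) pre.compute(P);
    std::fill(slot.begin(), slot.end(), -1);
    std::vector<int> vanchors;
    auto get_lv = [&](int a) -> const mat & {
      if (slot[a] < 0) {
        slot[a] = vanchors.size();
        vanchors.push_back(a);
        encode_anchor(g, P, pre, a, use_att, Lvs[a], ws);
      }
      return Lvs[a];
    };
    for (int i = 0; i < val_pm.size(); ++i)
      val_scores[i] =
          accu(get_lv(val_pm[i]) % get_lv(g.n_microbe + val_pd[i]));
    for (int i = 0; i < val_nm.size(); ++i)
      val_scores[val_pm.size() + i] =
          accu(get_lv(val_nm[i]) % get_lv(g.n_microbe + val_nd[i]));
    for (int a : vanchors) slot[a] = -1;
    const double auc = rank_auc(val_scores, val_labels);
    hist_loss.push_back(epoch_loss / std::max(n_batches, 1));
    hist_auc.push_back(auc);
    if (auc > best_auc + 1e-12) {
      best_auc = auc;
      best_epoch = epoch + 1;
      best = P;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
  }
  return List::create(
      _["entities"] = best.E, _["relations"] = best.R, _["wq"] = best.Wq,
      _["wk"] = best.Wk, _["wv"] = best.Wv, _["wo"] = best.Wo,
      _["train_loss"] = hist_loss, _["val_auc"] = hist_auc,
      _["best_epoch"] = best_epoch, _["best_val_auc"] = best_auc);
}
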