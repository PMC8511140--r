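// Compiled engine for the co-crystal graph network: forward pass,
// reverse-mode gradients and the Adam training loop.  The arithmetic
// mirrors the R reference layers exactly (graph convolution over bond-type
// adjacency slices, per-coformer global-state update, broadcast
// concatenation, multi-head global-attention readout, dense head with a
// two-dimensional output and softmax cross-entropy loss).
//
// Adjacency slices are visited as directed edge lists (both directions of
// every bond), so cost scales with bonds rather than N^2.

#include <RcppArmadillo.h>
#include <random>
#include <set>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::rowvec;
using arma::cube;
using arma::umat;

namespace {

struct Sample {
  mat V;                               // N x C0 node features
  std::vector<umat> edges;             // per slice: E x 2 directed (0-based)
  mat U;                               // 2 x D0 global state (may be 0 x 0)
  int n1;                              // atoms of coformer 1
};

struct Model {
  int T = 0, K = 0, Dn = 0;            // blocks, heads, dense layers
  bool has_global = false;
  std::vector<mat> gW, gb, W0, cb;     // per block (gW/gb empty when MG-only)
  std::vector<std::vector<mat>> h;     // per block, per bond-type slice: C x F
  std::vector<mat> aW1, ab1, aw2, ab2; // per head scorer MLP
  std::vector<mat> hW, hb;             // dense head

  std::vector<mat*> flat() {
    std::vector<mat*> out;
    for (int t = 0; t < T; ++t) {
      if (has_global) { out.push_back(&gW[t]); out.push_back(&gb[t]); }
      out.push_back(&W0[t]);
      for (auto& hl : h[t]) out.push_back(&hl);
      out.push_back(&cb[t]);
    }
    for (int k = 0; k < K; ++k) {
      out.push_back(&aW1[k]); out.push_back(&ab1[k]);
      out.push_back(&aw2[k]); out.push_back(&ab2[k]);
    }
    for (int d = 0; d < Dn; ++d) { out.push_back(&hW[d]); out.push_back(&hb[d]); }
    return out;
  }
};

mat as_m(SEXP x) { return as<mat>(x); }

Model parse_model(const List& params) {
  Model m;
  CharacterVector nm = params.names();
  std::set<std::string> keys;
  for (auto n : nm) keys.insert(as<std::string>(n));
  while (keys.count("b" + std::to_string(m.T + 1) + "_W0")) ++m.T;
  while (keys.count("att" + std::to_string(m.K + 1) + "_W1")) ++m.K;
  while (keys.count("head_W" + std::to_string(m.Dn + 1))) ++m.Dn;
  m.has_global = keys.count("b1_gW") > 0;
  for (int t = 1; t <= m.T; ++t) {
    std::string p = "b" + std::to_string(t) + "_";
    if (m.has_global) {
      m.gW.push_back(as_m(params[p + "gW"]));
      m.gb.push_back(as_m(params[p + "gb"]));
    }
    m.W0.push_back(as_m(params[p + "W0"]));
    cube hc = as<cube>(params[p + "h"]);
    std::vector<mat> slices;
    for (arma::uword l = 0; l < hc.n_slices; ++l) slices.push_back(hc.slice(l));
    m.h.push_back(std::move(slices));
    m.cb.push_back(as_m(params[p + "cb"]));
  }
  for (int k = 1; k <= m.K; ++k) {
    std::string p = "att" + std::to_string(k) + "_";
    m.aW1.push_back(as_m(params[p + "W1"]));
    m.ab1.push_back(as_m(params[p + "b1"]));
    m.aw2.push_back(as_m(params[p + "w2"]));
    m.ab2.push_back(as_m(params[p + "b2"]));
  }
  for (int d = 1; d <= m.Dn; ++d) {
    m.hW.push_back(as_m(params["head_W" + std::to_string(d)]));
    m.hb.push_back(as_m(params["head_b" + std::to_string(d)]));
  }
  return m;
}

List model_to_list(Model& m) {
  List out;
  for (int t = 0; t < m.T; ++t) {
    std::string p = "b" + std::to_string(t + 1) + "_";
    if (m.has_global) { out[p + "gW"] = m.gW[t]; out[p + "gb"] = m.gb[t]; }
    out[p + "W0"] = m.W0[t];
    cube hc(m.h[t][0].n_rows, m.h[t][0].n_cols, m.h[t].size());
    for (size_t l = 0; l < m.h[t].size(); ++l) hc.slice(l) = m.h[t][l];
    out[p + "h"] = hc;
    out[p + "cb"] = m.cb[t];
  }
  for (int k = 0; k < m.K; ++k) {
    std::string p = "att" + std::to_string(k + 1) + "_";
    out[p + "W1"] = m.aW1[k]; out[p + "b1"] = m.ab1[k];
    out[p + "w2"] = m.aw2[k]; out[p + "b2"] = m.ab2[k];
  }
  for (int d = 0; d < m.Dn; ++d) {
    out["head_W" + std::to_string(d + 1)] = m.hW[d];
    out["head_b" + std::to_string(d + 1)] = m.hb[d];
  }
  return out;
}

Model zeros_like(const Model& m) {
  Model z = m;
  auto zero = [](std::vector<mat>& v) { for (auto& x : v) x.zeros(); };
  zero(z.gW); zero(z.gb); zero(z.W0); zero(z.cb);
  for (auto& blk : z.h) for (auto& hl : blk) hl.zeros();
  zero(z.aW1); zero(z.ab1); zero(z.aw2); zero(z.ab2);
  zero(z.hW); zero(z.hb);
  return z;
}

Sample parse_sample(const List& s) {
  Sample out;
  out.V = as_m(s["V"]);
  List ed = s["edges"];
  for (int l = 0; l < ed.size(); ++l) {
    IntegerMatrix e = ed[l];
    umat ue(e.nrow(), 2);
    for (int r = 0; r < e.nrow(); ++r) { ue(r, 0) = e(r, 0); ue(r, 1) = e(r, 1); }
    out.edges.push_back(ue);
  }
  out.U = as_m(s["U"]);
  out.n1 = as<int>(s["n1"]);
  return out;
}

std::vector<Sample> parse_samples(const List& samples) {
  std::vector<Sample> out;
  out.reserve(samples.size());
  for (int i = 0; i < samples.size(); ++i) out.push_back(parse_sample(samples[i]));
  return out;
}

inline mat relu(const mat& x) { return arma::clamp(x, 0.0, arma::datum::inf); }

struct Cache {
  std::vector<mat> Vin, Zpre, Uin, Ugpre;     // per block
  mat X;                                       // final node embeddings
  mat Ufin;                                    // final global state (2 x G)
  std::vector<mat> Hpre;                       // per head: N x Hatt
  std::vector<vec> alpha;                      // per head
  std::vector<vec> r;                          // per head pooled
  rowvec g;                                    // head input
  std::vector<rowvec> zpre;                    // per dense layer pre-activation
  std::vector<rowvec> dropmask;                // per hidden dense layer
  vec logits;
};

// Inverted-dropout masks for the dense head's hidden layers (training only).
struct Dropout {
  double p = 0.0;
  std::mt19937* rng = nullptr;
  rowvec mask(int width) {
    rowvec m(width, arma::fill::ones);
    if (p > 0 && rng) {
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      for (int i = 0; i < width; ++i) {
        m(i) = (unif(*rng) < p) ? 0.0 : 1.0 / (1.0 - p);
      }
    }
    return m;
  }
};

// Graph convolution term: sum_l S_l (V h_l), S_l given as directed edges.
mat conv_term(const mat& V, const Sample& s, const std::vector<mat>& h) {
  mat out(V.n_rows, h[0].n_cols, arma::fill::zeros);
  for (size_t l = 0; l < h.size(); ++l) {
    if (s.edges[l].n_rows == 0) continue;
    mat M = V * h[l];
    const umat& e = s.edges[l];
    for (arma::uword r = 0; r < e.n_rows; ++r) out.row(e(r, 0)) += M.row(e(r, 1));
  }
  return out;
}

vec forward(const Sample& s, const Model& m, Cache& c,
            Dropout* drop = nullptr) {
  mat V = s.V;
  mat U = s.U;
  const int N = V.n_rows;
  for (int t = 0; t < m.T; ++t) {
    c.Vin.push_back(V);
    mat Z = V * m.W0[t] + conv_term(V, s, m.h[t]);
    Z.each_row() += m.cb[t].row(0);
    c.Zpre.push_back(Z);
    mat Vc = relu(Z);
    if (m.has_global) {
      c.Uin.push_back(U);
      mat Ug = U * m.gW[t];
      Ug.each_row() += m.gb[t].row(0);
      c.Ugpre.push_back(Ug);
      U = relu(Ug);
      mat B(N, U.n_cols);
      for (int i = 0; i < N; ++i) B.row(i) = U.row(i < s.n1 ? 0 : 1);
      V = arma::join_rows(Vc, B);
    } else {
      V = Vc;
    }
  }
  c.X = V;
  c.Ufin = U;
  // multi-head global attention readout
  rowvec g(m.K * V.n_cols + (m.has_global ? 2 * U.n_cols : 0));
  for (int k = 0; k < m.K; ++k) {
    mat Hp = V * m.aW1[k];
    Hp.each_row() += m.ab1[k].row(0);
    c.Hpre.push_back(Hp);
    vec sc = relu(Hp) * m.aw2[k].col(0) + m.ab2[k](0, 0);
    vec a = arma::exp(sc - sc.max());
    a /= arma::accu(a);
    c.alpha.push_back(a);
    vec rk = V.t() * a;
    c.r.push_back(rk);
    g.subvec(k * V.n_cols, (k + 1) * V.n_cols - 1) = rk.t();
  }
  if (m.has_global) {
    int off = m.K * V.n_cols;
    g.subvec(off, off + U.n_cols - 1) = U.row(0);
    g.subvec(off + U.n_cols, off + 2 * U.n_cols - 1) = U.row(1);
  }
  c.g = g;
  rowvec x = g;
  for (int d = 0; d < m.Dn; ++d) {
    rowvec z = x * m.hW[d] + m.hb[d].row(0);
    c.zpre.push_back(z);
    if (d < m.Dn - 1) {
      x = rowvec(relu(z));
      if (drop) {
        c.dropmask.push_back(drop->mask(x.n_cols));
        x %= c.dropmask.back();
      }
    } else {
      x = z;
    }
  }
  c.logits = x.t();
  return c.logits;
}

vec softmax2(const vec& z) {
  vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

// Accumulates dL/dtheta into `g`; returns the cross-entropy loss.
double backward(const Sample& s, int y, const Model& m, const Cache& c,
                Model& g) {
  vec p = softmax2(c.logits);
  double loss = -std::log(std::max(p(y), 1e-12));
  rowvec dz = p.t();
  dz(y) -= 1.0;

  // dense head
  const bool dropped = !c.dropmask.empty();
  std::vector<rowvec> xs(m.Dn);       // inputs of each dense layer
  xs[0] = c.g;
  for (int d = 1; d < m.Dn; ++d) {
    xs[d] = rowvec(relu(c.zpre[d - 1]));
    if (dropped) xs[d] %= c.dropmask[d - 1];
  }
  rowvec dx;
  for (int d = m.Dn - 1; d >= 0; --d) {
    g.hW[d] += xs[d].t() * dz;
    g.hb[d] += dz;
    dx = dz * m.hW[d].t();
    if (d > 0) {
      dz = dx % (c.zpre[d - 1] > 0);
      if (dropped) dz %= c.dropmask[d - 1];
    }
  }
  // split dg into head/readout and global-state parts
  const int Cfin = c.X.n_cols;
  const int N = c.X.n_rows;
  mat dX(N, Cfin, arma::fill::zeros);
  for (int k = 0; k < m.K; ++k) {
    vec dr = dx.subvec(k * Cfin, (k + 1) * Cfin - 1).t();
    const vec& a = c.alpha[k];
    dX += a * dr.t();
    vec dalpha = c.X * dr;
    vec ds = a % (dalpha - arma::dot(a, dalpha));
    mat Hpost = relu(c.Hpre[k]);
    g.aw2[k] += Hpost.t() * ds;
    g.ab2[k](0, 0) += arma::accu(ds);
    mat dH = (ds * m.aw2[k].col(0).t()) % (c.Hpre[k] > 0);
    g.aW1[k] += c.X.t() * dH;
    g.ab1[k] += arma::sum(dH, 0);
    dX += dH * m.aW1[k].t();
  }
  mat dU;
  if (m.has_global) {
    int off = m.K * Cfin;
    int G = c.Ufin.n_cols;
    dU.set_size(2, G);
    dU.row(0) = dx.subvec(off, off + G - 1);
    dU.row(1) = dx.subvec(off + G, off + 2 * G - 1);
  }

  // blocks in reverse
  mat dV = dX;
  for (int t = m.T - 1; t >= 0; --t) {
    const int F = m.W0[t].n_cols;
    mat dVc;
    if (m.has_global) {
      const int G = m.gW[t].n_cols;
      dVc = dV.cols(0, F - 1);
      mat dB = dV.cols(F, F + G - 1);
      for (int i = 0; i < N; ++i) dU.row(i < s.n1 ? 0 : 1) += dB.row(i);
      mat dUg = dU % (c.Ugpre[t] > 0);
      g.gW[t] += c.Uin[t].t() * dUg;
      g.gb[t] += arma::sum(dUg, 0);
      dU = dUg * m.gW[t].t();
    } else {
      dVc = dV;
    }
    mat dZ = dVc % (c.Zpre[t] > 0);
    g.W0[t] += c.Vin[t].t() * dZ;
    g.cb[t] += arma::sum(dZ, 0);
    mat dVin = dZ * m.W0[t].t();
    for (size_t l = 0; l < m.h[t].size(); ++l) {
      const umat& e = s.edges[l];
      if (e.n_rows == 0) continue;
      mat dM(N, F, arma::fill::zeros);
      for (arma::uword r = 0; r < e.n_rows; ++r) dM.row(e(r, 1)) += dZ.row(e(r, 0));
      g.h[t][l] += c.Vin[t].t() * dM;
      dVin += dM * m.h[t][l].t();
    }
    dV = dVin;
  }
  return loss;
}

}  // namespace

// [[Rcpp::export]]
List ccg_forward_cpp(List sample, List params) {
  Model m = parse_model(params);
  Sample s = parse_sample(sample);
  Cache c;
  vec logits = forward(s, m, c);
  mat att(s.V.n_rows, m.K);
  for (int k = 0; k < m.K; ++k) att.col(k) = c.alpha[k];
  return List::create(_["logits"] = logits, _["prob"] = softmax2(logits),
                      _["attention"] = att);
}

// [[Rcpp::export]]
arma::mat ccg_predict_cpp(List samples, List params) {
  Model m = parse_model(params);
  std::vector<Sample> ss = parse_samples(samples);
  mat out(ss.size(), 2);
  for (size_t i = 0; i < ss.size(); ++i) {
    Cache c;
    out.row(i) = softmax2(forward(ss[i], m, c)).t();
  }
  return out;
}

// [[Rcpp::export]]
List ccg_grad_cpp(List sample, int y, List params) {
  Model m = parse_model(params);
  Sample s = parse_sample(sample);
  Model g = zeros_like(m);
  Cache c;
  forward(s, m, c);
  double loss = backward(s, y, m, c, g);
  return List::create(_["loss"] = loss, _["grads"] = model_to_list(g));
}

// [[Rcpp::export]]
double ccg_loss_cpp(List samples, IntegerVector y, List params) {
  Model m = parse_model(params);
  std::vector<Sample> ss = parse_samples(samples);
  double total = 0.0;
  for (size_t i = 0; i < ss.size(); ++i) {
    Cache c;
    vec p = softmax2(forward(ss[i], m, c));
    total += -std::log(std::max(p(y[i]), 1e-12));
  }
  return total / std::max<size_t>(ss.size(), 1);
}

// [[Rcpp::export]]
List ccg_train_cpp(List samples, IntegerVector y, List params,
                   int epochs, int batch_size, double lr, int seed,
                   double weight_decay = 0.0, double dropout = 0.0) {
  Model m = parse_model(params);
  std::vector<Sample> ss = parse_samples(samples);
  const int n = ss.size();
  if (n == 0) stop("no training samples");

  Model grad = zeros_like(m), madam = zeros_like(m), vadam = zeros_like(m);
  std::vector<mat*> theta = m.flat(), gflat = grad.flat(),
                    mflat = madam.flat(), vflat = vadam.flat();

  std::mt19937 rng(static_cast<unsigned>(seed));
  Dropout drop{dropout, &rng};
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;
  NumericVector history(epochs);
  for (int ep = 0; ep < epochs; ++ep) {
    // explicit Fisher-Yates so shuffles are reproducible from the seed alone
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(rng() % static_cast<unsigned>(i + 1));
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      int stop_at = std::min(start + batch_size, n);
      int bs = stop_at - start;
      for (auto* g : gflat) g->zeros();
      double batch_loss = 0.0;
      for (int i = start; i < stop_at; ++i) {
        Cache c;
        forward(ss[order[i]], m, c, dropout > 0 ? &drop : nullptr);
        batch_loss += backward(ss[order[i]], y[order[i]], m, c, grad);
      }
      ep_loss += batch_loss;
      if (!std::isfinite(batch_loss)) {
        stop("divergence: non-finite loss at epoch %d", ep + 1);
      }
      ++step;
      double corr = std::sqrt(1.0 - std::pow(b2, step)) /
                    (1.0 - std::pow(b1, step));
      for (size_t p = 0; p < theta.size(); ++p) {
        mat gmean = *gflat[p] / bs;
        *mflat[p] = b1 * (*mflat[p]) + (1 - b1) * gmean;
        *vflat[p] = b2 * (*vflat[p]) + (1 - b2) * arma::square(gmean);
        *theta[p] -= lr * corr * (*mflat[p]) / (arma::sqrt(*vflat[p]) + eps);
        if (weight_decay > 0) *theta[p] *= (1.0 - lr * weight_decay);
      }
    }
    history[ep] = ep_loss / n;
    if (ep % 10 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = model_to_list(m), _["history"] = history);
}
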